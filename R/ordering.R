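# Ancestral reconstruction, branch substitution mapping, mt-first vs
# N-mt-first classification of contact pairs along root-to-tip paths, and
# the ordering statistics.

# state matrix for reconstruction: amino alignments give residue columns,
# codon alignments give codon-string columns
state_matrix <- function(alignment) {
  m <- unclass(alignment)
  if (aln_molecule(alignment) == "amino") {
    m[is_missing_state(m)] <- NA_character_
    return(m)
  }
  cod <- matrix(NA_character_, nrow(m), ncol(m) %/% 3L,
                dimnames = list(rownames(m), NULL))
  for (i in seq_len(nrow(m))) cod[i, ] <- to_codons(m[i, ])
  cod[grepl("[^ACGT]", cod)] <- NA_character_
  cod
}

#' Ancestral state reconstruction on a fixed tree
#'
#' `method = "fitch"` runs two-pass Fitch parsimony with a deterministic
#' resolution rule: on the downward pass, a node whose optimal set has more
#' than one state takes its parent's assigned state when that state is in
#' the set, else the lexicographically smallest member. `method =
#' "marginal_ml"` computes marginal posteriors under the Poisson model on
#' the tree's branch lengths and assigns each node its MAP state (ties
#' resolved lexicographically). Gaps are missing data: a gapped tip is
#' reported `NA` and constrains nothing; a fully missing column is `NA`
#' everywhere.
#'
#' @param alignment An [mn_alignment] (amino, or codon — codon columns are
#'   reconstructed as whole codons).
#' @param tree Rooted binary `phylo`, tips matching the alignment taxa.
#' @param method `"fitch"` (default) or `"marginal_ml"` (amino only).
#' @return Character matrix (rows = all nodes in ape numbering, columns =
#'   alignment sites) of reconstructed states, with attribute
#'   `parsimony_score` (per-column changes implied by the Fitch pass) for
#'   `method = "fitch"`.
#' @export
reconstruct_ancestral <- function(alignment, tree,
                                  method = c("fitch", "marginal_ml")) {
  method <- match.arg(method)
  if (!setequal(tree$tip.label, aln_taxa(alignment)))
    stop("tree tips and alignment taxa differ")
  sm <- state_matrix(alignment)[tree$tip.label, , drop = FALSE]
  n_tip <- ape::Ntip(tree)
  root <- n_tip + 1L
  n_node <- max(tree$edge)
  if (method == "marginal_ml") {
    if (aln_molecule(alignment) != "amino")
      stop("marginal_ml reconstruction is implemented for amino alignments")
    return(reconstruct_marginal_ml(sm, tree))
  }
  post <- reorder_postorder(tree)
  pre <- reorder_preorder(tree)
  parent <- integer(n_node)
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  children <- split(tree$edge[, 2], tree$edge[, 1])
  out <- matrix(NA_character_, n_node, ncol(sm))
  score <- integer(ncol(sm))
  for (col in seq_len(ncol(sm))) {
    obs <- sm[, col]
    alpha <- sort(unique(obs[!is.na(obs)]))
    if (!length(alpha)) next
    sets <- vector("list", n_node)
    for (i in seq_len(n_tip))
      sets[[i]] <- if (is.na(obs[i])) alpha else obs[i]
    # upward pass (fold of the binary Fitch rule; unique() preserves the
    # postorder guarantee that children are processed before parents)
    for (p in unique(tree$edge[post, 1])) {
      s <- NULL
      for (k in children[[as.character(p)]]) {
        sk <- sets[[k]]
        if (is.null(s)) { s <- sk; next }
        inter <- intersect(s, sk)
        if (length(inter)) s <- inter
        else { s <- union(s, sk); score[col] <- score[col] + 1L }
      }
      sets[[p]] <- sort(s)
    }
    # downward pass with deterministic resolution
    final <- character(n_node)
    final[root] <- sets[[root]][1]
    for (e in pre) {
      v <- tree$edge[e, 2]
      if (v <= n_tip) next
      ps <- final[tree$edge[e, 1]]
      final[v] <- if (ps %in% sets[[v]]) ps else sets[[v]][1]
    }
    out[(n_tip + 1L):n_node, col] <- final[(n_tip + 1L):n_node]
    out[seq_len(n_tip), col] <- obs
  }
  attr(out, "parsimony_score") <- score
  out
}

# marginal ML (MAP) reconstruction under the Poisson amino model
reconstruct_marginal_ml <- function(sm, tree) {
  n_tip <- ape::Ntip(tree)
  root <- n_tip + 1L
  n_node <- max(tree$edge)
  pfun <- make_transition_fun(NULL)
  lengths <- numeric(n_node)
  lengths[tree$edge[, 2]] <- tree$edge.length
  key <- apply(sm, 2L, paste, collapse = "\r")
  first <- which(!duplicated(key))
  map_back <- match(key, key[first])
  pat <- sm[, first, drop = FALSE]
  tips_part <- lapply(seq_len(n_tip), function(i) tip_partials(pat[i, ]))
  down <- down_partials(tree, tips_part, lengths, pfun)
  up <- up_partials(tree, down, lengths, pfun)
  out <- matrix(NA_character_, n_node, length(first))
  for (v in (n_tip + 1L):n_node) {
    marg <- if (v == root) down[[root]] else
      down[[v]] * (pfun(lengths[v]) %*% up[[v]])
    best <- apply(marg, 2, which.max)
    tot <- colSums(marg)
    states <- AMINO_ACIDS[best]
    states[tot == 0] <- NA_character_
    # a fully missing pattern has flat partials: leave NA
    allmiss <- apply(is.na(pat), 2, all)
    states[allmiss] <- NA_character_
    out[v, ] <- states
  }
  out[seq_len(n_tip), ] <- pat
  res <- out[, map_back, drop = FALSE]
  allmiss_full <- apply(is.na(sm), 2, all)
  res[, allmiss_full] <- NA_character_
  res
}

#' Map substitutions onto branches
#'
#' Emits one event per (branch, column) where the reconstructed state of the
#' child differs from that of the parent, both non-missing.
#'
#' @param states Node-by-column state matrix from [reconstruct_ancestral()].
#' @param tree The tree used for the reconstruction.
#' @param gene,genome Labels attached to the events (`genome` is `"mt"` or
#'   `"nuclear"`).
#' @return data.frame with columns `gene`, `genome`, `site`, `branch_id`,
#'   `depth`, `from`, `to`.
#' @export
map_substitutions <- function(states, tree, gene = NA_character_,
                              genome = NA_character_) {
  bt <- branch_table(tree)
  depth <- stats::setNames(bt$depth, as.character(bt$branch_id))
  ev <- list()
  for (e in seq_len(nrow(tree$edge))) {
    p <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    su <- states[p, ]; sv <- states[v, ]
    hit <- which(!is.na(su) & !is.na(sv) & su != sv)
    if (length(hit))
      ev[[length(ev) + 1L]] <- data.frame(
        gene = gene, genome = genome, site = hit, branch_id = v,
        depth = depth[[as.character(v)]], from = su[hit], to = sv[hit],
        stringsAsFactors = FALSE)
  }
  if (!length(ev))
    return(data.frame(gene = character(0), genome = character(0),
                      site = integer(0), branch_id = integer(0),
                      depth = integer(0), from = character(0),
                      to = character(0)))
  out <- do.call(rbind, ev)
  out[order(out$depth, out$branch_id, out$site), , drop = FALSE]
}

#' Classify the substitution order of one contact pair
#'
#' For every root-to-tip path carrying at least one substitution at each
#' partner site, the shallowest event per partner on that path is compared
#' by branch depth: shallower mt event -> `mt_first`, shallower N-mt event
#' -> `nmt_first`, the same branch -> `same_branch`. The per-pair
#' classification aggregates paths by majority of mt_first vs nmt_first
#' votes; an exact tie, or no qualifying path, gives `unresolved`; only
#' same-branch co-occurrences give `same_branch`. Branch separation is the
#' smallest depth difference among the winning paths (adjacent branches =
#' 1); pairs with separation 1 or 2 are `close`, otherwise `far`.
#'
#' @param mt_events,nmt_events Event data.frames ([map_substitutions()]).
#' @param pair List or one-row data.frame with `pair_id`, `mt_column`,
#'   `nmt_column`.
#' @param tree Rooted `phylo`.
#' @param tips Optional tip-label subset restricting the analysis to the
#'   root-to-tip paths of a lineage (e.g. primates).
#' @return One-row data.frame: `pair_id`, `classification`, `separation`,
#'   `proximity`, `n_paths_mt_first`, `n_paths_nmt_first`,
#'   `n_paths_same_branch`.
#' @export
classify_pair_order <- function(mt_events, nmt_events, pair, tree, tips = NULL) {
  mt_ev <- mt_events[mt_events$site == pair$mt_column, , drop = FALSE]
  nmt_ev <- nmt_events[nmt_events$site == pair$nmt_column, , drop = FALSE]
  paths <- tip_branch_paths(tree)
  if (!is.null(tips)) paths <- paths[match(tips, tree$tip.label)]
  votes <- c(mt_first = 0L, nmt_first = 0L, same_branch = 0L)
  seps <- list(mt_first = integer(0), nmt_first = integer(0))
  for (path in paths) {
    dm <- mt_ev$depth[mt_ev$branch_id %in% path]
    dn <- nmt_ev$depth[nmt_ev$branch_id %in% path]
    if (!length(dm) || !length(dn)) next
    dm <- min(dm); dn <- min(dn)
    if (dm == dn) { votes["same_branch"] <- votes["same_branch"] + 1L; next }
    lbl <- if (dm < dn) "mt_first" else "nmt_first"
    votes[lbl] <- votes[lbl] + 1L
    seps[[lbl]] <- c(seps[[lbl]], abs(dm - dn))
  }
  cls <- if (votes["mt_first"] + votes["nmt_first"] == 0L) {
    if (votes["same_branch"] > 0L) "same_branch" else "unresolved"
  } else if (votes["mt_first"] == votes["nmt_first"]) {
    "unresolved"
  } else if (votes["mt_first"] > votes["nmt_first"]) "mt_first" else "nmt_first"
  sep <- if (cls %in% c("mt_first", "nmt_first")) min(seps[[cls]]) else NA_integer_
  prox <- if (cls %in% c("mt_first", "nmt_first")) {
    if (sep >= 1 && sep <= 2) "close" else "far"
  } else NA_character_
  data.frame(pair_id = pair$pair_id, classification = cls,
             separation = sep, proximity = prox,
             n_paths_mt_first = unname(votes["mt_first"]),
             n_paths_nmt_first = unname(votes["nmt_first"]),
             n_paths_same_branch = unname(votes["same_branch"]),
             stringsAsFactors = FALSE)
}

#' Close/far proximity of a classified contact pair
#'
#' A resolved pair is `close` when its events are one or two branches apart
#' along the shared root-to-tip path (the deeper branch then necessarily
#' lies in the clade subtended by the shallower one), and `far` otherwise.
#' Same-branch and unresolved records have no proximity.
#'
#' @param record One-row record from [classify_pair_order()].
#' @return `"close"` or `"far"`.
#' @export
proximity <- function(record) {
  if (!record$classification %in% c("mt_first", "nmt_first"))
    stop("proximity applies only to mt_first/nmt_first records")
  if (record$separation >= 1 && record$separation <= 2) "close" else "far"
}

#' Chi-square test of equal mt-first and N-mt-first counts
#'
#' One-degree-of-freedom goodness-of-fit test of the observed (mt_first,
#' nmt_first) counts against equal expected counts.
#'
#' @param n_mt_first,n_nmt_first Non-negative counts (total >= 1).
#' @return List of class `mn_ordering_test`: `counts`, `chi_square`, `df`,
#'   `p`, `test`.
#' @export
chisq_equal_order <- function(n_mt_first, n_nmt_first) {
  if (n_mt_first + n_nmt_first < 1) stop("total count must be >= 1")
  ht <- stats::chisq.test(c(n_mt_first, n_nmt_first), p = c(0.5, 0.5),
                          correct = FALSE)
  structure(list(counts = c(mt_first = n_mt_first, nmt_first = n_nmt_first),
                 chi_square = unname(ht$statistic), df = unname(ht$parameter),
                 p = ht$p.value, test = "chisq_equal_order"),
            class = "mn_ordering_test")
}

#' Fisher exact test for mt-first enrichment
#'
#' Exact test on a 2x2 table of (mt_first, nmt_first) counts in a focal
#' versus a comparison dataset: conditional-MLE odds ratio, exact CI, and
#' the two-sided P obtained by summing tables at least as extreme
#' (probability at or below the observed table).
#'
#' @param table 2x2 matrix of non-negative counts (rows = datasets, columns
#'   = mt_first / nmt_first).
#' @return `mn_ordering_test` list: `odds_ratio`, `or_ci`, `p`, `test`.
#' @export
fisher_mtfirst_enrichment <- function(table) {
  stopifnot(is.matrix(table), all(dim(table) == 2), all(table >= 0))
  ht <- stats::fisher.test(table)
  structure(list(counts = table, odds_ratio = unname(ht$estimate),
                 or_ci = as.numeric(ht$conf.int), p = ht$p.value,
                 test = "fisher_mtfirst_enrichment"),
            class = "mn_ordering_test")
}

#' @export
print.mn_ordering_test <- function(x, ...) {
  if (x$test == "chisq_equal_order")
    cat(sprintf("chi-square = %.2f, df = %d, P = %.3g (mt_first = %d, nmt_first = %d)\n",
                x$chi_square, x$df, x$p, x$counts[1], x$counts[2]))
  else
    cat(sprintf("odds ratio = %.2f, 95%% CI = %.2f..%.2f, P = %.3g\n",
                x$odds_ratio, x$or_ci[1], x$or_ci[2], x$p))
  invisible(x)
}

#' Per-branch mt and N-mt substitution counts
#'
#' @param events Event data.frame with `genome` and `branch_id` columns
#'   (e.g. rbind of mt and N-mt [map_substitutions()] output).
#' @param tree Rooted `phylo`.
#' @return data.frame with one row per branch: `branch_id`, `depth`,
#'   `mt_count`, `nmt_count`, `more` (`"mt"`, `"nmt"` or `"equal"`).
#' @export
branch_substitution_summary <- function(events, tree) {
  bt <- branch_table(tree)
  mt <- table(factor(events$branch_id[events$genome == "mt"],
                     levels = bt$branch_id))
  nmt <- table(factor(events$branch_id[events$genome == "nuclear"],
                      levels = bt$branch_id))
  data.frame(branch_id = bt$branch_id, depth = bt$depth,
             mt_count = as.integer(mt), nmt_count = as.integer(nmt),
             more = ifelse(mt > nmt, "mt", ifelse(nmt > mt, "nmt", "equal")))
}
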