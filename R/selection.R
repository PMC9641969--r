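# Counting-based site-level positive-selection detection, contact
# enrichment, and frequency-based functional-nodal-mutation flags.

#' Counting-based positive-selection test for one codon site
#'
#' A counting (SLAC-style) alternative to likelihood branch-site machinery:
#' synonymous and nonsynonymous changes at the site are counted over the
#' (optionally foreground-restricted) branches by replaying the ancestral
#' codon reconstruction; the expected nonsynonymous fraction comes from the
#' site's NG86 opportunities on the parent codon of each branch, weighted by
#' branch length; the P value is the one-sided binomial probability of at
#' least the observed nonsynonymous count. Categorical agreement with
#' likelihood-based site tests is not claimed.
#'
#' @param alignment Codon [mn_alignment].
#' @param tree Rooted `phylo` with branch lengths.
#' @param site Codon index (1-based).
#' @param foreground Optional vector of branch ids restricting the counted
#'   branches (a foreground subtree set); `NULL` means all branches.
#' @param alpha,stringent_alpha Significance levels for the `selected` and
#'   `stringent` flags (defaults 0.05 / 0.01).
#' @param states Optional precomputed codon reconstruction
#'   ([reconstruct_ancestral()] on the codon alignment) to avoid repeating
#'   it per site.
#' @param code Genetic code.
#' @return List of class `mn_site_sel`: `site`, `n_changes`, `n_nonsyn`,
#'   `n_syn`, `excess` (site dN - dS scaled by opportunity), `p`,
#'   `selected`, `stringent`.
#' @export
site_selection_test <- function(alignment, tree, site, foreground = NULL,
                                alpha = 0.05, stringent_alpha = 0.01,
                                states = NULL, code = "standard") {
  if (is.null(states)) states <- reconstruct_ancestral(alignment, tree)
  bt <- branch_table(tree)
  lengths <- stats::setNames(bt$length, as.character(bt$branch_id))
  tabs <- codon_tables(code)
  branches <- if (is.null(foreground)) bt$branch_id else
    intersect(bt$branch_id, foreground)
  nd <- 0; sd_ <- 0
  opp_syn <- 0; opp_tot <- 0
  for (v in branches) {
    e <- which(tree$edge[, 2] == v)
    p <- tree$edge[e, 1]
    cu <- states[p, site]; cv <- states[v, site]
    if (is.na(cu)) next
    s_op <- tabs$sites[cu, ]
    t_b <- lengths[[as.character(v)]]
    opp_syn <- opp_syn + t_b * s_op[["syn"]]
    opp_tot <- opp_tot + t_b * (s_op[["syn"]] + s_op[["nonsyn"]])
    if (is.na(cv) || cu == cv) next
    d <- codon_path_counts(cu, cv, code)
    sd_ <- sd_ + d[["syn"]]
    nd <- nd + d[["nonsyn"]]
  }
  n_tot <- round(nd + sd_)
  p_syn <- if (opp_tot > 0) opp_syn / opp_tot else 0.25
  p_ns <- 1 - p_syn
  p_val <- if (n_tot == 0) 1 else
    stats::pbinom(round(nd) - 1L, n_tot, p_ns, lower.tail = FALSE)
  excess <- {
    s_sites <- opp_syn; n_sites <- opp_tot - opp_syn
    dn <- if (n_sites > 0) nd / n_sites else 0
    ds <- if (s_sites > 0) sd_ / s_sites else 0
    dn - ds
  }
  structure(list(site = site, n_changes = n_tot, n_nonsyn = nd, n_syn = sd_,
                 excess = excess, p = p_val,
                 selected = p_val < alpha,
                 stringent = p_val < stringent_alpha),
            class = "mn_site_sel")
}

#' Run the site selection test across all sites of a gene
#'
#' @inheritParams site_selection_test
#' @param gene Label attached to the rows.
#' @return data.frame with one row per codon site: `gene`, `site`,
#'   `n_changes`, `n_nonsyn`, `n_syn`, `excess`, `p`, `selected`,
#'   `stringent`.
#' @export
scan_site_selection <- function(alignment, tree, gene = NA_character_,
                                foreground = NULL, alpha = 0.05,
                                stringent_alpha = 0.01, code = "standard") {
  states <- reconstruct_ancestral(alignment, tree)
  n_sites <- ncol(states)
  rows <- lapply(seq_len(n_sites), function(s) {
    r <- site_selection_test(alignment, tree, s, foreground = foreground,
                             alpha = alpha, stringent_alpha = stringent_alpha,
                             states = states, code = code)
    data.frame(gene = gene, site = s, n_changes = r$n_changes,
               n_nonsyn = r$n_nonsyn, n_syn = r$n_syn, excess = r$excess,
               p = r$p, selected = r$selected, stringent = r$stringent)
  })
  do.call(rbind, rows)
}

#' Proportion of selected sites per partition
#'
#' @param results data.frame from [scan_site_selection()] (columns `site`,
#'   `selected`; optionally `gene`).
#' @param partition Named character vector site -> `"contact"` /
#'   `"non-contact"` (names are site indices, or `"gene:site"` keys when
#'   `results` spans genes).
#' @return data.frame per partition cell: `partition`, `n_sites`,
#'   `n_selected`, `proportion` (NA for empty cells).
#' @export
proportion_selected <- function(results, partition) {
  key <- if (!is.null(results$gene) && any(grepl(":", names(partition))))
    paste0(results$gene, ":", results$site) else as.character(results$site)
  status <- partition[key]
  lev <- unique(stats::na.omit(as.character(partition)))
  out <- lapply(lev, function(lv) {
    sel <- results$selected[!is.na(status) & status == lv]
    data.frame(partition = lv, n_sites = length(sel),
               n_selected = sum(sel),
               proportion = if (length(sel)) mean(sel) else NA_real_)
  })
  do.call(rbind, out)
}

#' Contact enrichment of positively selected sites
#'
#' Fisher exact test of selection status against contact status over sites.
#'
#' @param selected Logical vector (site selected?).
#' @param contact Logical vector of the same length (site in a mitonuclear
#'   contact pair?).
#' @return `mn_ordering_test` from [fisher_mtfirst_enrichment()] machinery,
#'   with rows = contact status and columns = selected status.
#' @export
contact_enrichment <- function(selected, contact) {
  stopifnot(length(selected) == length(contact))
  tab <- matrix(c(sum(contact & selected), sum(contact & !selected),
                  sum(!contact & selected), sum(!contact & !selected)),
                2, 2, byrow = TRUE,
                dimnames = list(c("contact", "non-contact"),
                                c("selected", "not_selected")))
  fisher_mtfirst_enrichment(tab)
}

#' Frequency-based functional-nodal-mutation (FNM) flag
#'
#' Flags a substitution whose derived residue is rare (frequency below
#' `threshold`) among the non-gap residues of its alignment column. This is
#' the frequency component of predictive deleteriousness models only — no
#' structural stability term — and is labelled "frequency-FNM" accordingly.
#'
#' @param event One event row (needs `site` and `to`).
#' @param alignment The amino [mn_alignment] the event was mapped on.
#' @param threshold Frequency threshold (default 0.05).
#' @return List of class `mn_fnm`: `site`, `derived`, `frequency`,
#'   `flagged`, `threshold` (`flagged` is NA for an all-gap column).
#' @export
flag_functional_nodal <- function(event, alignment, threshold = 0.05) {
  col <- unclass(alignment)[, event$site]
  res <- col[!is_missing_state(col)]
  if (!length(res))
    return(structure(list(site = event$site, derived = event$to,
                          frequency = NA_real_, flagged = NA,
                          threshold = threshold), class = "mn_fnm"))
  freq <- mean(res == event$to)
  structure(list(site = event$site, derived = event$to, frequency = freq,
                 flagged = freq < threshold, threshold = threshold),
            class = "mn_fnm")
}
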