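# Synthetic-data generator: seeded trees, correlated lineage rate scalars,
# amino-acid and codon sequence evolution with full event logs, and
# compensatory contact-pair dynamics with known ordering ground truth.

#' Simulation configuration
#'
#' Bundles every tunable of the synthetic-data generator. All randomness in
#' the generator flows from `seed`; sub-streams are derived per stage so that
#' stages can be re-run independently with identical results.
#'
#' Defaults describe a mammal-like study system: 60 taxa, lineage log-rate
#' scalars with sd 0.3 (so the fastest of ~60 lineages evolves roughly 3x
#' faster than the slowest), strong mitonuclear rate coupling (rho = 0.8),
#' purifying selection throughout with elevated omega in nuclear-encoded
#' mitochondrially targeted (N-mt) genes, and a mild transition bias.
#'
#' @param n_taxa Number of tips (>= 2).
#' @param tree_source `"yule"` or a fixed Newick string.
#' @param seq_length Sites (amino mode) or codons (codon mode).
#' @param rate_coupling_rho Correlation in \[-1, 1\] between mt and N-mt
#'   per-branch log rate scalars.
#' @param scalar_sd Standard deviation (>= 0) of the log scalars.
#' @param base_rate Expected substitutions per site per unit branch length.
#' @param omega_by_geneset Named vector of dN/dS values (>= 0) per gene set.
#' @param kappa Transition/transversion rate ratio (> 0).
#' @param compensation_boost_beta Rate multiplier (>= 1) applied to a contact
#'   partner after its mate substitutes.
#' @param compensation_direction `"mt_triggers_n"`, `"n_triggers_mt"` or
#'   `"none"`.
#' @param seed Integer master seed.
#' @return A list of class `mn_sim_config`.
#' @export
simulation_config <- function(n_taxa = 60L,
                              tree_source = "yule",
                              seq_length = 300L,
                              rate_coupling_rho = 0.8,
                              scalar_sd = 0.3,
                              base_rate = 0.1,
                              omega_by_geneset = c(mt = 0.06, nmt_oxphos = 0.16,
                                                   nmt_ribo = 0.16, glycolysis = 0.07,
                                                   cytoribo = 0.03, nrand = 0.12),
                              kappa = 2,
                              compensation_boost_beta = 1,
                              compensation_direction = c("none", "mt_triggers_n",
                                                         "n_triggers_mt"),
                              seed = 1L) {
  compensation_direction <- match.arg(compensation_direction)
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  if (abs(rate_coupling_rho) > 1) stop("rate_coupling_rho must be in [-1, 1]")
  if (scalar_sd < 0) stop("scalar_sd must be >= 0")
  if (base_rate < 0) stop("base_rate must be >= 0")
  if (any(omega_by_geneset < 0)) stop("omega values must be >= 0")
  if (kappa <= 0) stop("kappa must be > 0")
  if (compensation_boost_beta < 1) stop("compensation_boost_beta must be >= 1")
  structure(list(n_taxa = as.integer(n_taxa), tree_source = tree_source,
                 seq_length = as.integer(seq_length),
                 rate_coupling_rho = rate_coupling_rho, scalar_sd = scalar_sd,
                 base_rate = base_rate, omega_by_geneset = omega_by_geneset,
                 kappa = kappa,
                 compensation_boost_beta = compensation_boost_beta,
                 compensation_direction = compensation_direction,
                 seed = as.integer(seed)),
            class = "mn_sim_config")
}

#' Generate a random Yule (pure-birth) tree
#'
#' @param n_taxa Number of tips (>= 2).
#' @param seed Integer seed; identical seeds give byte-identical trees.
#' @return Rooted binary `phylo` with tips `s01, s02, ...` and positive
#'   branch lengths.
#' @export
generate_yule_tree <- function(n_taxa, seed) {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  set.seed(stage_seed(seed, "tree"))
  tree <- ape::rphylo(n_taxa, birth = 1, death = 0)
  tree$tip.label <- sprintf("s%02d", seq_len(n_taxa))
  tree
}

#' Draw correlated mt / N-mt branch rate scalars
#'
#' Per-branch log scalars are bivariate normal with mean 0, standard
#' deviation `sd` per margin and correlation `rho`; exponentiation gives
#' strictly positive multiplicative rate scalars. These emulate lineage
#' effects shared (to degree `rho`) between the mitochondrial and
#' nuclear-encoded mt-targeted gene sets.
#'
#' @param tree Rooted `phylo`.
#' @param rho Correlation in \[-1, 1\].
#' @param sd Standard deviation of the log scalars (>= 0).
#' @param seed Integer seed.
#' @return data.frame with columns `branch_id`, `mt`, `nmt`.
#' @export
draw_branch_scalars <- function(tree, rho, sd, seed) {
  if (abs(rho) > 1) stop("rho must be in [-1, 1]")
  if (sd < 0) stop("sd must be >= 0")
  bt <- branch_table(tree)
  set.seed(stage_seed(seed, "scalars"))
  n <- nrow(bt)
  z1 <- stats::rnorm(n)
  z2 <- stats::rnorm(n)
  log_mt <- sd * z1
  log_nmt <- sd * (rho * z1 + sqrt(1 - rho^2) * z2)
  data.frame(branch_id = bt$branch_id, mt = exp(log_mt), nmt = exp(log_nmt))
}

# per-branch amino-acid evolution with an equal-exchangeability 20-state
# process; returns node-state matrix plus event log
sim_amino_states <- function(tree, rates_per_branch, length, root_seq = NULL) {
  n_tip <- ape::Ntip(tree)
  root <- n_tip + 1L
  n_node <- max(tree$edge)
  bt <- branch_table(tree)
  depth <- stats::setNames(bt$depth, bt$branch_id)
  states <- matrix(NA_character_, n_node, length)
  if (is.null(root_seq)) root_seq <- sample(AMINO_ACIDS, length, replace = TRUE)
  states[root, ] <- root_seq
  ev_site <- integer(0); ev_branch <- integer(0); ev_depth <- integer(0)
  ev_from <- character(0); ev_to <- character(0)
  for (e in reorder_preorder(tree)) {
    p <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    seq_v <- states[p, ]
    r <- rates_per_branch[[as.character(v)]]
    k <- stats::rpois(length, r)
    for (site in which(k > 0)) {
      for (j in seq_len(k[site])) {
        from <- seq_v[site]
        to <- sample(setdiff(AMINO_ACIDS, from), 1)
        seq_v[site] <- to
        ev_site <- c(ev_site, site); ev_branch <- c(ev_branch, v)
        ev_depth <- c(ev_depth, depth[[as.character(v)]])
        ev_from <- c(ev_from, from); ev_to <- c(ev_to, to)
      }
    }
    states[v, ] <- seq_v
  }
  events <- data.frame(site = ev_site, branch_id = ev_branch,
                       depth = ev_depth, from = ev_from, to = ev_to,
                       stringsAsFactors = FALSE)
  list(states = states, events = events, root_seq = root_seq)
}

# precompute GY-style codon rate structure for (omega, kappa, code): per sense
# codon the sense targets, their weights, and total weight; weights are scaled
# so the uniform-average total rate equals 1
codon_rate_tables <- function(omega, kappa, code = "standard") {
  tabs <- codon_tables(code)
  per <- lapply(tabs$sense, function(cd) {
    nb <- tabs$neighbors[[cd]]
    w <- ifelse(nb$transition, kappa, 1) * ifelse(nb$synonymous, 1, omega)
    list(to = nb$to, w = w, syn = nb$synonymous, total = sum(w))
  })
  names(per) <- tabs$sense
  z <- mean(vapply(per, `[[`, numeric(1), "total"))
  for (i in seq_along(per)) {
    per[[i]]$w <- per[[i]]$w / z
    per[[i]]$total <- per[[i]]$total / z
  }
  per
}

# Gillespie simulation of one codon site along a branch of effective length
# t, conditioned on at least one event: the first waiting time is drawn from
# the truncated exponential, subsequent ones unconditionally
sim_codon_site_active <- function(codon, t, rate_tabs) {
  events <- list()
  rt <- rate_tabs[[codon]]
  u <- stats::runif(1)
  time <- -log(1 - u * (1 - exp(-rt$total * t))) / rt$total
  repeat {
    to <- if (length(rt$to) == 1L) rt$to else sample(rt$to, 1, prob = rt$w)
    events[[length(events) + 1L]] <- c(from = codon, to = to)
    codon <- to
    rt <- rate_tabs[[codon]]
    if (rt$total <= 0) break
    time <- time + stats::rexp(1, rt$total)
    if (time > t) break
  }
  list(codon = codon, events = events)
}

#' Simulate sequence evolution along a tree with a full event log
#'
#' Amino mode evolves each site under a 20-state equal-exchangeability
#' (Poisson) process at rate `base_rate * scalar * branch length` per site.
#' Codon mode evolves sense codons under a Goldman-Yang-style omega/kappa
#' parameterization with uniform codon frequencies; proposals to stop codons
#' are excluded. Every substitution is logged with its branch, so ground
#' truth is available for recovery tests.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param scalars Named numeric vector of per-branch rate scalars (names are
#'   branch ids as in [branch_table()]); missing branches are an error.
#' @param length Number of sites (amino) or codons (codon mode).
#' @param mode `"amino"` or `"codon"`.
#' @param config An [simulation_config()] (supplies `base_rate`, `kappa` and,
#'   via `gene_set`, omega and the genetic code).
#' @param gene_set Label used to pick omega from `config$omega_by_geneset`
#'   and attached to the output alignment.
#' @param code Genetic code for codon mode (see [genetic_code()]).
#' @param seed Optional seed override; defaults to a sub-stream of
#'   `config$seed` keyed by `gene_set`.
#' @return List with `alignment` (an [mn_alignment] of tip sequences) and
#'   `truth` (list: `events` data.frame with columns gene, site, branch_id,
#'   depth, from, to; `root_seq`; `node_states` matrix).
#' @export
simulate_alignment <- function(tree, scalars, length, mode = c("amino", "codon"),
                               config = simulation_config(), gene_set = "mt",
                               code = "standard", seed = NULL) {
  mode <- match.arg(mode)
  if (length < 1) stop("length must be >= 1")
  bt <- branch_table(tree)
  ids <- as.character(bt$branch_id)
  if (!all(ids %in% names(scalars)))
    stop("missing scalar for branch(es): ",
         paste(setdiff(ids, names(scalars)), collapse = ", "))
  if (is.null(seed)) seed <- stage_seed(config$seed, paste0("alignment:", gene_set))
  set.seed(seed)
  eff_len <- stats::setNames(config$base_rate * scalars[ids] * bt$length, ids)
  n_tip <- ape::Ntip(tree)
  if (mode == "amino") {
    sim <- sim_amino_states(tree, as.list(eff_len), length)
    tipm <- sim$states[seq_len(n_tip), , drop = FALSE]
    rownames(tipm) <- tree$tip.label
    aln <- mn_alignment(tipm, molecule = "amino", gene_set = gene_set)
    ev <- sim$events
    ev$gene <- rep(gene_set, nrow(ev))
    return(list(alignment = aln,
                truth = list(events = ev[, c("gene", "site", "branch_id",
                                             "depth", "from", "to")],
                             root_seq = sim$root_seq, node_states = sim$states)))
  }
  # codon mode
  omega <- config$omega_by_geneset[[gene_set]]
  if (is.null(omega) || is.na(omega))
    stop("no omega configured for gene set ", gene_set)
  rate_tabs <- codon_rate_tables(omega, config$kappa, code)
  sense <- names(rate_tabs)
  root <- n_tip + 1L
  n_node <- max(tree$edge)
  states <- matrix(NA_character_, n_node, length)
  states[root, ] <- sample(sense, length, replace = TRUE)
  depth <- stats::setNames(bt$depth, ids)
  ev_site <- integer(0); ev_branch <- integer(0); ev_depth <- integer(0)
  ev_from <- character(0); ev_to <- character(0)
  tot_rate <- vapply(rate_tabs, `[[`, numeric(1), "total")
  for (e in reorder_preorder(tree)) {
    p <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    seq_v <- states[p, ]
    t_eff <- eff_len[[as.character(v)]]
    # thinning: only sites whose exponential clock fires enter the loop
    p_event <- 1 - exp(-tot_rate[seq_v] * t_eff)
    active <- which(stats::runif(length) < p_event)
    for (site in active) {
      res <- sim_codon_site_active(seq_v[site], t_eff, rate_tabs)
      for (x in res$events) {
        ev_site <- c(ev_site, site); ev_branch <- c(ev_branch, v)
        ev_depth <- c(ev_depth, depth[[as.character(v)]])
        ev_from <- c(ev_from, x[["from"]]); ev_to <- c(ev_to, x[["to"]])
      }
      seq_v[site] <- res$codon
    }
    states[v, ] <- seq_v
  }
  events <- data.frame(site = ev_site, branch_id = ev_branch,
                       depth = ev_depth, from = ev_from, to = ev_to,
                       gene = gene_set, stringsAsFactors = FALSE)
  tip_nuc <- t(apply(states[seq_len(n_tip), , drop = FALSE], 1,
                     function(row) unlist(strsplit(row, ""))))
  rownames(tip_nuc) <- tree$tip.label
  aln <- mn_alignment(tip_nuc, molecule = "codon", gene_set = gene_set)
  list(alignment = aln,
       truth = list(events = events[, c("gene", "site", "branch_id", "depth",
                                        "from", "to")],
                    root_seq = states[root, ], node_states = states))
}

#' Simulate compensatory mitonuclear contact pairs
#'
#' Each pair couples one mt site and one N-mt site. The designated trigger
#' site (set by `compensation_direction`) substitutes at the baseline rate;
#' once it substitutes on a lineage, the partner's substitution rate on the
#' remainder of that lineage is multiplied by `compensation_boost_beta` until
#' the partner substitutes. With `direction = "none"` or `beta = 1` the two
#' processes are independent. The true per-pair ordering label (mt_first /
#' nmt_first / same_branch, by branch depth along shared root-to-tip paths)
#' is recorded.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param n_pairs Number of contact pairs (>= 1).
#' @param config An [simulation_config()].
#' @return List with `mt_alignment`, `nmt_alignment` (amino [mn_alignment]s,
#'   pair i at column i of each) and `truth` (list: `events` data.frame with
#'   pair_id, gene, genome, site, branch_id, depth, time, from, to; `labels`
#'   data.frame with pair_id, label).
#' @export
simulate_compensatory_pairs <- function(tree, n_pairs, config = simulation_config()) {
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  set.seed(stage_seed(config$seed, "pairs"))
  beta <- config$compensation_boost_beta
  dir <- config$compensation_direction
  mu <- config$base_rate
  n_tip <- ape::Ntip(tree)
  root <- n_tip + 1L
  n_node <- max(tree$edge)
  bt <- branch_table(tree)
  depth <- stats::setNames(bt$depth, as.character(bt$branch_id))
  # node start times (distance from root)
  node_time <- numeric(n_node)
  pre <- reorder_preorder(tree)
  for (e in pre) {
    p <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    node_time[v] <- (if (p == root) 0 else node_time[p]) + tree$edge.length[e]
  }
  mt_states <- matrix(NA_character_, n_node, n_pairs)
  nmt_states <- matrix(NA_character_, n_node, n_pairs)
  mt_states[root, ] <- sample(AMINO_ACIDS, n_pairs, replace = TRUE)
  nmt_states[root, ] <- sample(AMINO_ACIDS, n_pairs, replace = TRUE)
  # boosted[node, pair]: does the boost apply at the start of branches below?
  boosted <- matrix(FALSE, n_node, n_pairs)
  ev_pair <- integer(0); ev_mt <- logical(0); ev_branch <- integer(0)
  ev_depth <- integer(0); ev_time <- numeric(0)
  ev_from <- character(0); ev_to <- character(0)
  for (e in pre) {
    p <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    len <- tree$edge.length[e]
    mt_v <- mt_states[p, ]; nmt_v <- nmt_states[p, ]
    boost_v <- boosted[p, ]
    t0 <- if (p == root) 0 else node_time[p]
    trig_is_mt <- (dir != "n_triggers_mt")  # for "none", boost is never set
    for (i in seq_len(n_pairs)) {
      t <- 0
      # boost state at branch start comes from the parent; a trigger event
      # arms the boost for descendant branches only (pending), while a
      # partner substitution switches any boost off immediately
      active <- boost_v[i]
      pending <- FALSE
      repeat {
        r_mt <- mu * (if (!trig_is_mt && active) beta else 1)
        r_nmt <- mu * (if (trig_is_mt && active) beta else 1)
        tot <- r_mt + r_nmt
        t <- t + stats::rexp(1, tot)
        if (t > len) break
        is_mt <- stats::runif(1) < r_mt / tot
        if (is_mt) {
          from <- mt_v[i]
          mt_v[i] <- sample(setdiff(AMINO_ACIDS, from), 1)
          to <- mt_v[i]
        } else {
          from <- nmt_v[i]
          nmt_v[i] <- sample(setdiff(AMINO_ACIDS, from), 1)
          to <- nmt_v[i]
        }
        if (dir != "none") {
          if (is_mt == trig_is_mt) pending <- TRUE
          else { active <- FALSE; pending <- FALSE }
        }
        ev_pair <- c(ev_pair, i); ev_mt <- c(ev_mt, is_mt)
        ev_branch <- c(ev_branch, v)
        ev_depth <- c(ev_depth, depth[[as.character(v)]])
        ev_time <- c(ev_time, t0 + t)
        ev_from <- c(ev_from, from); ev_to <- c(ev_to, to)
      }
      boost_v[i] <- active || pending
    }
    mt_states[v, ] <- mt_v
    nmt_states[v, ] <- nmt_v
    boosted[v, ] <- boost_v
  }
  events <- data.frame(
    pair_id = ev_pair, gene = ifelse(ev_mt, "mt_sim", "nmt_sim"),
    genome = ifelse(ev_mt, "mt", "nuclear"), site = ev_pair,
    branch_id = ev_branch, depth = ev_depth, time = ev_time,
    from = ev_from, to = ev_to, stringsAsFactors = FALSE)
  labels <- true_pair_labels(events, tree, n_pairs)
  mt_tip <- mt_states[seq_len(n_tip), , drop = FALSE]
  nmt_tip <- nmt_states[seq_len(n_tip), , drop = FALSE]
  rownames(mt_tip) <- rownames(nmt_tip) <- tree$tip.label
  list(mt_alignment = mn_alignment(mt_tip, "amino", gene_set = "mt_sim"),
       nmt_alignment = mn_alignment(nmt_tip, "amino", gene_set = "nmt_sim"),
       truth = list(events = events, labels = labels))
}

# ground-truth ordering labels from the simulator's own event log: per
# root-to-tip path containing events at both partners, compare the depths of
# the shallowest events; majority over paths, ties broken by absolute time
true_pair_labels <- function(events, tree, n_pairs) {
  paths <- tip_branch_paths(tree)
  out <- data.frame(pair_id = seq_len(n_pairs),
                    label = rep("unresolved", n_pairs),
                    stringsAsFactors = FALSE)
  for (i in seq_len(n_pairs)) {
    evi <- events[events$pair_id == i, ]
    if (!nrow(evi)) next
    votes <- c(mt_first = 0L, nmt_first = 0L, same_branch = 0L)
    for (path in paths) {
      mt_on <- evi[evi$genome == "mt" & evi$branch_id %in% path, ]
      nmt_on <- evi[evi$genome == "nuclear" & evi$branch_id %in% path, ]
      if (!nrow(mt_on) || !nrow(nmt_on)) next
      dm <- min(mt_on$depth); dn <- min(nmt_on$depth)
      lbl <- if (dm == dn) "same_branch" else if (dm < dn) "mt_first" else "nmt_first"
      votes[lbl] <- votes[lbl] + 1L
    }
    if (sum(votes) == 0L) next
    if (votes["mt_first"] != votes["nmt_first"]) {
      out$label[i] <- if (votes["mt_first"] > votes["nmt_first"]) "mt_first" else "nmt_first"
    } else if (votes["mt_first"] == 0L) {
      out$label[i] <- "same_branch"
    } else {
      # exact vote tie: fall back to the true first event times
      tmt <- min(evi$time[evi$genome == "mt"])
      tnmt <- min(evi$time[evi$genome == "nuclear"])
      out$label[i] <- if (tmt < tnmt) "mt_first" else "nmt_first"
    }
  }
  out
}

#' Write a simulation truth log as TSV
#'
#' @param truth Truth list from [simulate_alignment()] or
#'   [simulate_compensatory_pairs()].
#' @param path Output path.
#' @export
write_truth_tsv <- function(truth, path) {
  utils::write.table(truth$events, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
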