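# End-to-end orchestration from one YAML config: synthetic data generation,
# rate estimation, ERC, dN/dS, ordering and selection stages, TSV outputs.

pipeline_defaults <- function() {
  list(
    seed = 1L,
    output_dir = NULL,
    synthetic = list(n_taxa = 30L, seq_length = 200L, rho_target = 0.8,
                     rho_control = 0.0, scalar_sd = 0.3, lineage_sd = 0.3,
                     base_rate = 0.1, kappa = 2,
                     omega = list(mt = 0.06, nmt_oxphos = 0.16,
                                  glycolysis = 0.07),
                     n_pairs = 150L, contact_site_rate = 0.03,
                     compensation_boost_beta = 1,
                     compensation_direction = "none"),
    stages = list(erc = TRUE, dnds = TRUE, ordering = TRUE, selection = TRUE),
    erc = list(n_boot = 2000L, rate_method = "ml", n_background_genes = 30L),
    dnds = list(n_genes_per_set = 4L, n_codons = 120L),
    ordering = list(max_close_separation = 2L),
    selection = list(alpha = 0.05, stringent_alpha = 0.01),
    printed_counts = NULL)
}

merge_config <- function(defaults, user) {
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && is.list(user[[k]]))
      defaults[[k]] <- merge_config(defaults[[k]], user[[k]])
    else defaults[[k]] <- user[[k]]
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Reads a YAML config (or takes a list), fills documented defaults, and
#' either returns the resolved config or raises one error listing every
#' violation found.
#'
#' @param path Path to a YAML file, or a list of settings.
#' @return List of class `mn_config`.
#' @export
validate_config <- function(path) {
  user <- if (is.character(path)) {
    if (!file.exists(path)) stop("config file not found: ", path)
    yaml::read_yaml(path)
  } else if (is.list(path)) path else stop("path must be a file path or list")
  if (is.null(user)) user <- list()
  cfg <- merge_config(pipeline_defaults(), user)
  errs <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) errs <<- c(errs, msg)
  chk(is.numeric(cfg$seed) && cfg$seed == round(cfg$seed), "seed must be an integer")
  s <- cfg$synthetic
  chk(s$n_taxa >= 2, "synthetic.n_taxa must be >= 2")
  chk(s$seq_length >= 1, "synthetic.seq_length must be >= 1")
  chk(abs(s$rho_target) <= 1, "synthetic.rho_target must be in [-1, 1]")
  chk(abs(s$rho_control) <= 1, "synthetic.rho_control must be in [-1, 1]")
  chk(s$scalar_sd >= 0, "synthetic.scalar_sd must be >= 0")
  chk(s$base_rate >= 0, "synthetic.base_rate must be >= 0")
  chk(s$contact_site_rate >= 0, "synthetic.contact_site_rate must be >= 0")
  chk(s$compensation_boost_beta >= 1,
      "synthetic.compensation_boost_beta must be >= 1")
  chk(s$compensation_direction %in% c("none", "mt_triggers_n", "n_triggers_mt"),
      "synthetic.compensation_direction invalid")
  chk(cfg$erc$n_boot >= 2, "erc.n_boot must be >= 2")
  chk(cfg$erc$rate_method %in% c("ml", "counts"), "erc.rate_method must be ml or counts")
  chk(cfg$selection$alpha > 0 && cfg$selection$alpha < 1,
      "selection.alpha must be in (0, 1)")
  if (!is.null(cfg$printed_counts))
    chk(all(c("mt_first", "nmt_first") %in% names(cfg$printed_counts)),
        "printed_counts needs mt_first and nmt_first")
  if (length(errs)) stop("invalid config:\n  - ", paste(errs, collapse = "\n  - "))
  cfg$seed <- as.integer(cfg$seed)
  class(cfg) <- "mn_config"
  cfg
}

# per-branch log scalars for a family of gene sets: a lineage-wide effect
# shared by every set plus set-specific components, with the mt component
# coupled at set-specific rho to each target. Background halves are
# concatenations of many independent orthologs, so their set-specific
# deviation shrinks by sqrt(genes per half).
geneset_scalars <- function(tree, cfg) {
  s <- cfg$synthetic
  bt <- branch_table(tree)
  n <- nrow(bt)
  set.seed(stage_seed(cfg$seed, "geneset_scalars"))
  lineage <- stats::rnorm(n, 0, s$lineage_sd)
  z_mt <- stats::rnorm(n)
  mk <- function(rho, sd = s$scalar_sd) {
    z <- rho * z_mt + sqrt(1 - rho^2) * stats::rnorm(n)
    exp(lineage + sd * z)
  }
  bg_sd <- s$scalar_sd / sqrt(max(1, cfg$erc$n_background_genes / 2))
  out <- list(mt = exp(lineage + s$scalar_sd * z_mt),
              nmt = mk(s$rho_target),
              control = mk(s$rho_control),
              nrand1 = mk(0, bg_sd),
              nrand2 = mk(0, bg_sd))
  lapply(out, function(x) stats::setNames(x, as.character(bt$branch_id)))
}

#' Star phylogeny of independent lineages
#'
#' A rooted star tree with unit branch lengths: every taxon is an
#' independent lineage sharing no branches, the exchangeable-sample setting
#' under which taxon-level correlation calibrations are well defined.
#'
#' @param n_taxa Number of tips (>= 2).
#' @return A `phylo` object.
#' @export
star_tree <- function(n_taxa) {
  if (n_taxa < 2) stop("n_taxa must be >= 2")
  tips <- sprintf("s%02d", seq_len(n_taxa))
  txt <- paste0("(", paste0(tips, ":1", collapse = ","), "):0;")
  ape::read.tree(text = txt)
}

# root-to-tip rates for one gene set: "ml" re-estimates branch lengths from
# a simulated alignment; "counts" draws the realized per-branch substitution
# counts directly (the same Poisson process as the event log, without
# building sequences — used for large calibration sweeps)
rates_for_set <- function(tree, scalars, set, cfg) {
  n_sites <- cfg$synthetic$seq_length
  sim_cfg <- simulation_config(
    n_taxa = ape::Ntip(tree), seq_length = n_sites,
    scalar_sd = cfg$synthetic$scalar_sd, base_rate = cfg$synthetic$base_rate,
    kappa = cfg$synthetic$kappa, seed = cfg$seed)
  if (cfg$erc$rate_method == "counts") {
    rates <- simulate_tip_rate_counts(tree, scalars, n_sites,
                                      cfg$synthetic$base_rate,
                                      seed = stage_seed(cfg$seed,
                                                        paste0("counts:", set)),
                                      gene_set = set)
    return(list(rates = rates, alignment = NULL, truth = NULL))
  }
  sim <- simulate_alignment(tree, scalars, n_sites, mode = "amino",
                            config = sim_cfg, gene_set = set)
  topo <- tree
  topo$edge.length <- NULL
  fit <- estimate_branch_lengths(sim$alignment, topo, model = "poisson",
                                 tol = 1e-4)
  list(rates = root_to_tip_distances(fit, gene_set = set),
       alignment = sim$alignment, truth = sim$truth)
}

#' Realized root-to-tip rates by direct Poisson branch counts
#'
#' Draws the number of substitutions per branch from the same Poisson
#' counting process the sequence simulator logs (`rate = base_rate * scalar
#' * branch length` per site) and sums counts along each tip's root path,
#' divided by the site count. Distributionally identical to replaying an
#' event log from [simulate_alignment()], without building sequences.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param scalars Named per-branch scalars (names = branch ids).
#' @param n_sites Number of sites.
#' @param base_rate Substitutions per site per unit branch length.
#' @param seed Integer seed.
#' @param gene_set Label for the result.
#' @return An `mn_rates` vector.
#' @export
simulate_tip_rate_counts <- function(tree, scalars, n_sites, base_rate, seed,
                                     gene_set = NA_character_) {
  bt <- branch_table(tree)
  set.seed(seed)
  lam <- base_rate * as.numeric(scalars[as.character(bt$branch_id)]) *
    bt$length * n_sites
  counts <- stats::setNames(stats::rpois(nrow(bt), lam), bt$branch_id)
  paths <- tip_branch_paths(tree)
  out <- vapply(paths, function(p) sum(counts[as.character(p)]) / n_sites,
                numeric(1))
  names(out) <- tree$tip.label
  structure(out, gene_set = gene_set, class = "mn_rates")
}

#' Realized per-tip substitution rates from a truth log
#'
#' Counts the logged substitutions along each tip's root path and divides by
#' the number of sites: the realized root-to-tip rate, the generator-side
#' counterpart of [root_to_tip_distances()] on an estimated tree.
#'
#' @param events Truth event data.frame (columns `branch_id`, `site`).
#' @param tree The simulated tree.
#' @param n_sites Number of sites simulated.
#' @param gene_set Label for the result.
#' @return An `mn_rates` vector.
#' @export
realized_tip_rates <- function(events, tree, n_sites, gene_set = NA_character_) {
  paths <- tip_branch_paths(tree)
  per_branch <- table(factor(events$branch_id, levels = seq_len(max(tree$edge))))
  out <- vapply(paths, function(p) sum(per_branch[as.character(p)]) / n_sites,
                numeric(1))
  names(out) <- tree$tip.label
  structure(out, gene_set = gene_set, class = "mn_rates")
}

#' Run the ERC stage of the pipeline
#'
#' Generates (or reuses) the synthetic tree and gene-set alignments,
#' estimates per-taxon root-to-tip rates, normalizes the mt set by the
#' first background half and every nuclear target by the second half
#' (never the same half — asserted), and computes Spearman ERCs plus the
#' bootstrap BCa difference between the mt-coupled target and the control
#' set.
#'
#' @param config An `mn_config` from [validate_config()] (or a list/path,
#'   validated on the fly).
#' @return List: `erc_table` (data.frame per gene set), `difference`
#'   (`mn_erc_diff` for N-mt vs control), `rates` (list of `mn_rates`),
#'   `tree`, `pic` (phylogenetic contrasts correlation for the N-mt set).
#' @export
run_erc_pipeline <- function(config) {
  cfg <- if (inherits(config, "mn_config")) config else validate_config(config)
  tree <- generate_yule_tree(cfg$synthetic$n_taxa, cfg$seed)
  sc <- geneset_scalars(tree, cfg)
  sets <- list()
  for (set in names(sc)) sets[[set]] <- rates_for_set(tree, sc[[set]], set, cfg)
  norm_mt <- normalize_rates(sets$mt$rates, sets$nrand1$rates)
  stopifnot(!identical(attr(sets$nrand1$rates, "gene_set"),
                       attr(sets$nrand2$rates, "gene_set")))
  norm_nmt <- normalize_rates(sets$nmt$rates, sets$nrand2$rates)
  norm_ctl <- normalize_rates(sets$control$rates, sets$nrand2$rates)
  erc_nmt <- spearman_erc(norm_mt, norm_nmt, n_boot = cfg$erc$n_boot,
                          seed = stage_seed(cfg$seed, "erc_nmt"))
  erc_ctl <- spearman_erc(norm_mt, norm_ctl, n_boot = cfg$erc$n_boot,
                          seed = stage_seed(cfg$seed, "erc_ctl"))
  diff <- bootstrap_difference(norm_mt, norm_nmt, norm_ctl,
                               n_boot = cfg$erc$n_boot,
                               seed = stage_seed(cfg$seed, "erc_diff"))
  pic_res <- pic_correlation(tree, norm_mt, norm_nmt)
  erc_table <- data.frame(
    target = c("nmt", "control"),
    r_s = c(erc_nmt$r_s, erc_ctl$r_s),
    ci_lo = c(erc_nmt$ci_lo, erc_ctl$ci_lo),
    ci_hi = c(erc_nmt$ci_hi, erc_ctl$ci_hi),
    n = c(erc_nmt$n, erc_ctl$n))
  out <- list(erc_table = erc_table, difference = diff,
              rates = lapply(sets, `[[`, "rates"), tree = tree, pic = pic_res,
              normalized = list(mt = norm_mt, nmt = norm_nmt, control = norm_ctl))
  maybe_write(out$erc_table, cfg, "erc_table.tsv")
  out
}

#' Run the substitution-ordering stage of the pipeline
#'
#' With `printed_counts` set in the config, computes the ordering chi-square
#' directly from externally obtained (mt_first, nmt_first) counts. Otherwise
#' simulates compensatory contact pairs, reconstructs ancestral states
#' (Fitch), maps substitutions, classifies each pair, and runs the
#' chi-square and the close-vs-far Fisher test.
#'
#' @inheritParams run_erc_pipeline
#' @return List: `records` (per-pair classifications), `counts`, `chisq`
#'   (`mn_ordering_test`), `fisher_close_far`, `branch_summary`, `truth`
#'   (simulator ground truth), `proportions`.
#' @export
run_ordering_pipeline <- function(config) {
  cfg <- if (inherits(config, "mn_config")) config else validate_config(config)
  if (!is.null(cfg$printed_counts)) {
    a <- cfg$printed_counts$mt_first; b <- cfg$printed_counts$nmt_first
    test <- chisq_equal_order(a, b)
    return(list(counts = c(mt_first = a, nmt_first = b), chisq = test,
                proportions = c(mt_first = a / (a + b), nmt_first = b / (a + b)),
                records = NULL, truth = NULL))
  }
  s <- cfg$synthetic
  tree <- generate_yule_tree(s$n_taxa, cfg$seed)
  sim_cfg <- simulation_config(
    n_taxa = s$n_taxa, base_rate = s$contact_site_rate, scalar_sd = s$scalar_sd,
    compensation_boost_beta = s$compensation_boost_beta,
    compensation_direction = s$compensation_direction, seed = cfg$seed)
  sim <- simulate_compensatory_pairs(tree, s$n_pairs, sim_cfg)
  mt_states <- reconstruct_ancestral(sim$mt_alignment, tree)
  nmt_states <- reconstruct_ancestral(sim$nmt_alignment, tree)
  mt_ev <- map_substitutions(mt_states, tree, gene = "mt_sim", genome = "mt")
  nmt_ev <- map_substitutions(nmt_states, tree, gene = "nmt_sim",
                              genome = "nuclear")
  records <- do.call(rbind, lapply(seq_len(s$n_pairs), function(i)
    classify_pair_order(mt_ev, nmt_ev,
                        list(pair_id = i, mt_column = i, nmt_column = i), tree)))
  n_mt <- sum(records$classification == "mt_first")
  n_nmt <- sum(records$classification == "nmt_first")
  test <- if (n_mt + n_nmt >= 1) chisq_equal_order(n_mt, n_nmt) else NULL
  close_tab <- with(records[records$classification %in% c("mt_first", "nmt_first"), ],
                    table(factor(proximity, levels = c("close", "far")),
                          factor(classification, levels = c("mt_first", "nmt_first"))))
  fisher_cf <- if (all(dim(close_tab) == 2))
    fisher_mtfirst_enrichment(matrix(close_tab, 2, 2,
                                     dimnames = dimnames(close_tab))) else NULL
  branch_summary <- branch_substitution_summary(rbind(mt_ev, nmt_ev), tree)
  out <- list(records = records,
              counts = c(mt_first = n_mt, nmt_first = n_nmt,
                         same_branch = sum(records$classification == "same_branch"),
                         unresolved = sum(records$classification == "unresolved")),
              chisq = test, fisher_close_far = fisher_cf,
              branch_summary = branch_summary, truth = sim$truth,
              proportions = if (n_mt + n_nmt > 0)
                c(mt_first = n_mt / (n_mt + n_nmt),
                  nmt_first = n_nmt / (n_mt + n_nmt)) else NULL,
              tree = tree, events = rbind(mt_ev, nmt_ev))
  maybe_write(out$records, cfg, "ordering_records.tsv")
  maybe_write(out$branch_summary, cfg, "branch_substitutions.tsv")
  out
}

# dN/dS stage: per-gene synthetic codon alignments per gene set, NG86
# estimates, ANOVA + Tukey comparisons
run_dnds_stage <- function(cfg, tree) {
  s <- cfg$synthetic
  omega <- unlist(s$omega)
  sim_cfg <- simulation_config(
    n_taxa = s$n_taxa, base_rate = s$base_rate, kappa = s$kappa,
    omega_by_geneset = omega, seed = cfg$seed)
  bt <- branch_table(tree)
  flat <- stats::setNames(rep(1, nrow(bt)), as.character(bt$branch_id))
  omegas <- c(); groups <- c()
  genes <- list()
  for (set in names(omega)) {
    for (g in seq_len(cfg$dnds$n_genes_per_set)) {
      gene <- sprintf("%s_g%d", set, g)
      code <- if (set == "mt") "vertebrate_mito" else "standard"
      sim <- simulate_alignment(
        tree, flat, cfg$dnds$n_codons, mode = "codon", config = sim_cfg,
        gene_set = set, code = code,
        seed = stage_seed(cfg$seed, paste0("dnds:", gene)))
      est <- geneset_dnds(sim$alignment, code = code)
      omegas[gene] <- est$omega
      groups[gene] <- set
      genes[[gene]] <- est
    }
  }
  comp <- compare_groups(omegas, groups)
  list(omega_by_gene = omegas, groups = groups, comparisons = comp,
       estimates = genes)
}

# selection stage: site scans of one mt and one nmt codon gene, pooled
# proportions and mt-vs-nmt enrichment of selected sites
run_selection_stage <- function(cfg, tree) {
  s <- cfg$synthetic
  omega <- unlist(s$omega)
  sim_cfg <- simulation_config(
    n_taxa = s$n_taxa, base_rate = s$base_rate, kappa = s$kappa,
    omega_by_geneset = omega, seed = cfg$seed)
  bt <- branch_table(tree)
  flat <- stats::setNames(rep(1, nrow(bt)), as.character(bt$branch_id))
  scans <- list()
  for (set in intersect(c("mt", "nmt_oxphos"), names(omega))) {
    code <- if (set == "mt") "vertebrate_mito" else "standard"
    sim <- simulate_alignment(tree, flat, cfg$dnds$n_codons, mode = "codon",
                              config = sim_cfg, gene_set = set, code = code,
                              seed = stage_seed(cfg$seed, paste0("sel:", set)))
    scans[[set]] <- scan_site_selection(
      sim$alignment, tree, gene = set, alpha = cfg$selection$alpha,
      stringent_alpha = cfg$selection$stringent_alpha, code = code)
  }
  all_scan <- do.call(rbind, scans)
  prop <- stats::aggregate(selected ~ gene, data = all_scan, FUN = mean)
  enrich <- if (length(scans) == 2) {
    is_nmt <- all_scan$gene != "mt"
    contact_enrichment(all_scan$selected, is_nmt)
  } else NULL
  list(scan = all_scan, proportions = prop, nmt_vs_mt = enrich)
}

#' Run the full analysis
#'
#' Composes the enabled stages (ERC, dN/dS, ordering, selection) into one
#' report; every table is also written as TSV when `output_dir` is set.
#'
#' @inheritParams run_erc_pipeline
#' @return List of class `mn_report` with sections `erc`, `dnds`,
#'   `ordering`, `selection` (enabled stages only) and `metadata`.
#' @export
run_full_analysis <- function(config) {
  cfg <- if (inherits(config, "mn_config")) config else validate_config(config)
  report <- list()
  tree <- generate_yule_tree(cfg$synthetic$n_taxa, cfg$seed)
  if (isTRUE(cfg$stages$erc)) report$erc <- run_erc_pipeline(cfg)
  if (isTRUE(cfg$stages$dnds)) report$dnds <- run_dnds_stage(cfg, tree)
  if (isTRUE(cfg$stages$ordering)) report$ordering <- run_ordering_pipeline(cfg)
  if (isTRUE(cfg$stages$selection)) report$selection <- run_selection_stage(cfg, tree)
  report$metadata <- list(
    package_version = as.character(utils::packageVersion("mitonuc")),
    seed = cfg$seed,
    stage_seeds = vapply(c("tree", "geneset_scalars", "pairs", "erc_diff"),
                         function(s) stage_seed(cfg$seed, s), integer(1)),
    timestamp = format(Sys.time(), tz = "UTC"),
    stages = names(report))
  if (isTRUE(cfg$stages$dnds))
    maybe_write(report$dnds$comparisons, cfg, "dnds_comparisons.tsv")
  class(report) <- "mn_report"
  report
}

maybe_write <- function(df, cfg, name) {
  if (is.null(cfg$output_dir) || is.null(df)) return(invisible(NULL))
  dir.create(cfg$output_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.table(df, file.path(cfg$output_dir, name), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(NULL)
}
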