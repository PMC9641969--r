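# Evolutionary rate covariation: background normalization, Spearman
# correlations, bootstrap BCa difference tests, and a phylogenetically
# corrected (independent-contrasts) correlation.

#' Split background ortholog genes into two normalization halves
#'
#' Seeded uniform shuffle, then halving (sizes differ by at most 1). By
#' construction the first half (`nrand1`) is designated to normalize the mt
#' gene set and the second half (`nrand2`) the nuclear target sets, so a
#' target is never normalized by the same genes as the mt set
#' (anti-autocorrelation).
#'
#' @param genes Character vector of >= 2 gene names.
#' @param seed Integer seed.
#' @return List with elements `nrand1` and `nrand2`.
#' @export
split_random_orthologs <- function(genes, seed) {
  if (length(genes) < 2) stop("need at least 2 genes to split")
  set.seed(stage_seed(seed, "ortholog_split"))
  shuffled <- sample(genes)
  k <- ceiling(length(genes) / 2)
  list(nrand1 = shuffled[seq_len(k)], nrand2 = shuffled[-seq_len(k)])
}

#' Normalize target rates by background rates
#'
#' Divides each taxon's target root-to-tip rate by its background rate,
#' removing lineage-wide effects (demography, generation time, mutation
#' rate) so that residual covariation reflects gene-set-specific
#' coevolution. Taxa with background 0 are dropped with a warning.
#'
#' @param target,background [root_to_tip_distances()] vectors (`mn_rates`).
#' @return An `mn_rates` vector of dimensionless ratios over shared taxa.
#' @export
normalize_rates <- function(target, background) {
  shared <- intersect(names(target), names(background))
  if (!length(shared)) stop("no shared taxa between target and background")
  bg <- as.numeric(background[shared])
  zero <- bg <= 0
  if (any(zero)) {
    warning("dropping taxa with zero background rate: ",
            paste(shared[zero], collapse = ", "))
    shared <- shared[!zero]
    bg <- bg[!zero]
  }
  if (!length(shared)) stop("no taxa with positive background rate")
  structure(as.numeric(target[shared]) / bg, names = shared,
            gene_set = attr(target, "gene_set"), class = "mn_rates")
}

#' Spearman rank correlation between two normalized rate vectors
#'
#' @param x,y `mn_rates` vectors; computed over shared taxa (>= 3). Ties
#'   receive average ranks.
#' @param n_boot If > 0, a percentile bootstrap CI on r_s from this many
#'   paired-taxon resamples.
#' @param seed Seed for the bootstrap.
#' @return List of class `mn_erc` with `r_s`, `n`, `method`, `ci_lo`, `ci_hi`.
#' @export
spearman_erc <- function(x, y, n_boot = 0L, seed = 1L) {
  shared <- intersect(names(x), names(y))
  if (length(shared) < 3) stop("need at least 3 shared taxa")
  xv <- as.numeric(x[shared]); yv <- as.numeric(y[shared])
  if (stats::sd(rank(xv)) == 0 || stats::sd(rank(yv)) == 0)
    stop("degenerate input: constant ranks")
  r_s <- stats::cor(xv, yv, method = "spearman")
  ci <- c(NA_real_, NA_real_)
  if (n_boot > 0) {
    set.seed(stage_seed(seed, "spearman_ci"))
    reps <- replicate(n_boot, {
      i <- sample.int(length(xv), replace = TRUE)
      suppressWarnings(stats::cor(xv[i], yv[i], method = "spearman"))
    })
    ci <- stats::quantile(reps[!is.na(reps)], c(0.025, 0.975), names = FALSE)
  }
  structure(list(r_s = r_s, n = length(shared), method = "spearman",
                 ci_lo = ci[1], ci_hi = ci[2]), class = "mn_erc")
}

#' @export
print.mn_erc <- function(x, ...) {
  cat(sprintf("ERC (%s): r_s = %.3f, n = %d", x$method, x$r_s, x$n))
  if (!is.na(x$ci_lo)) cat(sprintf(", 95%% CI = %.3f..%.3f", x$ci_lo, x$ci_hi))
  cat("\n")
  invisible(x)
}

# BCa interval from bootstrap replicates + jackknife values
bca_interval <- function(reps, theta_hat, jack, conf = 0.95) {
  reps <- reps[is.finite(reps)]
  z0 <- stats::qnorm(mean(reps < theta_hat))
  if (!is.finite(z0)) z0 <- 0
  jm <- mean(jack)
  num <- sum((jm - jack)^3)
  den <- 6 * sum((jm - jack)^2)^1.5
  a <- if (den == 0) 0 else num / den
  alpha <- (1 - conf) / 2
  zlo <- stats::qnorm(alpha); zhi <- stats::qnorm(1 - alpha)
  p_lo <- stats::pnorm(z0 + (z0 + zlo) / (1 - a * (z0 + zlo)))
  p_hi <- stats::pnorm(z0 + (z0 + zhi) / (1 - a * (z0 + zhi)))
  stats::quantile(reps, c(p_lo, p_hi), names = FALSE, type = 6)
}

#' Bootstrap BCa test for a difference of rate correlations
#'
#' Tests whether the correlation of mt rates with gene set A differs from the
#' correlation of mt rates with gene set B. Taxa are resampled with
#' replacement jointly (paired rows); each replicate recomputes
#' `r_s(mt, A) - r_s(mt, B)`; the bias-corrected and accelerated (BCa)
#' interval uses the bias correction z0 (fraction of replicates below the
#' point estimate) and acceleration from the leave-one-taxon-out jackknife.
#' A difference is "statistically robust" when the CI excludes 0.
#'
#' @param mt,setA,setB `mn_rates` vectors with >= 4 shared taxa.
#' @param n_boot Bootstrap replicates (default 10000; must be >= 2).
#' @param seed Integer seed.
#' @param conf Confidence level (default 0.95).
#' @return List of class `mn_erc_diff`: `delta_r_s`, `ci_lo`, `ci_hi`,
#'   `n_boot`, `n_dropped` (degenerate replicates), `ci_type = "bca"`.
#' @export
bootstrap_difference <- function(mt, setA, setB, n_boot = 10000L, seed = 1L,
                                 conf = 0.95) {
  if (n_boot < 2) stop("n_boot must be >= 2 for a CI")
  shared <- Reduce(intersect, list(names(mt), names(setA), names(setB)))
  if (length(shared) < 4) stop("need at least 4 shared taxa")
  m <- cbind(mt = as.numeric(mt[shared]), a = as.numeric(setA[shared]),
             b = as.numeric(setB[shared]))
  stat <- function(rows) {
    rm_ <- rank(m[rows, 1L]); ra <- rank(m[rows, 2L]); rb <- rank(m[rows, 3L])
    if (rm_[which.max(rm_)] == rm_[which.min(rm_)] ||
        ra[which.max(ra)] == ra[which.min(ra)] ||
        rb[which.max(rb)] == rb[which.min(rb)]) return(NA_real_)
    stats::cor(rm_, ra) - stats::cor(rm_, rb)
  }
  n <- length(shared)
  theta_hat <- stat(seq_len(n))
  if (is.na(theta_hat)) stop("degenerate input: constant ranks")
  set.seed(stage_seed(seed, "bootstrap_difference"))
  reps <- vapply(seq_len(n_boot), function(i)
    stat(sample.int(n, replace = TRUE)), numeric(1))
  n_drop <- sum(is.na(reps))
  if (n_drop > 0.1 * n_boot)
    stop(sprintf("%d of %d bootstrap replicates degenerate", n_drop, n_boot))
  jack <- vapply(seq_len(n), function(i) stat(setdiff(seq_len(n), i)), numeric(1))
  jack <- jack[!is.na(jack)]
  ci <- bca_interval(reps[!is.na(reps)], theta_hat, jack, conf = conf)
  structure(list(delta_r_s = theta_hat, ci_lo = ci[1], ci_hi = ci[2],
                 n_boot = n_boot, n_dropped = n_drop, ci_type = "bca",
                 n = n, conf = conf),
            class = "mn_erc_diff")
}

#' @export
print.mn_erc_diff <- function(x, ...) {
  cat(sprintf("delta r_s = %.3f, %d%% BCa CI = %.3f..%.3f (n_boot = %d)\n",
              x$delta_r_s, round(100 * x$conf), x$ci_lo, x$ci_hi, x$n_boot))
  invisible(x)
}

#' Phylogenetically corrected rate correlation (independent contrasts)
#'
#' Felsenstein independent contrasts of the two normalized rate vectors on
#' the given tree, correlated by Pearson correlation through the origin.
#' Stands in for an unspecified "phylogenetic correlation test": shared
#' ancestry is removed by the contrasts. Zero-length internal branches are
#' floored at a small epsilon with a warning.
#'
#' @param tree Rooted `phylo` whose tips cover the shared taxa of `x`, `y`.
#' @param x,y `mn_rates` vectors.
#' @param eps Branch-length floor.
#' @return `mn_erc` list with `method = "pic"` and `n` = number of contrasts.
#' @export
pic_correlation <- function(tree, x, y, eps = 1e-8) {
  shared <- intersect(names(x), names(y))
  shared <- intersect(shared, tree$tip.label)
  if (length(shared) < 3) stop("need at least 3 shared taxa on the tree")
  tr <- ape::keep.tip(tree, shared)
  if (any(tr$edge.length <= 0)) {
    warning("flooring non-positive branch lengths at eps")
    tr$edge.length[tr$edge.length <= 0] <- eps
  }
  cx <- ape::pic(as.numeric(x[tr$tip.label]), tr)
  cy <- ape::pic(as.numeric(y[tr$tip.label]), tr)
  r <- sum(cx * cy) / sqrt(sum(cx^2) * sum(cy^2))
  structure(list(r_s = r, n = length(cx), method = "pic",
                 ci_lo = NA_real_, ci_hi = NA_real_), class = "mn_erc")
}
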