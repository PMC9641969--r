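# Gene-wise dN/dS by Nei-Gojobori (1986) counting with Jukes-Cantor
# correction, and the group comparisons used on the gene-wise estimates.

#' Pairwise dN/dS between two codon sequences (NG86)
#'
#' Nei-Gojobori fractional site counting (stop-codon mutations excluded from
#' site denominators), averaged over the two sequences; codon differences at
#' more than one position are resolved by averaging over minimal mutational
#' pathways, excluding pathways that pass through a stop codon. Proportions
#' are corrected with the Jukes-Cantor distance
#' `d = -(3/4) log(1 - (4/3) p)`. Codons containing gaps or ambiguity in
#' either sequence are skipped.
#'
#' @param seqA,seqB Character strings (or character vectors of single
#'   nucleotides) of equal length divisible by 3.
#' @param code Genetic code (see [genetic_code()]).
#' @return List of class `mn_dnds`: `N`, `S` (site counts), `Nd`, `Sd`
#'   (difference counts), `d_N`, `d_S`, `omega` (NA when `d_S` is 0),
#'   `saturated` (TRUE when a JC correction is undefined), `codons_used`.
#' @export
pairwise_dnds_ng86 <- function(seqA, seqB, code = "standard") {
  a <- if (length(seqA) == 1L) strsplit(toupper(seqA), "")[[1]] else toupper(seqA)
  b <- if (length(seqB) == 1L) strsplit(toupper(seqB), "")[[1]] else toupper(seqB)
  if (length(a) != length(b)) stop("sequences differ in length")
  if (length(a) %% 3L != 0L) stop("length must be divisible by 3")
  pairwise_dnds_codons(to_codons(a), to_codons(b), code = code)
}

# NG86 on codon-string vectors (shared by the string and alignment entries)
pairwise_dnds_codons <- function(ca, cb, code = "standard") {
  gc <- genetic_code(code)
  ok <- !grepl("[^ACGT]", ca) & !grepl("[^ACGT]", cb)
  ok <- ok & !is.na(gc[ca]) & !is.na(gc[cb]) & gc[ca] != "*" & gc[cb] != "*"
  ca <- ca[ok]; cb <- cb[ok]
  if (!length(ca)) stop("no comparable codons")
  tabs <- codon_tables(code)
  sa <- tabs$sites[ca, , drop = FALSE]
  sb <- tabs$sites[cb, , drop = FALSE]
  S <- (sum(sa[, "syn"]) + sum(sb[, "syn"])) / 2
  N <- (sum(sa[, "nonsyn"]) + sum(sb[, "nonsyn"])) / 2
  Sd <- 0; Nd <- 0
  for (i in which(ca != cb)) {
    d <- codon_path_counts(ca[i], cb[i], code)
    Sd <- Sd + d[["syn"]]
    Nd <- Nd + d[["nonsyn"]]
  }
  p_s <- if (S > 0) Sd / S else 0
  p_n <- if (N > 0) Nd / N else 0
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  saturated <- (p_s >= 0.75) || (p_n >= 0.75)
  d_S <- if (p_s < 0.75) jc(p_s) else NA_real_
  d_N <- if (p_n < 0.75) jc(p_n) else NA_real_
  omega <- if (!saturated && !is.na(d_S) && d_S > 0) d_N / d_S else NA_real_
  structure(list(N = N, S = S, Nd = Nd, Sd = Sd, d_N = d_N, d_S = d_S,
                 omega = omega, saturated = saturated, codons_used = length(ca)),
            class = "mn_dnds")
}

#' @export
print.mn_dnds <- function(x, ...) {
  cat(sprintf("NG86: N = %.2f, S = %.2f, Nd = %.2f, Sd = %.2f, dN = %s, dS = %s, omega = %s\n",
              x$N, x$S, x$Nd, x$Sd, format(x$d_N, digits = 4),
              format(x$d_S, digits = 4), format(x$omega, digits = 4)))
  invisible(x)
}

#' Gene-level dN/dS from a codon alignment
#'
#' NG86 over all unordered taxon pairs: gene-level `d_N` and `d_S` are the
#' means of the pairwise estimates over non-saturated pairs, and
#' `omega = mean(d_N) / mean(d_S)` (the ratio of means, which is stabler
#' than a mean of ratios when some pairwise `d_S` are near 0). Saturated
#' pairs are excluded and counted; a gene with all pairs saturated is
#' flagged.
#'
#' @param alignment A codon [mn_alignment] with >= 2 taxa.
#' @param code Genetic code (see [genetic_code()]).
#' @return `mn_dnds` list with the averaged quantities plus `n_pairs`,
#'   `n_saturated`, `all_saturated`.
#' @export
geneset_dnds <- function(alignment, code = "standard") {
  if (aln_molecule(alignment) != "codon") stop("codon alignment required")
  taxa <- aln_taxa(alignment)
  if (length(taxa) < 2) stop("need >= 2 taxa")
  codons <- lapply(taxa, function(tx) to_codons(unclass(alignment)[tx, ]))
  names(codons) <- taxa
  pairs <- utils::combn(taxa, 2, simplify = FALSE)
  res <- lapply(pairs, function(p)
    pairwise_dnds_codons(codons[[p[1]]], codons[[p[2]]], code = code))
  sat <- vapply(res, `[[`, logical(1), "saturated")
  keep <- res[!sat]
  if (!length(keep)) {
    return(structure(list(N = NA_real_, S = NA_real_, Nd = NA_real_,
                          Sd = NA_real_, d_N = NA_real_, d_S = NA_real_,
                          omega = NA_real_, saturated = TRUE,
                          n_pairs = length(res), n_saturated = sum(sat),
                          all_saturated = TRUE), class = "mn_dnds"))
  }
  mean_of <- function(f) mean(vapply(keep, `[[`, numeric(1), f))
  d_N <- mean_of("d_N"); d_S <- mean_of("d_S")
  structure(list(N = mean_of("N"), S = mean_of("S"), Nd = mean_of("Nd"),
                 Sd = mean_of("Sd"), d_N = d_N, d_S = d_S,
                 omega = if (d_S > 0) d_N / d_S else NA_real_,
                 saturated = FALSE, n_pairs = length(res),
                 n_saturated = sum(sat), all_saturated = FALSE),
            class = "mn_dnds")
}

#' Compare gene-wise omega between gene sets (ANOVA + Tukey HSD)
#'
#' One-way ANOVA of gene-wise dN/dS on gene-set membership, followed by all
#' pairwise Tukey honest-significant-difference comparisons. Groups with
#' fewer than 2 genes are excluded with a warning.
#'
#' @param omega_by_gene Named numeric vector, gene -> omega.
#' @param groups Named character vector, gene -> gene-set label.
#' @return data.frame with columns `comparison`, `diff`, `lwr`, `upr`,
#'   `p_adj`, plus attribute `anova_p`.
#' @export
compare_groups <- function(omega_by_gene, groups) {
  genes <- intersect(names(omega_by_gene), names(groups))
  df <- data.frame(omega = as.numeric(omega_by_gene[genes]),
                   group = as.character(groups[genes]))
  df <- df[!is.na(df$omega), ]
  sizes <- table(df$group)
  small <- names(sizes)[sizes < 2]
  if (length(small)) {
    warning("excluding groups with < 2 genes: ", paste(small, collapse = ", "))
    df <- df[!(df$group %in% small), ]
  }
  if (length(unique(df$group)) < 2) stop("need >= 2 groups with >= 2 genes")
  df$group <- factor(df$group)
  fit <- stats::aov(omega ~ group, data = df)
  tk <- stats::TukeyHSD(fit)$group
  out <- data.frame(comparison = rownames(tk), diff = tk[, "diff"],
                    lwr = tk[, "lwr"], upr = tk[, "upr"],
                    p_adj = tk[, "p adj"], row.names = NULL)
  attr(out, "anova_p") <- summary(fit)[[1]][["Pr(>F)"]][1]
  out
}

#' Trend of omega on contact-residue fraction
#'
#' Ordinary least-squares regression of gene-wise dN/dS on the fraction of a
#' gene's residues that contact the other genome's proteins, with the
#' Pearson correlation and its two-sided P value.
#'
#' @param omega_by_gene Named numeric vector, gene -> omega.
#' @param contact_fraction_by_gene Named numeric vector, gene -> proportion.
#' @return List with `slope`, `intercept`, `r`, `p`, `n`.
#' @export
contact_fraction_trend <- function(omega_by_gene, contact_fraction_by_gene) {
  genes <- intersect(names(omega_by_gene), names(contact_fraction_by_gene))
  x <- as.numeric(contact_fraction_by_gene[genes])
  y <- as.numeric(omega_by_gene[genes])
  keep <- is.finite(x) & is.finite(y)
  x <- x[keep]; y <- y[keep]
  if (length(x) < 3) stop("need >= 3 genes with both values")
  if (stats::sd(x) == 0) stop("degenerate input: constant contact fraction")
  fit <- stats::lm(y ~ x)
  ct <- stats::cor.test(x, y)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       r = unname(ct$estimate), p = ct$p.value, n = length(x))
}
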