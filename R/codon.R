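# Codon-level machinery shared by the simulator, the NG86 estimator and the
# site-selection test: genetic codes, single-nucleotide neighbourhoods,
# NG86 fractional site counts and minimal mutational pathways.

NUCS <- c("T", "C", "A", "G")

# transitions: A<->G, C<->T
is_transition <- function(a, b) {
  (a %in% c("A", "G") & b %in% c("A", "G")) |
    (a %in% c("C", "T") & b %in% c("C", "T"))
}

#' Genetic code lookup
#'
#' Returns a named character vector mapping the 64 codons to one-letter amino
#' acids (`"*"` for stops). Mitochondrially encoded genes use the vertebrate
#' mitochondrial code; nuclear genes the standard code.
#'
#' @param code `"standard"` or `"vertebrate_mito"`.
#' @export
genetic_code <- function(code = c("standard", "vertebrate_mito")) {
  code <- match.arg(code)
  key <- paste0("gc:", code)
  hit <- .codon_cache[[key]]
  if (!is.null(hit)) return(hit)
  id <- if (code == "standard") "1" else "2"
  gc <- Biostrings::getGeneticCode(id)
  names(gc) <- chartr("U", "T", names(gc))
  .codon_cache[[key]] <- gc
  gc
}

# all sense (non-stop) codons for a code, in fixed lexicographic order
sense_codons <- function(code = "standard") {
  gc <- genetic_code(code)
  sort(names(gc)[gc != "*"])
}

# the 9 single-nucleotide neighbours of a codon
codon_neighbors <- function(codon) {
  s <- strsplit(codon, "")[[1]]
  out <- character(0)
  for (pos in 1:3) {
    for (n in setdiff(NUCS, s[pos])) {
      t <- s; t[pos] <- n
      out <- c(out, paste(t, collapse = ""))
    }
  }
  out
}

#' NG86 fractional synonymous and nonsynonymous site counts for one codon
#'
#' For each codon position, counts the fraction of the three possible
#' single-nucleotide changes that are synonymous; changes to stop codons are
#' excluded from the denominator. Summed over positions this gives the
#' codon's synonymous site count; the nonsynonymous count is the complement,
#' so `syn + nonsyn = 3` whenever no neighbour is a stop.
#'
#' @param codon A 3-character codon string (must not be a stop).
#' @param code Genetic code name (see [genetic_code()]).
#' @return Named numeric vector `c(syn, nonsyn)`.
#' @export
count_sites_ng86 <- function(codon, code = "standard") {
  gc <- genetic_code(code)
  codon <- toupper(codon)
  if (is.na(gc[codon])) stop("not a codon: ", codon)
  if (gc[codon] == "*") stop("stop codon supplied: ", codon)
  aa <- gc[[codon]]
  s <- strsplit(codon, "")[[1]]
  syn <- 0; nonsyn <- 0
  for (pos in 1:3) {
    targets <- vapply(setdiff(NUCS, s[pos]), function(n) {
      t <- s; t[pos] <- n; paste(t, collapse = "")
    }, character(1))
    taa <- gc[targets]
    ok <- taa != "*"
    if (!any(ok)) next
    syn <- syn + sum(taa[ok] == aa) / sum(ok)
    nonsyn <- nonsyn + sum(taa[ok] != aa) / sum(ok)
  }
  c(syn = syn, nonsyn = nonsyn)
}

# cached per-code tables -------------------------------------------------

.codon_cache <- new.env(parent = emptyenv())

codon_tables <- function(code = "standard") {
  key <- code
  if (!is.null(.codon_cache[[key]])) return(.codon_cache[[key]])
  gc <- genetic_code(code)
  sense <- sense_codons(code)
  sites <- t(vapply(sense, count_sites_ng86, numeric(2), code = code))
  # neighbour list: for each sense codon, data.frame of sense neighbours
  nb <- lapply(sense, function(cd) {
    targets <- codon_neighbors(cd)
    keep <- gc[targets] != "*"
    targets <- targets[keep]
    data.frame(to = targets,
               transition = is_transition(substr_diff(cd, targets)$from,
                                          substr_diff(cd, targets)$to),
               synonymous = gc[targets] == gc[[cd]],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  names(nb) <- sense
  out <- list(gc = gc, sense = sense, sites = sites, neighbors = nb)
  .codon_cache[[key]] <- out
  out
}

# for equal-length codon strings differing at one position, the nucleotides
substr_diff <- function(a, b) {
  sa <- strsplit(a, "")[[1]]
  sb <- do.call(rbind, strsplit(b, ""))
  pos <- apply(sb, 1, function(r) which(r != sa)[1])
  list(from = sa[pos], to = sb[cbind(seq_along(pos), pos)])
}

# NG86 pathway-averaged difference counts between two codons.
# Enumerates orderings of the differing positions; pathways through stop
# codons are excluded (if every pathway is blocked, all are retained so the
# count stays defined). Returns c(syn_diffs, nonsyn_diffs). Results are
# memoized per (code, codon pair).
codon_path_counts <- function(c1, c2, code = "standard") {
  key <- paste0("path:", code, ":", c1, ":", c2)
  hit <- .codon_cache[[key]]
  if (!is.null(hit)) return(hit)
  res <- codon_path_counts_raw(c1, c2, code)
  .codon_cache[[key]] <- res
  res
}

codon_path_counts_raw <- function(c1, c2, code = "standard") {
  gc <- genetic_code(code)
  if (c1 == c2) return(c(syn = 0, nonsyn = 0))
  s1 <- strsplit(c1, "")[[1]]; s2 <- strsplit(c2, "")[[1]]
  pos <- which(s1 != s2)
  perms <- permutations_of(pos)
  path_counts <- list()
  for (ord in perms) {
    cur <- s1; syn <- 0; nonsyn <- 0; blocked <- FALSE
    for (p in ord) {
      nxt <- cur; nxt[p] <- s2[p]
      aa_from <- gc[[paste(cur, collapse = "")]]
      aa_to <- gc[[paste(nxt, collapse = "")]]
      if (aa_to == "*") { blocked <- TRUE; break }
      if (aa_from == aa_to) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    if (!blocked) path_counts[[length(path_counts) + 1L]] <- c(syn, nonsyn)
  }
  if (!length(path_counts)) { # every pathway passes a stop: retain all
    for (ord in perms) {
      cur <- s1; syn <- 0; nonsyn <- 0
      for (p in ord) {
        nxt <- cur; nxt[p] <- s2[p]
        aa_from <- gc[[paste(cur, collapse = "")]]
        aa_to <- gc[[paste(nxt, collapse = "")]]
        if (identical(aa_from, aa_to)) syn <- syn + 1 else nonsyn <- nonsyn + 1
        cur <- nxt
      }
      path_counts[[length(path_counts) + 1L]] <- c(syn, nonsyn)
    }
  }
  m <- do.call(rbind, path_counts)
  c(syn = mean(m[, 1]), nonsyn = mean(m[, 2]))
}

permutations_of <- function(x) {
  if (length(x) <= 1L) return(list(x))
  out <- list()
  for (i in seq_along(x))
    for (rest in permutations_of(x[-i]))
      out[[length(out) + 1L]] <- c(x[i], rest)
  out
}

# split a nucleotide row (character vector) into codon strings
to_codons <- function(chars) {
  n <- length(chars) %/% 3L
  vapply(seq_len(n), function(i)
    paste(chars[(3L * i - 2L):(3L * i)], collapse = ""), character(1))
}
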