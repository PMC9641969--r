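#' Multiple sequence alignment container
#'
#' A light container for an aligned set of equal-length sequences, the unit
#' that flows through every stage of the package. Sequences are stored as a
#' character matrix with one row per taxon and one column per position
#' (amino-acid residues, or nucleotides for codon alignments).
#'
#' @param seqs Character matrix (taxa x positions) of single characters, or a
#'   named character vector of strings of equal length.
#' @param molecule `"amino"` or `"codon"`. Codon alignments must have a number
#'   of columns divisible by 3.
#' @param gene_set Optional gene-set label (e.g. `"mt"`, `"nmt_oxphos"`).
#' @return An object of class `mn_alignment`: the character matrix with
#'   attributes `molecule` and `gene_set`.
#' @examples
#' aln <- mn_alignment(c(sp1 = "ACDE", sp2 = "ACDK"), molecule = "amino")
#' aln_length(aln)
#' @export
mn_alignment <- function(seqs, molecule = c("amino", "codon"), gene_set = NA_character_) {
  molecule <- match.arg(molecule)
  if (is.character(seqs) && !is.matrix(seqs)) {
    if (is.null(names(seqs))) stop("sequence vector must be named by taxon")
    n <- nchar(seqs)
    if (length(unique(n)) != 1L) stop("sequences must all have the same length")
    m <- do.call(rbind, strsplit(seqs, ""))
    rownames(m) <- names(seqs)
    seqs <- m
  }
  if (!is.matrix(seqs) || !is.character(seqs)) stop("seqs must be a character matrix")
  if (is.null(rownames(seqs))) stop("taxa must be given as rownames")
  if (anyDuplicated(rownames(seqs))) stop("taxon names must be unique")
  if (molecule == "codon" && ncol(seqs) %% 3L != 0L)
    stop("codon alignment length must be divisible by 3")
  seqs[] <- toupper(seqs)
  alpha <- if (molecule == "amino") c(AMINO_ACIDS, "-", "X") else c("A", "C", "G", "T", "-", "N")
  bad <- setdiff(unique(as.vector(seqs)), alpha)
  if (length(bad)) stop("characters not in the ", molecule, " alphabet: ",
                        paste(bad, collapse = " "))
  structure(seqs, molecule = molecule, gene_set = gene_set,
            class = c("mn_alignment", "matrix", "array"))
}

#' The 20 standard amino acids, alphabetically ordered
#' @export
AMINO_ACIDS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                 "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

#' @export
print.mn_alignment <- function(x, ...) {
  cat(sprintf("mn_alignment: %d taxa x %d %s positions (gene set: %s)\n",
              nrow(x), ncol(x), attr(x, "molecule"), attr(x, "gene_set")))
  invisible(x)
}

#' @rdname mn_alignment
#' @param x An `mn_alignment`.
#' @export
aln_taxa <- function(x) rownames(x)

#' @rdname mn_alignment
#' @export
aln_length <- function(x) ncol(x)

#' @rdname mn_alignment
#' @export
aln_molecule <- function(x) attr(x, "molecule")

# characters treated as missing data: gap plus the molecule's ambiguity
# code (X for residues, N for nucleotides — N is Asn in amino alignments)
is_missing_state <- function(ch, molecule = "amino") {
  if (molecule == "amino") ch %in% c("-", "X") else ch %in% c("-", "N")
}

#' Read an alignment from a FASTA file
#'
#' @param path Path to an (uncompressed) FASTA file.
#' @inheritParams mn_alignment
#' @return An [mn_alignment].
#' @export
read_fasta_alignment <- function(path, molecule = c("amino", "codon"),
                                 gene_set = NA_character_) {
  molecule <- match.arg(molecule)
  type <- if (molecule == "amino") "AA" else "DNA"
  x <- ape::read.FASTA(path, type = type)
  m <- toupper(as.character(as.matrix(x)))
  mn_alignment(m, molecule = molecule, gene_set = gene_set)
}

#' Write an alignment to a FASTA file
#'
#' @param x An [mn_alignment].
#' @param path Output path.
#' @export
write_fasta_alignment <- function(x, path) {
  seqs <- apply(unclass(x), 1L, paste, collapse = "")
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(seqs))
    writeLines(c(paste0(">", names(seqs)[i]), seqs[[i]]), con)
  invisible(path)
}

#' Concatenate gene alignments into one supermatrix
#'
#' Taxa missing from an input alignment are padded with gaps in that gene's
#' block; taxa whose overall padded fraction exceeds `max_gap_fraction` are
#' dropped with a warning. Per-gene column offsets are recorded so downstream
#' stages can recover gene boundaries.
#'
#' @param alignments List of [mn_alignment] objects of the same molecule type.
#' @param max_gap_fraction Taxa padded beyond this fraction of total columns
#'   are excluded (default 0.5).
#' @return An [mn_alignment] with attributes `offsets` (named start column per
#'   gene) and `pad_fraction` (per-taxon padded fraction).
#' @export
concatenate_alignments <- function(alignments, max_gap_fraction = 0.5) {
  if (!length(alignments)) stop("no alignments supplied")
  mols <- vapply(alignments, aln_molecule, character(1))
  if (length(unique(mols)) != 1L) stop("molecule type differs across alignments")
  taxa <- sort(unique(unlist(lapply(alignments, aln_taxa))))
  widths <- vapply(alignments, ncol, integer(1))
  total <- sum(widths)
  out <- matrix("-", length(taxa), total, dimnames = list(taxa, NULL))
  padded <- matrix(FALSE, length(taxa), length(alignments))
  at <- 1L
  offsets <- integer(length(alignments))
  for (i in seq_along(alignments)) {
    a <- alignments[[i]]
    offsets[i] <- at
    cols <- at:(at + ncol(a) - 1L)
    present <- intersect(taxa, aln_taxa(a))
    out[present, cols] <- unclass(a)[present, , drop = FALSE]
    padded[!(taxa %in% present), i] <- TRUE
    at <- at + ncol(a)
  }
  names(offsets) <- vapply(seq_along(alignments), function(i) {
    gs <- attr(alignments[[i]], "gene_set")
    if (is.na(gs)) paste0("gene", i) else gs
  }, character(1))
  pad_frac <- as.vector(padded %*% widths) / total
  names(pad_frac) <- taxa
  drop <- pad_frac > max_gap_fraction
  if (any(drop)) {
    warning("dropping over-padded taxa: ", paste(taxa[drop], collapse = ", "))
    out <- out[!drop, , drop = FALSE]
  }
  res <- mn_alignment(out, molecule = mols[1],
                      gene_set = attr(alignments[[1]], "gene_set"))
  attr(res, "offsets") <- offsets
  attr(res, "pad_fraction") <- pad_frac
  res
}
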