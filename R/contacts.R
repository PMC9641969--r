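# Mitonuclear residue contact pairs from a protein-complex structure, and
# mapping of structure residues to alignment columns.

#' Parse a PDB structure with a chain -> gene/genome map
#'
#' Reads the coordinate records of a PDB file (via \pkg{bio3d}), keeping
#' heavy atoms of ATOM records only: hydrogens are dropped, HETATM records
#' ignored, and for alternate locations only the highest-occupancy atom per
#' (chain, residue, atom name) is kept.
#'
#' @param path Path to a PDB-format file.
#' @param chain_map data.frame with columns `chain`, `gene`, `genome`
#'   (`"mt"` or `"nuclear"`), and optionally `reference_taxon`.
#' @return List of class `mn_structure`: `atoms` (data.frame chain, resno,
#'   resid, elety, x, y, z), `chains` (per-chain one-letter sequences, in
#'   residue-number order), `residue_numbers` (per-chain author numbering),
#'   `chain_map`.
#' @export
parse_structure <- function(path, chain_map = NULL) {
  pdb <- tryCatch(bio3d::read.pdb(path, verbose = FALSE, rm.alt = FALSE),
                  error = function(e) stop("cannot parse PDB file: ",
                                           conditionMessage(e)))
  at <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  if (!nrow(at)) stop("no ATOM records in ", path)
  elem <- at$elesy
  if (is.null(elem) || all(is.na(elem)))
    elem <- toupper(substr(gsub("[0-9 ]", "", at$elety), 1, 1))
  at <- at[!(elem %in% c("H", "D")), , drop = FALSE]
  # altloc: keep highest occupancy per (chain, residue, atom name)
  if (any(nzchar(at$alt) & !is.na(at$alt))) {
    key <- paste(at$chain, at$resno, at$elety)
    o <- order(key, -replace(at$o, is.na(at$o), 1))
    at <- at[o, , drop = FALSE]
    at <- at[!duplicated(paste(at$chain, at$resno, at$elety)), , drop = FALSE]
  }
  atoms <- data.frame(chain = at$chain, resno = at$resno, resid = at$resid,
                      elety = at$elety, x = at$x, y = at$y, z = at$z,
                      stringsAsFactors = FALSE)
  if (any(!is.finite(c(atoms$x, atoms$y, atoms$z))))
    stop("non-finite coordinates in structure")
  chains <- list(); resnos <- list()
  for (ch in unique(atoms$chain)) {
    sub <- atoms[atoms$chain == ch, ]
    sub <- sub[!duplicated(sub$resno), ]
    sub <- sub[order(sub$resno), ]
    chains[[ch]] <- paste(bio3d::aa321(sub$resid), collapse = "")
    resnos[[ch]] <- sub$resno
  }
  structure(list(atoms = atoms, chains = chains, residue_numbers = resnos,
                 chain_map = chain_map),
            class = "mn_structure")
}

#' @export
print.mn_structure <- function(x, ...) {
  cat(sprintf("mn_structure: %d chains, %d heavy atoms\n",
              length(x$chains), nrow(x$atoms)))
  invisible(x)
}

# van der Waals radii (Angstrom) for the vdw-overlap contact criterion
VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
               SE = 1.90, FE = 1.40, CU = 1.40, MG = 1.73, ZN = 1.39)

atom_element <- function(elety) {
  e <- toupper(gsub("[0-9' ]", "", elety))
  two <- substr(e, 1, 2)
  one <- substr(e, 1, 1)
  ifelse(two %in% names(VDW_RADII) & !(one %in% c("C", "N", "O", "S", "P")),
         two, one)
}

#' Find mitonuclear residue contact pairs
#'
#' Reports every (mt residue, nuclear residue) pair whose minimum heavy-atom
#' Euclidean distance is at or below `cutoff` (default 5 Angstrom,
#' inclusive) and whose genes come from different genomes; intra-genome
#' pairs are never reported. The alternative `criterion = "vdw"` uses a van
#' der Waals overlap `r_i + r_j - d >= overlap_min` instead.
#'
#' @param structure An [parse_structure()] result whose `chain_map` covers
#'   every chain to be scanned.
#' @param cutoff Distance cutoff in Angstrom (criterion `"distance"`).
#' @param criterion `"distance"` (default) or `"vdw"`.
#' @param overlap_min Minimum vdw overlap in Angstrom (criterion `"vdw"`;
#'   -1 allows a 1 Angstrom gap).
#' @return data.frame with columns `mt_gene`, `mt_chain`, `mt_residue`,
#'   `n_gene`, `n_chain`, `n_residue`, `distance` (min heavy-atom distance,
#'   Angstrom). Residue numbers are PDB author numbering.
#' @export
find_contact_pairs <- function(structure, cutoff = 5.0,
                               criterion = c("distance", "vdw"),
                               overlap_min = -1.0) {
  criterion <- match.arg(criterion)
  cm <- structure$chain_map
  if (is.null(cm)) stop("structure has no chain map")
  chains <- unique(structure$atoms$chain)
  unmapped <- setdiff(chains, cm$chain)
  if (length(unmapped))
    stop("chains missing from chain map: ", paste(unmapped, collapse = ", "))
  genome_of <- stats::setNames(cm$genome, cm$chain)
  gene_of <- stats::setNames(cm$gene, cm$chain)
  at <- structure$atoms
  mt_ch <- chains[genome_of[chains] == "mt"]
  n_ch <- chains[genome_of[chains] == "nuclear"]
  out <- list()
  for (cm_ch in mt_ch) for (cn_ch in n_ch) {
    A <- at[at$chain == cm_ch, ]
    B <- at[at$chain == cn_ch, ]
    d2 <- outer(A$x, B$x, "-")^2 + outer(A$y, B$y, "-")^2 +
      outer(A$z, B$z, "-")^2
    if (criterion == "vdw") {
      ra <- VDW_RADII[atom_element(A$elety)]; ra[is.na(ra)] <- 1.7
      rb <- VDW_RADII[atom_element(B$elety)]; rb[is.na(rb)] <- 1.7
      hit <- (outer(ra, rb, "+") - sqrt(d2)) >= overlap_min
    } else {
      hit <- d2 <= cutoff^2
    }
    if (!any(hit)) next
    idx <- which(hit, arr.ind = TRUE)
    pr <- data.frame(mt_res = A$resno[idx[, 1]], n_res = B$resno[idx[, 2]],
                     d = sqrt(d2[idx]))
    agg <- stats::aggregate(d ~ mt_res + n_res, data = pr, FUN = min)
    out[[length(out) + 1L]] <- data.frame(
      mt_gene = gene_of[[cm_ch]], mt_chain = cm_ch, mt_residue = agg$mt_res,
      n_gene = gene_of[[cn_ch]], n_chain = cn_ch, n_residue = agg$n_res,
      distance = agg$d, stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(mt_gene = character(0), mt_chain = character(0),
                      mt_residue = integer(0), n_gene = character(0),
                      n_chain = character(0), n_residue = integer(0),
                      distance = numeric(0)))
  res <- do.call(rbind, out)
  res[order(res$mt_gene, res$mt_residue, res$n_gene, res$n_residue), ,
      drop = FALSE]
}

#' Map a structure residue to an alignment column
#'
#' Globally aligns the chain's polymer sequence to the reference taxon's
#' ungapped sequence (match 1, mismatch -1, gap -2 per gap position), maps
#' the residue through the alignment, then converts the reference position
#' to the (1-based) alignment column. Refuses when the pairwise identity is
#' below 50%, which usually indicates a wrong chain/gene pairing.
#'
#' @param structure_sequence One-letter chain sequence (string).
#' @param residue_index 1-based index into the chain polymer sequence (not
#'   author numbering; see [residue_index_from_number()]).
#' @param alignment An amino-acid [mn_alignment] containing the reference.
#' @param reference_taxon Taxon name in the alignment.
#' @return The alignment column (integer), or `NA` with a warning when the
#'   residue falls outside the reference (e.g. in a terminal extension).
#' @export
map_residue_to_column <- function(structure_sequence, residue_index,
                                  alignment, reference_taxon) {
  if (!(reference_taxon %in% aln_taxa(alignment)))
    stop("reference taxon not in alignment: ", reference_taxon)
  row <- unclass(alignment)[reference_taxon, ]
  ref_ungapped <- row[!is_missing_state(row)]
  ref_cols <- which(!is_missing_state(row))
  if (residue_index < 1 || residue_index > nchar(structure_sequence))
    stop("residue_index outside chain sequence")
  mat <- matrix(-1, 26, 26, dimnames = list(LETTERS, LETTERS))
  diag(mat) <- 1
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(structure_sequence),
    Biostrings::AAString(paste(ref_ungapped, collapse = "")),
    type = "global", substitutionMatrix = mat,
    gapOpening = 0, gapExtension = 2)
  ident <- Biostrings::nmatch(pa) /
    min(nchar(structure_sequence), length(ref_ungapped))
  if (ident < 0.5)
    stop(sprintf("pairwise identity %.0f%% < 50%%: wrong chain/gene pairing suspected",
                 100 * ident))
  ap <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  i_chain <- 0L; i_ref <- 0L
  for (k in seq_along(ap)) {
    if (ap[k] != "-") i_chain <- i_chain + 1L
    if (as_[k] != "-") i_ref <- i_ref + 1L
    if (i_chain == residue_index && ap[k] != "-") {
      if (as_[k] == "-") {
        warning("residue ", residue_index, " aligns to a gap in the reference")
        return(NA_integer_)
      }
      return(ref_cols[i_ref])
    }
  }
  warning("residue ", residue_index, " not mappable")
  NA_integer_
}

#' Convert a PDB author residue number to a chain sequence index
#'
#' @param structure An `mn_structure`.
#' @param chain Chain id.
#' @param resno Author residue number.
#' @return 1-based index into the chain's polymer sequence.
#' @export
residue_index_from_number <- function(structure, chain, resno) {
  idx <- match(resno, structure$residue_numbers[[chain]])
  if (is.na(idx)) stop("residue ", resno, " not in chain ", chain)
  idx
}

#' Classify genes as contact or non-contact
#'
#' A gene is "contact" when it appears in at least one mitonuclear contact
#' pair. Also returns each gene's contact-residue fraction (distinct contact
#' residues / residue count) when residue counts are supplied — the
#' predictor used by [contact_fraction_trend()].
#'
#' @param pairs Contact-pair data.frame from [find_contact_pairs()].
#' @param genes Character vector of genes to classify.
#' @param n_residues Optional named vector of per-gene residue counts.
#' @return List with `status` (named character, `"contact"`/`"non-contact"`)
#'   and `contact_fraction` (named numeric, NA without residue counts).
#' @export
classify_contact_genes <- function(pairs, genes, n_residues = NULL) {
  res_by_gene <- c(split(pairs$mt_residue, pairs$mt_gene),
                   split(pairs$n_residue, pairs$n_gene))
  n_contact <- vapply(genes, function(g) {
    r <- res_by_gene[[g]]
    if (is.null(r)) 0L else length(unique(r))
  }, integer(1))
  status <- ifelse(n_contact > 0, "contact", "non-contact")
  names(status) <- genes
  frac <- rep(NA_real_, length(genes)); names(frac) <- genes
  if (!is.null(n_residues)) {
    ok <- genes %in% names(n_residues)
    frac[ok] <- n_contact[ok] / as.numeric(n_residues[genes[ok]])
  }
  list(status = status, contact_fraction = frac)
}
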