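#' Branch table for a rooted tree
#'
#' Gives every branch a stable id (the number of its child node, following
#' \pkg{ape} node numbering) together with its parent, child, length and
#' depth. Depth is the count of edges from the root, so a root-adjacent
#' branch has depth 1.
#'
#' @param tree A rooted `phylo` object.
#' @return data.frame with columns `branch_id`, `parent`, `child`, `length`,
#'   `depth`.
#' @export
branch_table <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  n_tip <- ape::Ntip(tree)
  root <- n_tip + 1L
  depth <- integer(max(tree$edge))
  # edges in tree$edge are not guaranteed preorder; iterate until stable
  ord <- reorder_preorder(tree)
  for (e in ord) {
    p <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    depth[v] <- if (p == root) 1L else depth[p] + 1L
  }
  len <- tree$edge.length
  if (is.null(len)) len <- rep(NA_real_, nrow(tree$edge))
  data.frame(branch_id = tree$edge[, 2],
             parent = tree$edge[, 1],
             child = tree$edge[, 2],
             length = len,
             depth = depth[tree$edge[, 2]])
}

# indices of tree$edge rows in preorder (parent before child)
reorder_preorder <- function(tree) {
  et <- ape::reorder.phylo(tree, "postorder")
  o <- match(paste(et$edge[, 1], et$edge[, 2]),
             paste(tree$edge[, 1], tree$edge[, 2]))
  rev(o)
}

# indices of tree$edge rows in postorder (children before parents)
reorder_postorder <- function(tree) rev(reorder_preorder(tree))

#' Root-to-tip distances (lineage evolutionary rates)
#'
#' Sums branch lengths along each tip's unique root path. With branch lengths
#' in expected substitutions per site, the result is each lineage's total
#' amount of evolution for the gene set — the raw rate consumed by the ERC
#' stage.
#'
#' @param tree Rooted `phylo` with branch lengths.
#' @param gene_set Optional label attached to the result.
#' @return Named numeric vector (one value per tip) of class `mn_rates` with
#'   attribute `gene_set`.
#' @export
root_to_tip_distances <- function(tree, gene_set = NA_character_) {
  stopifnot(inherits(tree, "phylo"))
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (is.null(tree$edge.length)) stop("tree has no branch lengths")
  n_tip <- ape::Ntip(tree)
  root <- n_tip + 1L
  d <- numeric(max(tree$edge))
  for (e in reorder_preorder(tree)) {
    p <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    d[v] <- (if (p == root) 0 else d[p]) + tree$edge.length[e]
  }
  out <- d[seq_len(n_tip)]
  names(out) <- tree$tip.label
  structure(out, gene_set = gene_set, class = "mn_rates")
}

#' @export
print.mn_rates <- function(x, ...) {
  cat(sprintf("mn_rates (%s): %d taxa\n", attr(x, "gene_set"), length(x)))
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

# branch ids (child nodes) on the root-to-tip path of each tip, root first
tip_branch_paths <- function(tree) {
  n_tip <- ape::Ntip(tree)
  root <- n_tip + 1L
  parent <- integer(max(tree$edge))
  parent[tree$edge[, 2]] <- tree$edge[, 1]
  lapply(seq_len(n_tip), function(tip) {
    path <- integer(0)
    v <- tip
    while (v != root) {
      path <- c(v, path)
      v <- parent[v]
    }
    path
  })
}

# derive a reproducible sub-stream seed from a master seed and a stage name;
# kept below 2^31 so it is a valid R integer
stage_seed <- function(seed, stage) {
  h <- 0
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 1000003L
  as.integer((abs(as.numeric(seed)) %% 2147480000 + h * 1009) %% 2147483647)
}

#' Write a tree with branch lengths to a Newick file
#' @param tree A `phylo` object.
#' @param path Output path.
#' @export
write_newick <- function(tree, path) {
  ape::write.tree(tree, file = path)
  invisible(path)
}
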