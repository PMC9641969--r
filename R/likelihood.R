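# Felsenstein pruning under a 20-state equal-exchangeability (Poisson)
# amino-acid model, optionally with 4-category discrete gamma rates or a
# user-supplied exchangeability matrix, plus fixed-topology branch-length
# estimation by per-branch 1-D maximization.

N_AA <- 20L

# discrete gamma rates, k equal-probability categories, category means
# (mean-of-bin discretization)
discrete_gamma_rates <- function(alpha, k = 4L) {
  if (alpha <= 0) stop("alpha must be > 0")
  b <- stats::qgamma(seq(0, 1, length.out = k + 1L), shape = alpha, rate = alpha)
  r <- k * (stats::pgamma(b[-1L], shape = alpha + 1, rate = alpha) -
              stats::pgamma(b[-(k + 1L)], shape = alpha + 1, rate = alpha))
  r
}

# transition-probability factory. Default: Poisson closed form
#   P_same(t) = 1/20 + (19/20) exp(-20/19 t),  P_diff(t) = (1 - exp(-20/19 t))/20
# with t in expected substitutions per site. With an exchangeability matrix S
# (symmetric, diagonal ignored), builds a reversible model with uniform
# frequencies, scaled to one expected substitution per unit t.
make_transition_fun <- function(exchangeability = NULL) {
  if (is.null(exchangeability)) {
    return(function(t) {
      e <- exp(-N_AA / (N_AA - 1) * t)
      p_diff <- (1 - e) / N_AA
      m <- matrix(p_diff, N_AA, N_AA)
      diag(m) <- 1 / N_AA + (N_AA - 1) / N_AA * e
      m
    })
  }
  S <- exchangeability
  stopifnot(is.matrix(S), nrow(S) == N_AA, ncol(S) == N_AA)
  Q <- (S + t(S)) / 2 / N_AA
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  Q <- Q / (-sum(diag(Q)) / N_AA)  # mean rate 1
  eig <- eigen(Q, symmetric = TRUE)
  function(t) {
    eig$vectors %*% (exp(eig$values * t) * t(eig$vectors))
  }
}

# compress alignment columns into unique patterns
aln_patterns <- function(alignment) {
  m <- unclass(alignment)
  key <- apply(m, 2L, paste, collapse = "\r")
  first <- !duplicated(key)
  w <- as.vector(table(factor(key, levels = key[first])))
  list(states = m[, first, drop = FALSE], weights = w)
}

# tip partial-likelihood matrices (N_AA x npat); missing data -> all ones
tip_partials <- function(states_row) {
  npat <- length(states_row)
  m <- matrix(0, N_AA, npat)
  idx <- match(states_row, AMINO_ACIDS)
  miss <- is.na(idx)
  m[cbind(idx[!miss], which(!miss))] <- 1
  m[, miss] <- 1
  m
}

# post-order ("down") partials for all nodes at one rate category.
# lengths: vector indexed by child node id; returns list of matrices.
down_partials <- function(tree, tips_part, lengths, pfun, rate = 1) {
  n_node <- max(tree$edge)
  n_tip <- ape::Ntip(tree)
  npat <- ncol(tips_part[[1]])
  down <- vector("list", n_node)
  for (i in seq_len(n_tip)) down[[i]] <- tips_part[[i]]
  for (e in reorder_postorder(tree)) {
    p <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    Pm <- pfun(lengths[v] * rate)
    contrib <- Pm %*% down[[v]]
    down[[p]] <- if (is.null(down[[p]])) contrib else down[[p]] * contrib
  }
  down
}

# pre-order ("up") partials: up[[v]] (over parent states) is the likelihood
# of all data outside v's subtree, excluding edge (parent, v). Valid for the
# symmetric transition matrices used here.
up_partials <- function(tree, down, lengths, pfun, rate = 1) {
  n_node <- max(tree$edge)
  n_tip <- ape::Ntip(tree)
  root <- n_tip + 1L
  npat <- ncol(down[[1]])
  children <- split(tree$edge[, 2], tree$edge[, 1])
  contrib <- vector("list", n_node)  # P(t_v) %*% down[[v]]
  for (e in seq_len(nrow(tree$edge))) {
    v <- tree$edge[e, 2]
    contrib[[v]] <- pfun(lengths[v] * rate) %*% down[[v]]
  }
  up <- vector("list", n_node)
  up[[root]] <- matrix(1, N_AA, npat)
  for (e in reorder_preorder(tree)) {
    p <- tree$edge[e, 1]; v <- tree$edge[e, 2]
    sib <- setdiff(children[[as.character(p)]], v)
    m <- up_edge <- if (p == root) matrix(1, N_AA, npat) else
      pfun(lengths[p] * rate) %*% up[[p]]
    for (s in sib) m <- m * contrib[[s]]
    up[[v]] <- m
  }
  up
}

#' Exact log-likelihood of an alignment on a tree (pruning algorithm)
#'
#' Computes the exact log-likelihood under a 20-state equal-exchangeability
#' (Poisson) amino-acid model via Felsenstein's post-order recursion. Gaps
#' and ambiguity codes are missing data (partial likelihood 1 for every
#' state); an all-gap column therefore contributes 0. `poisson_gamma`
#' averages site likelihoods over 4 discrete gamma rate categories.
#'
#' @param alignment An amino-acid [mn_alignment].
#' @param tree Rooted `phylo` with branch lengths; tips must match the
#'   alignment taxa.
#' @param model `"poisson"` or `"poisson_gamma"`.
#' @param alpha Gamma shape (poisson_gamma only).
#' @param exchangeability Optional symmetric 20x20 exchangeability matrix
#'   (rows/columns in [AMINO_ACIDS] order) replacing equal exchangeabilities.
#' @return The log-likelihood (a single number).
#' @export
pruning_log_likelihood <- function(alignment, tree,
                                   model = c("poisson", "poisson_gamma"),
                                   alpha = 1, exchangeability = NULL) {
  model <- match.arg(model)
  if (!ncol(alignment)) stop("zero-length alignment")
  if (aln_molecule(alignment) != "amino") stop("amino-acid alignment required")
  if (!setequal(tree$tip.label, aln_taxa(alignment)))
    stop("tree tips and alignment taxa differ")
  pat <- aln_patterns(alignment)
  pfun <- make_transition_fun(exchangeability)
  rates <- if (model == "poisson") 1 else discrete_gamma_rates(alpha, 4L)
  lengths <- numeric(max(tree$edge))
  lengths[tree$edge[, 2]] <- tree$edge.length
  tips_part <- lapply(tree$tip.label, function(tx)
    tip_partials(pat$states[tx, ]))
  n_tip <- ape::Ntip(tree)
  root <- n_tip + 1L
  site_lik <- 0
  for (r in rates) {
    down <- down_partials(tree, tips_part, lengths, pfun, rate = r)
    site_lik <- site_lik + colSums(down[[root]]) / N_AA / length(rates)
  }
  sum(pat$weights * log(site_lik))
}

#' Estimate branch lengths on a fixed topology
#'
#' Maximum-likelihood branch lengths under the Poisson (optionally +gamma)
#' amino-acid model, holding the topology fixed. Each round recomputes the
#' pruning partials and then maximizes each branch length in turn by Brent's
#' 1-D method on \[0, `max_length`\]; rounds repeat until the log-likelihood
#' improves by less than `tol`.
#'
#' @inheritParams pruning_log_likelihood
#' @param topology Rooted `phylo`; existing branch lengths are used as
#'   starting values, otherwise all branches start at 0.1.
#' @param tol Convergence tolerance in log-likelihood units (default 1e-6).
#' @param max_rounds Maximum optimization rounds before a diagnostic error.
#' @param max_length Upper bound per branch (substitutions/site).
#' @param root_edge Under a reversible model only the sum of the two
#'   root-adjacent branch lengths is identifiable. `"balance"` (default)
#'   splits that sum equally after convergence — a deterministic convention;
#'   `"keep"` leaves the arbitrary allocation the optimizer landed on.
#' @return The topology with ML branch lengths and attribute `logLik`.
#' @export
estimate_branch_lengths <- function(alignment, topology,
                                    model = c("poisson", "poisson_gamma"),
                                    alpha = 1, exchangeability = NULL,
                                    tol = 1e-6, max_rounds = 50L,
                                    max_length = 10,
                                    root_edge = c("balance", "keep")) {
  root_edge <- match.arg(root_edge)
  model <- match.arg(model)
  if (!ncol(alignment)) stop("zero-length alignment")
  if (!setequal(topology$tip.label, aln_taxa(alignment)))
    stop("tree tips and alignment taxa differ")
  tree <- topology
  if (is.null(tree$edge.length)) tree$edge.length <- rep(0.1, nrow(tree$edge))
  tree$edge.length[tree$edge.length <= 0] <- 1e-8
  pat <- aln_patterns(alignment)
  pfun <- make_transition_fun(exchangeability)
  rates <- if (model == "poisson") 1 else discrete_gamma_rates(alpha, 4L)
  k <- length(rates)
  tips_part <- lapply(tree$tip.label, function(tx) tip_partials(pat$states[tx, ]))
  n_tip <- ape::Ntip(tree)
  root <- n_tip + 1L
  w <- pat$weights
  edge_child <- tree$edge[, 2]

  loglik_from_down <- function(downs) {
    sl <- 0
    for (ci in seq_len(k)) sl <- sl + colSums(downs[[ci]][[root]]) / N_AA / k
    sum(w * log(sl))
  }

  lengths <- numeric(max(tree$edge))
  lengths[edge_child] <- tree$edge.length
  cur_ll <- -Inf
  for (round in seq_len(max_rounds)) {
    new_ll <- NA_real_
    for (v in edge_child) {
      # fresh partials per edge: each 1-D step is then true coordinate
      # ascent, so the log-likelihood is monotone over rounds
      downs <- lapply(rates, function(r)
        down_partials(tree, tips_part, lengths, pfun, rate = r))
      ups <- lapply(seq_len(k), function(ci)
        up_partials(tree, downs[[ci]], lengths, pfun, rate = rates[ci]))
      if (is.na(new_ll)) new_ll <- loglik_from_down(downs)
      f <- function(t) {
        sl <- 0
        for (ci in seq_len(k)) {
          Pm <- pfun(t * rates[ci])
          sl <- sl + colSums(ups[[ci]][[v]] * (Pm %*% downs[[ci]][[v]])) / N_AA / k
        }
        sum(w * log(sl))
      }
      opt <- stats::optimize(f, c(0, max_length), maximum = TRUE, tol = 1e-8)
      lengths[v] <- if (f(0) >= opt$objective) 0 else opt$maximum
      tree$edge.length <- lengths[edge_child]
    }
    if (is.finite(cur_ll) && new_ll - cur_ll < tol) {
      if (root_edge == "balance") {
        re <- which(tree$edge[, 1] == root)
        if (length(re) == 2)
          tree$edge.length[re] <- mean(tree$edge.length[re])
      }
      attr(tree, "logLik") <- new_ll
      return(tree)
    }
    cur_ll <- new_ll
  }
  final_ll <- pruning_log_likelihood(
    mn_alignment(unclass(alignment), "amino"), tree, model = model,
    alpha = alpha, exchangeability = exchangeability)
  cond <- structure(
    class = c("mn_no_convergence", "error", "condition"),
    message = sprintf(
      "branch-length optimization did not converge in %d rounds (last logLik %.6f)",
      max_rounds, final_ll),
    call = NULL, tree = tree)
  stop(cond)
}
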