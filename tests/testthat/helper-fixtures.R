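# Shared fixtures, built in code.

# four-taxon balanced tree with unit branch lengths
tree4 <- function() ape::read.tree(text = "((A:1,B:1):1,(C:1,D:1):1);")

# a small synthetic PDB coordinate file; returns its path
write_mini_pdb <- function(lines, path = tempfile(fileext = ".pdb")) {
  writeLines(c(lines, "END"), path)
  path
}

pdb_atom <- function(serial, elety, resid, chain, resno, x, y, z,
                     occ = 1.00, record = "ATOM", element = NULL) {
  if (is.null(element)) element <- substr(gsub("[0-9]", "", elety), 1, 1)
  sprintf("%-6s%5d %-4s %3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, elety, resid, chain, resno, x, y, z, occ, 0.00,
          element)
}

# brute-force Fitch parsimony score: minimum changes over all internal
# labelings drawn from the observed states (an optimal labeling never needs
# unobserved states)
brute_force_parsimony <- function(tree, tip_states) {
  states <- sort(unique(tip_states))
  n_tip <- ape::Ntip(tree)
  n_int <- tree$Nnode
  grid <- expand.grid(rep(list(states), n_int), stringsAsFactors = FALSE)
  best <- Inf
  for (i in seq_len(nrow(grid))) {
    lab <- c(tip_states[tree$tip.label], unlist(grid[i, ]))
    changes <- sum(lab[tree$edge[, 1]] != lab[tree$edge[, 2]])
    best <- min(best, changes)
  }
  best
}

# independent NG86 oracle: exhaustive pathway enumeration, written against
# the published counting rules rather than the package internals
oracle_ng86 <- function(seqA, seqB, code = "standard") {
  gc <- mitonuc::genetic_code(code)
  a <- strsplit(toupper(seqA), "")[[1]]
  b <- strsplit(toupper(seqB), "")[[1]]
  nc <- length(a) / 3
  site_count <- function(codon) {
    aa <- gc[[codon]]
    s <- strsplit(codon, "")[[1]]
    syn <- 0
    for (pos in 1:3) {
      alts <- setdiff(c("T", "C", "A", "G"), s[pos])
      t_cod <- vapply(alts, function(n) {
        tt <- s; tt[pos] <- n; paste(tt, collapse = "")
      }, character(1))
      keep <- gc[t_cod] != "*"
      if (any(keep)) syn <- syn + sum(gc[t_cod[keep]] == aa) / sum(keep)
    }
    syn
  }
  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  perms <- function(x) {
    if (length(x) <= 1) return(list(x))
    out <- list()
    for (i in seq_along(x)) for (p in perms(x[-i]))
      out[[length(out) + 1]] <- c(x[i], p)
    out
  }
  for (i in seq_len(nc)) {
    ca <- paste(a[(3 * i - 2):(3 * i)], collapse = "")
    cb <- paste(b[(3 * i - 2):(3 * i)], collapse = "")
    sa <- site_count(ca); sb <- site_count(cb)
    S <- S + (sa + sb) / 2
    N <- N + (3 - sa + 3 - sb) / 2 -
      (stop_frac(ca, gc) + stop_frac(cb, gc)) / 2
    if (ca == cb) next
    pos <- which(strsplit(ca, "")[[1]] != strsplit(cb, "")[[1]])
    counts <- list()
    for (ord in perms(pos)) {
      cur <- strsplit(ca, "")[[1]]; syn <- 0; non <- 0; blocked <- FALSE
      for (p in ord) {
        nxt <- cur; nxt[p] <- strsplit(cb, "")[[1]][p]
        f <- gc[[paste(cur, collapse = "")]]; t <- gc[[paste(nxt, collapse = "")]]
        if (t == "*") { blocked <- TRUE; break }
        if (f == t) syn <- syn + 1 else non <- non + 1
        cur <- nxt
      }
      if (!blocked) counts[[length(counts) + 1]] <- c(syn, non)
    }
    if (length(counts)) {
      m <- do.call(rbind, counts)
      Sd <- Sd + mean(m[, 1]); Nd <- Nd + mean(m[, 2])
    }
  }
  list(S = S, N = N, Sd = Sd, Nd = Nd)
}

stop_frac <- function(codon, gc) {
  s <- strsplit(codon, "")[[1]]
  frac <- 0
  for (pos in 1:3) {
    alts <- setdiff(c("T", "C", "A", "G"), s[pos])
    t_cod <- vapply(alts, function(n) {
      tt <- s; tt[pos] <- n; paste(tt, collapse = "")
    }, character(1))
    n_stop <- sum(gc[t_cod] == "*")
    # a position with stop neighbours still sums to 1 site over its
    # non-stop alternatives, so no site mass is lost unless all are stops
    if (n_stop == 3) frac <- frac + 1
  }
  frac
}

# exhaustive two-sided Fisher P for a 2x2 table by hypergeometric enumeration
oracle_fisher_p <- function(tab) {
  m <- tab[1, 1] + tab[2, 1]
  n <- tab[1, 2] + tab[2, 2]
  k <- tab[1, 1] + tab[1, 2]
  x <- tab[1, 1]
  support <- max(0, k - n):min(k, m)
  probs <- stats::dhyper(support, m, n, k)
  p_obs <- stats::dhyper(x, m, n, k)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}
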