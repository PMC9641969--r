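test_that("the site test matches the one-sided binomial closed form", {
  # 8 nonsynonymous, 0 synonymous changes at a site whose parent codon is
  # always GGG (1 syn site of 3): P = P(X >= 8 | n = 8, p_ns = 2/3).
  # Hand-built reconstruction: every internal node GGG; 8 tip branches end
  # in AGG (G -> R, nonsynonymous), the other tips stay GGG.
  n_ch <- 8
  tr <- ape::rtree(10, br = 1)
  n_node <- max(tr$edge)
  states <- matrix("GGG", n_node, 1)
  states[seq_len(n_ch), 1] <- "AGG"
  ev <- map_substitutions(states, tr)
  expect_equal(nrow(ev), n_ch)
  dummy <- mn_alignment(
    matrix("G", ape::Ntip(tr), 3, dimnames = list(tr$tip.label, NULL)),
    "codon")
  res <- site_selection_test(dummy, tr, 1, states = states)
  expect_equal(res$n_nonsyn, n_ch)
  expect_equal(res$n_syn, 0)
  # GGG -> AGG is G -> R on every branch; p_syn from GGG opportunities
  expect_equal(res$p, (2 / 3)^n_ch, tolerance = 1e-10)
  expect_gt(res$excess, 0)
})

test_that("an invariant site is never selected and has P = 1", {
  tr <- tree4()
  a <- mn_alignment(
    matrix(rep(c("A", "A", "A"), each = 4), 4, 3,
           dimnames = list(tr$tip.label, NULL)), "codon")
  res <- site_selection_test(a, tr, 1)
  expect_equal(res$p, 1)
  expect_false(res$selected)
})

test_that("foreground covering the whole tree equals the unrestricted call", {
  tr <- generate_yule_tree(8, 41)
  bt <- branch_table(tr)
  flat <- stats::setNames(rep(1, nrow(bt)), bt$branch_id)
  sim <- simulate_alignment(tr, flat, 40, "codon",
                            simulation_config(omega_by_geneset = c(g = 1),
                                              base_rate = 0.2, seed = 42),
                            gene_set = "g")
  all_b <- bt$branch_id
  r1 <- scan_site_selection(sim$alignment, tr, gene = "g")
  states <- reconstruct_ancestral(sim$alignment, tr)
  r2 <- vapply(seq_len(nrow(r1)), function(s)
    site_selection_test(sim$alignment, tr, s, foreground = all_b,
                        states = states)$p, numeric(1))
  expect_equal(r1$p, r2)
})

test_that("stringent calls are a subset of selected calls", {
  tr <- generate_yule_tree(10, 43)
  bt <- branch_table(tr)
  flat <- stats::setNames(rep(1, nrow(bt)), bt$branch_id)
  sim <- simulate_alignment(tr, flat, 150, "codon",
                            simulation_config(omega_by_geneset = c(g = 3),
                                              base_rate = 0.15, seed = 44),
                            gene_set = "g")
  scan <- scan_site_selection(sim$alignment, tr, gene = "g")
  expect_true(all(!scan$stringent | scan$selected))
})

test_that("neutral simulations keep the false-positive rate near alpha", {
  flagged <- 0; total <- 0
  for (s in 1:15) {
    tr <- generate_yule_tree(10, 50 + s)
    bt <- branch_table(tr)
    flat <- stats::setNames(rep(1, nrow(bt)), bt$branch_id)
    sim <- simulate_alignment(tr, flat, 80, "codon",
                              simulation_config(omega_by_geneset = c(g = 1),
                                                base_rate = 0.15,
                                                seed = 50 + s),
                              gene_set = "g")
    scan <- scan_site_selection(sim$alignment, tr, gene = "g")
    flagged <- flagged + sum(scan$selected)
    total <- total + nrow(scan)
  }
  expect_lte(flagged / total, 0.10)
})

test_that("positive selection flags more sites than neutrality", {
  # dense regime (about 10 reconstructed changes per codon site) so the
  # counting test has binomial resolution to reject at all
  wins <- 0
  for (s in 1:6) {
    tr <- generate_yule_tree(20, 70 + s)
    bt <- branch_table(tr)
    flat <- stats::setNames(rep(1, nrow(bt)), bt$branch_id)
    frac <- function(om, seed) {
      sim <- simulate_alignment(
        tr, flat, 100, "codon",
        simulation_config(omega_by_geneset = c(g = om), base_rate = 0.6,
                          seed = seed), gene_set = "g")
      mean(scan_site_selection(sim$alignment, tr, gene = "g")$selected)
    }
    if (frac(3, 70 + s) > frac(1, 170 + s)) wins <- wins + 1
  }
  expect_gte(wins, 5)
})

test_that("selected-site proportions are counted per partition", {
  res <- data.frame(gene = "g", site = 1:20,
                    selected = c(rep(TRUE, 2), rep(FALSE, 8),
                                 TRUE, rep(FALSE, 9)))
  part <- stats::setNames(rep(c("contact", "non-contact"), each = 10),
                          as.character(1:20))
  pr <- proportion_selected(res, part)
  expect_equal(pr$proportion[pr$partition == "contact"], 0.2)
  expect_equal(pr$proportion[pr$partition == "non-contact"], 0.1)
  none <- res; none$selected <- FALSE
  expect_true(all(proportion_selected(none, part)$proportion == 0))
})

test_that("contact enrichment reproduces the conditional-MLE odds ratio", {
  selected <- c(rep(TRUE, 20), rep(FALSE, 80), rep(TRUE, 10), rep(FALSE, 90))
  contact <- c(rep(TRUE, 100), rep(FALSE, 100))
  r <- contact_enrichment(selected, contact)
  expect_equal(r$counts["contact", "selected"], 20)
  # independent conditional-MLE oracle: maximize the noncentral
  # hypergeometric likelihood in the odds ratio
  m <- 30; n <- 170; k <- 100; x <- 20
  nll <- function(psi) {
    supp <- max(0, k - n):min(k, m)
    w <- choose(m, supp) * choose(n, k - supp) * psi^supp
    -log(choose(m, x) * choose(n, k - x) * psi^x / sum(w))
  }
  psi_hat <- stats::optimize(nll, c(0.1, 30))$minimum
  expect_equal(r$odds_ratio, psi_hat, tolerance = 1e-3)
  # direction flips when rows are swapped
  r_sw <- contact_enrichment(selected, !contact)
  expect_equal(r_sw$odds_ratio, 1 / r$odds_ratio, tolerance = 1e-6)
  expect_equal(r_sw$p, r$p, tolerance = 1e-10)
})

test_that("frequency-FNM flags rare derived residues only", {
  a <- mn_alignment(c(t1 = "K", t2 = "K", t3 = "K", t4 = "R"), "amino")
  ev <- data.frame(site = 1, to = "W")
  expect_true(flag_functional_nodal(ev, a)$flagged)     # frequency 0
  ev2 <- data.frame(site = 1, to = "K")
  expect_false(flag_functional_nodal(ev2, a)$flagged)   # frequency 0.75
  expect_false(isTRUE(flag_functional_nodal(ev2, a, threshold = 0)$flagged))
  gap <- mn_alignment(c(t1 = "-", t2 = "-"), "amino")
  expect_true(is.na(flag_functional_nodal(ev, gap)$flagged))
})
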