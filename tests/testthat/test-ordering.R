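test_that("fitch reconstruction resolves the four-taxon fixture as stated", {
  tr <- tree4()
  a <- mn_alignment(c(A = "K", B = "K", C = "R", D = "R"), "amino")
  rec <- reconstruct_ancestral(a, tr)
  root <- ape::Ntip(tr) + 1L
  # root ambiguous {K, R}, resolved lexicographically to K
  expect_equal(rec[root, 1], "K")
  expect_equal(attr(rec, "parsimony_score"), 1L)
  ev <- map_substitutions(rec, tr, gene = "g", genome = "mt")
  expect_equal(nrow(ev), 1)
  expect_equal(ev$depth, 1L)
  expect_equal(ev$from, "K")
  expect_equal(ev$to, "R")
})

test_that("invariant and fully missing columns produce no events", {
  tr <- tree4()
  a <- mn_alignment(c(A = "KK-", B = "KK-", C = "KR-", D = "KK-"), "amino")
  rec <- reconstruct_ancestral(a, tr)
  ev <- map_substitutions(rec, tr)
  expect_true(all(ev$site == 2))
  expect_true(all(is.na(rec[, 3])))
  root <- ape::Ntip(tr) + 1L
  expect_equal(unique(rec[root:(root + tr$Nnode - 1L), 1]), "K")
})

test_that("fitch attains the brute-force parsimony score on small fixtures", {
  set.seed(23)
  for (rep in 1:25) {
    n <- sample(4:6, 1)
    tr <- ape::rtree(n)
    tip_states <- stats::setNames(sample(c("K", "R", "Q", "E"), n,
                                         replace = TRUE), tr$tip.label)
    a <- mn_alignment(matrix(tip_states, ncol = 1,
                             dimnames = list(names(tip_states), NULL)),
                      "amino")
    rec <- reconstruct_ancestral(a, tr)
    ev <- map_substitutions(rec, tr)
    expect_equal(nrow(ev), brute_force_parsimony(tr, tip_states))
    expect_equal(unname(attr(rec, "parsimony_score")),
                 brute_force_parsimony(tr, tip_states))
  }
})

test_that("fitch score agrees with phangorn on multi-column data", {
  skip_if_not_installed("phangorn")
  tr <- generate_yule_tree(8, 19)
  bt <- branch_table(tr)
  flat <- stats::setNames(rep(1, nrow(bt)), bt$branch_id)
  sim <- simulate_alignment(tr, flat, 60, "amino",
                            simulation_config(base_rate = 0.3, seed = 20),
                            gene_set = "g")
  rec <- reconstruct_ancestral(sim$alignment, tr)
  m <- unclass(sim$alignment)
  pd <- phangorn::phyDat(m, type = "USER", levels = AMINO_ACIDS)
  expect_equal(sum(attr(rec, "parsimony_score")),
               as.integer(phangorn::fitch(tr, pd)))
})

test_that("marginal ML reconstruction recovers states on clean data", {
  tr <- tree4()
  a <- mn_alignment(c(A = "K", B = "K", C = "R", D = "R"), "amino")
  rec <- reconstruct_ancestral(a, tr, method = "marginal_ml")
  # the two cherry ancestors take their children's shared state
  bt <- branch_table(tr)
  expect_true(all(rec[5:7, 1] %in% c("K", "R")))
  kk_anc <- tr$edge[tr$edge[, 2] == 1, 1]  # parent of tip A
  expect_equal(rec[kk_anc, 1], "K")
})

test_that("substitution mapping recovers most true events at low rates", {
  tr <- generate_yule_tree(15, 27)
  bt <- branch_table(tr)
  flat <- stats::setNames(rep(1, nrow(bt)), bt$branch_id)
  sim <- simulate_alignment(tr, flat, 1000, "amino",
                            simulation_config(base_rate = 0.02, seed = 28),
                            gene_set = "g")
  rec <- reconstruct_ancestral(sim$alignment, tr)
  ev <- map_substitutions(rec, tr)
  truth <- sim$truth$events
  # the two root-adjacent branches are interchangeable event placements
  # under a reversible model (unrooted unidentifiability), so a hit on the
  # sibling root branch counts as recovered
  root_children <- tr$edge[tr$edge[, 1] == ape::Ntip(tr) + 1L, 2]
  equiv <- function(b) if (b %in% root_children) root_children else b
  hit <- 0
  for (i in seq_len(nrow(truth)))
    if (any(ev$site == truth$site[i] &
              ev$branch_id %in% equiv(truth$branch_id[i])))
      hit <- hit + 1
  expect_gt(hit / nrow(truth), 0.9)
})

test_that("pair ordering follows shallowest-event depth on shared paths", {
  # caterpillar tree so depths are easy to stage
  tr <- ape::read.tree(text = "(((((A:1,B:1):1,C:1):1,D:1):1,E:1):1,F:1);")
  bt <- branch_table(tr)
  # pick branches at depth 2 and depth 5 on A's root path
  paths <- mitonuc:::tip_branch_paths(tr)
  pa <- paths[[which(tr$tip.label == "A")]]
  mt_ev <- data.frame(gene = "mt", genome = "mt", site = 1,
                      branch_id = pa[2], depth = 2L, from = "K", to = "R")
  nmt_ev <- data.frame(gene = "n", genome = "nuclear", site = 1,
                       branch_id = pa[5], depth = 5L, from = "A", to = "V")
  rec <- classify_pair_order(mt_ev, nmt_ev,
                             list(pair_id = 1, mt_column = 1, nmt_column = 1),
                             tr)
  expect_equal(rec$classification, "mt_first")
  expect_equal(rec$separation, 3L)
  expect_equal(rec$proximity, "far")
  # same branch
  nmt_same <- nmt_ev; nmt_same$branch_id <- pa[2]; nmt_same$depth <- 2L
  rec2 <- classify_pair_order(mt_ev, nmt_same,
                              list(pair_id = 2, mt_column = 1, nmt_column = 1),
                              tr)
  expect_equal(rec2$classification, "same_branch")
  # events in mutually exclusive clades share no root-to-tip path
  pf <- paths[[which(tr$tip.label == "F")]]
  nmt_f <- nmt_ev; nmt_f$branch_id <- pf[1]; nmt_f$depth <- 1L
  mt_a <- mt_ev; mt_a$branch_id <- pa[5]; mt_a$depth <- 5L
  rec3 <- classify_pair_order(mt_a, nmt_f,
                              list(pair_id = 3, mt_column = 1, nmt_column = 1),
                              tr)
  expect_equal(rec3$classification, "unresolved")
})

test_that("proximity is close at separations 1 and 2, far beyond", {
  rec <- data.frame(classification = "mt_first", separation = 1L)
  expect_equal(proximity(rec), "close")
  rec$separation <- 2L
  expect_equal(proximity(rec), "close")
  rec$separation <- 3L
  expect_equal(proximity(rec), "far")
  expect_error(proximity(data.frame(classification = "same_branch",
                                    separation = NA_integer_)), "mt_first")
})

test_that("ordering chi-square matches the goodness-of-fit closed form", {
  r <- chisq_equal_order(74, 323)
  expect_equal(r$chi_square, 156.17, tolerance = 0.005 / 156)
  expect_lt(r$p, 1e-4)
  expect_equal(chisq_equal_order(50, 50)$chi_square, 0)
  expect_equal(chisq_equal_order(50, 50)$p, 1)
  expect_equal(chisq_equal_order(10, 30)$chi_square, 10)
  expect_error(chisq_equal_order(0, 0), "count")
})

test_that("fisher test matches hypergeometric enumeration", {
  flat <- fisher_mtfirst_enrichment(matrix(c(5, 5, 5, 5), 2, 2))
  expect_equal(flat$odds_ratio, 1, tolerance = 1e-6)
  expect_equal(flat$p, 1)
  diag_ <- fisher_mtfirst_enrichment(matrix(c(10, 0, 0, 10), 2, 2))
  expect_equal(diag_$p, 2 / choose(20, 10), tolerance = 1e-10)
  set.seed(33)
  for (rep in 1:30) {
    tab <- matrix(sample(0:6, 4, replace = TRUE), 2, 2)
    if (sum(tab) == 0) next
    expect_equal(fisher_mtfirst_enrichment(tab)$p, oracle_fisher_p(tab),
                 tolerance = 1e-9)
  }
})

test_that("branch summaries conserve event counts and flag the majority", {
  tr <- generate_yule_tree(12, 31)
  bt <- branch_table(tr)
  flat <- stats::setNames(rep(1, nrow(bt)), bt$branch_id)
  # mt evolves 5x faster than nuclear
  mt <- simulate_alignment(tr, flat, 300, "amino",
                           simulation_config(base_rate = 0.25, seed = 32),
                           gene_set = "mt")
  nmt <- simulate_alignment(tr, flat, 300, "amino",
                            simulation_config(base_rate = 0.05, seed = 33),
                            gene_set = "nmt")
  ev <- rbind(cbind(mt$truth$events, genome = "mt"),
              cbind(nmt$truth$events, genome = "nuclear"))
  bs <- branch_substitution_summary(ev, tr)
  expect_equal(sum(bs$mt_count) + sum(bs$nmt_count), nrow(ev))
  expect_gt(mean(bs$more == "mt"), 0.5)
  empty <- branch_substitution_summary(ev[0, ], tr)
  expect_true(all(empty$mt_count == 0) && all(empty$nmt_count == 0))
})
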