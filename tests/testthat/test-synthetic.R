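test_that("yule trees have the forced shape and are seed-deterministic", {
  t2 <- generate_yule_tree(2, seed = 1)
  expect_equal(ape::Ntip(t2), 2L)
  expect_equal(t2$Nnode, 1L)
  t60 <- generate_yule_tree(60, seed = 7)
  expect_equal(ape::Ntip(t60), 60L)
  expect_equal(t60$Nnode, 59L)
  expect_equal(nrow(t60$edge), 118L)
  expect_true(all(t60$edge.length > 0))
  expect_identical(ape::write.tree(generate_yule_tree(60, 7)),
                   ape::write.tree(t60))
  expect_error(generate_yule_tree(1, 1), "n_taxa")
})

test_that("branch table depths start at 1 below the root", {
  tr <- tree4()
  bt <- branch_table(tr)
  expect_equal(sort(unique(bt$depth)), c(1L, 2L))
  root_children <- bt$branch_id[bt$depth == 1]
  expect_length(root_children, 2L)
})

test_that("branch scalars honour degenerate and perfect coupling", {
  tr <- generate_yule_tree(20, 2)
  s0 <- draw_branch_scalars(tr, rho = 0.5, sd = 0, seed = 3)
  expect_true(all(s0$mt == 1) && all(s0$nmt == 1))
  s1 <- draw_branch_scalars(tr, rho = 1, sd = 0.4, seed = 3)
  expect_equal(s1$mt, s1$nmt)
  expect_error(draw_branch_scalars(tr, rho = 1.2, sd = 1, seed = 1), "rho")
})

test_that("uncoupled scalars are empirically uncorrelated at large n", {
  # 10,000 branches via a large star-like tree
  tr <- star_tree(10000)
  s <- draw_branch_scalars(tr, rho = 0, sd = 0.5, seed = 11)
  expect_lt(abs(cor(log(s$mt), log(s$nmt))), 0.05)
})

test_that("zero branch lengths give identical tips and no events", {
  tr <- tree4()
  tr$edge.length[] <- 0
  bt <- branch_table(tr)
  sc <- stats::setNames(rep(1, nrow(bt)), bt$branch_id)
  sim <- simulate_alignment(tr, sc, 30, "amino",
                            simulation_config(seed = 5), gene_set = "mt")
  m <- unclass(sim$alignment)
  expect_equal(nrow(sim$truth$events), 0L)
  for (tx in rownames(m))
    expect_equal(unname(m[tx, ]), sim$truth$root_seq)
})

test_that("amino event counts follow the Poisson mean", {
  tr <- generate_yule_tree(12, 4)
  bt <- branch_table(tr)
  sc <- stats::setNames(rep(1, nrow(bt)), bt$branch_id)
  mu <- 0.2; S <- 400
  L <- sum(tr$edge.length)
  sim <- simulate_alignment(tr, sc, S, "amino",
                            simulation_config(base_rate = mu, seed = 8),
                            gene_set = "mt")
  expect_lt(abs(nrow(sim$truth$events) - mu * L * S), 3 * sqrt(mu * L * S))
})

test_that("replaying the event log from the root reproduces the tips", {
  tr <- generate_yule_tree(10, 9)
  bt <- branch_table(tr)
  sc <- stats::setNames(rep(1, nrow(bt)), bt$branch_id)
  sim <- simulate_alignment(tr, sc, 100, "amino",
                            simulation_config(base_rate = 0.3, seed = 10),
                            gene_set = "mt")
  # replay: walk each tip's root path applying its events in branch order
  paths <- mitonuc:::tip_branch_paths(tr)
  ev <- sim$truth$events
  for (tip in seq_len(ape::Ntip(tr))) {
    seqs <- sim$truth$root_seq
    for (b in paths[[tip]]) {
      sub <- ev[ev$branch_id == b, ]
      for (k in seq_len(nrow(sub))) seqs[sub$site[k]] <- sub$to[k]
    }
    expect_equal(unname(unclass(sim$alignment)[tr$tip.label[tip], ]), seqs)
  }
})

test_that("tip divergence matches the 20-state closed form", {
  # two taxa at fixed distance: P(diff) = (19/20) (1 - exp(-20/19 d))
  tr <- ape::read.tree(text = "(A:1,B:1);")
  bt <- branch_table(tr)
  sc <- stats::setNames(rep(1, nrow(bt)), bt$branch_id)
  mu <- 0.15; S <- 4000
  sim <- simulate_alignment(tr, sc, S, "amino",
                            simulation_config(base_rate = mu, seed = 12),
                            gene_set = "mt")
  m <- unclass(sim$alignment)
  p_obs <- mean(m["A", ] != m["B", ])
  p_exp <- 19 / 20 * (1 - exp(-20 / 19 * (2 * mu)))
  expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / S))
})

test_that("codon mode with omega 0 never logs a nonsynonymous event", {
  tr <- generate_yule_tree(8, 2)
  bt <- branch_table(tr)
  sc <- stats::setNames(rep(1, nrow(bt)), bt$branch_id)
  sim <- simulate_alignment(
    tr, sc, 150, "codon",
    simulation_config(omega_by_geneset = c(mt = 0), base_rate = 0.3, seed = 3),
    gene_set = "mt")
  gc <- genetic_code("standard")
  expect_gt(nrow(sim$truth$events), 0)
  expect_true(all(gc[sim$truth$events$from] == gc[sim$truth$events$to]))
})

test_that("identical configs give identical alignments and logs", {
  tr <- generate_yule_tree(8, 2)
  bt <- branch_table(tr)
  sc <- stats::setNames(rep(1, nrow(bt)), bt$branch_id)
  cfg <- simulation_config(base_rate = 0.2, seed = 42)
  s1 <- simulate_alignment(tr, sc, 60, "amino", cfg, gene_set = "mt")
  s2 <- simulate_alignment(tr, sc, 60, "amino", cfg, gene_set = "mt")
  expect_identical(unclass(s1$alignment), unclass(s2$alignment))
  expect_identical(s1$truth$events, s2$truth$events)
})

test_that("a missing branch scalar is a configuration error", {
  tr <- tree4()
  expect_error(
    simulate_alignment(tr, c("5" = 1), 10, "amino", simulation_config(seed = 1)),
    "missing scalar")
})

test_that("independent compensatory processes are order-symmetric", {
  tr <- generate_yule_tree(30, 6)
  cfg <- simulation_config(n_taxa = 30, base_rate = 0.1,
                           compensation_boost_beta = 1,
                           compensation_direction = "none", seed = 6)
  sim <- simulate_compensatory_pairs(tr, 1000, cfg)
  lab <- sim$truth$labels$label
  n_mt <- sum(lab == "mt_first"); n_nmt <- sum(lab == "nmt_first")
  expect_gt(n_mt + n_nmt, 200)
  expect_lt(abs(n_mt / (n_mt + n_nmt) - 0.5), 0.05)
  expect_error(simulate_compensatory_pairs(tr, 0, cfg), "n_pairs")
})

test_that("a strong mt-trigger boost makes mt-first labels dominate", {
  tr <- generate_yule_tree(30, 5)
  cfg <- simulation_config(n_taxa = 30, base_rate = 0.03,
                           compensation_boost_beta = 50,
                           compensation_direction = "mt_triggers_n", seed = 5)
  sim <- simulate_compensatory_pairs(tr, 400, cfg)
  lab <- sim$truth$labels$label
  n_mt <- sum(lab == "mt_first"); n_nmt <- sum(lab == "nmt_first")
  expect_gt(n_mt / (n_mt + n_nmt), 0.8)
})

test_that("simulation config enforces its bounds", {
  expect_error(simulation_config(rate_coupling_rho = 1.5), "rho")
  expect_error(simulation_config(scalar_sd = -1), "scalar_sd")
  expect_error(simulation_config(compensation_boost_beta = 0.5), "beta")
  expect_error(simulation_config(kappa = 0), "kappa")
})
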