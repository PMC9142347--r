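test_that("degenerate configurations reproduce the grand mean exactly", {
  vc0 <- c(G = 0, L = 0, A = 0, LA = 0, block = 0, row = 0, col = 0,
           GL = 0, GA = 0, GLA = 0, error = 0)
  sim <- simulate_met(met_sim_config(n_genotypes = 6, n_locations = 2,
                                     n_years = 2, n_replicates = 2,
                                     mu = 100, varcomp = vc0, seed = 5))
  expect_true(all(sim$plots$value == 100))
})

test_that("simulation is deterministic under the seed and substreams are stable", {
  cfg <- met_sim_config(n_genotypes = 8, n_years = 2, n_replicates = 2,
                        seed = 42)
  s1 <- simulate_met(cfg)
  s2 <- simulate_met(cfg)
  expect_identical(s1$plots, s2$plots)
  expect_identical(s1$truth, s2$truth)
  # genotype effect draws do not depend on the number of replicates
  cfg3 <- met_sim_config(n_genotypes = 8, n_years = 2, n_replicates = 3,
                         seed = 42)
  expect_identical(simulate_met(cfg3)$truth$G, s1$truth$G)
})

test_that("drawn genotype effects have the configured variance", {
  # 500 draws at sigma2_G = 4: sample variance within 15% (chi-square CI)
  cfg <- met_sim_config(n_genotypes = 500, n_locations = 1, n_years = 1,
                        n_replicates = 1,
                        varcomp = c(G = 4, L = 0, A = 0, LA = 0, block = 0,
                                    row = 0, col = 0, GL = 0, GA = 0,
                                    GLA = 0, error = 0),
                        mu = 100, seed = 9)
  sim <- simulate_met(cfg)
  expect_lt(abs(var(sim$truth$G) - 4) / 4, 0.15)
})

test_that("selection funnel retains exactly the configured genotype counts", {
  cfg <- met_sim_config(n_genotypes = 20, n_locations = 2, n_years = 4,
                        n_replicates = 2, funnel = c(20L, 15L, 10L, 6L),
                        seed = 3)
  sim <- simulate_met(cfg)
  counts <- tapply(sim$plots$genotype, sim$plots$year,
                   function(g) length(unique(g)))
  expect_equal(as.integer(counts), c(20L, 15L, 10L, 6L))
  # genotype sets are nested: later years are subsets of earlier ones
  sets <- tapply(sim$plots$genotype, sim$plots$year, unique)
  for (i in 2:4) expect_true(all(sets[[i]] %in% sets[[i - 1]]))
  # invalid funnels are rejected
  expect_error(met_sim_config(n_genotypes = 20, n_years = 4,
                              funnel = c(20L, 15L, 16L, 6L)),
               "non-increasing")
})

test_that("augmented layout repeats checks within blocks and keeps positions unique", {
  cfg <- met_sim_config(n_genotypes = 10, n_locations = 1, n_years = 1,
                        n_replicates = 2, design = "augmented_alpha",
                        check_ids = c("chkA", "chkB"), seed = 2)
  sim <- simulate_met(cfg)
  p <- sim$plots
  one_block <- p[p$block == "b1", ]
  expect_equal(sum(one_block$genotype == "chkA"), 2L)
  expect_equal(sum(one_block$genotype == "g01"), 1L)
  expect_false(anyDuplicated(p[c("location", "year", "row", "column")]) > 0)
})

test_that("score simulation clips to scale and reports the clipped fraction", {
  s <- simulate_scores(n_evaluators = 4, n_genotypes = 5,
                       sigma2_evaluator = 0, sigma2_error = 0, mu = 7,
                       genotype_effects = rep(0, 5), seed = 1)
  expect_true(all(s$scores$score == 7))
  expect_equal(s$clip_fraction, 0)

  s2 <- simulate_scores(n_evaluators = 4, n_genotypes = 5,
                        sigma2_evaluator = 0, sigma2_error = 25, mu = 7,
                        genotype_effects = rep(0, 5), seed = 1)
  expect_true(all(s2$scores$score >= 1 & s2$scores$score <= 10))
  expect_gt(s2$clip_fraction, 0)
})

test_that("FW simulator honours its generative equation", {
  slopes <- c(0.6, 1.0, 1.4)                 # mean 1
  s <- simulate_fw(3, 5, slopes, mu = 10, noise_sd = 0, seed = 4)
  x <- unclass(s$blues)
  # y_ij - mu - g_i equals beta_i * E_j exactly
  for (i in 1:3)
    expect_equal(unname(x[i, ] - 10 - s$truth$g[i]),
                 unname(slopes[i] * s$truth$env), tolerance = 1e-12)
  expect_equal(mean(s$truth$env), 0, tolerance = 1e-12)
})
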