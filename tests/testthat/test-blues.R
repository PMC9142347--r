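test_that("balanced complete RCBD BLUEs are the arithmetic genotype means", {
  g_eff <- setNames(c(-20, 0, 15, 30, -5), sprintf("g%02d", 1:5))
  p <- rcbd_plots(g_eff, block_eff = c(-10, 5, 5), noise_sd = 8, seed = 2)
  b <- estimate_blues(p, "yield_kg_ha", "locA", 2020, spatial = "none")
  means <- tapply(p$value, p$genotype, mean)
  expect_equal(b$blue, as.numeric(means[b$genotype]), tolerance = 1e-10)
})

test_that("single unreplicated plots come back unchanged", {
  df <- data.frame(genotype = sprintf("g%02d", 1:4), location = "locA",
                   year = 2020L, block = "b1", row = 1L, column = 1:4,
                   trait = "yield_kg_ha", value = c(100, 120, 90, 110))
  p <- met_plots(df)
  # saturated fit: SEs are undefined (0 residual df), estimates exact
  b <- suppressWarnings(
    estimate_blues(p, "yield_kg_ha", "locA", 2020, spatial = "none"))
  expect_equal(b$blue, c(100, 120, 90, 110), tolerance = 1e-10)
})

test_that("augmented-design BLUEs match the dense GLS oracle on a 12-plot toy", {
  # 2 checks replicated in each of 3 blocks, 6 unreplicated entries,
  # a strong additive block effect to be corrected through the checks
  set.seed(12)
  blocks <- sprintf("b%d", 1:3)
  block_eff <- c(b1 = -30, b2 = 0, b3 = 30)
  g_eff <- c(chk1 = 0, chk2 = 25,
             setNames(rnorm(6, 0, 15), sprintf("e%02d", 1:6)))
  rows <- list()
  entries <- split(sprintf("e%02d", 1:6), rep(1:3, each = 2))
  for (b in 1:3) {
    gen <- c("chk1", "chk2", entries[[b]])
    rows[[b]] <- data.frame(genotype = gen, location = "locA",
                            year = 2020L, block = blocks[b], row = b,
                            column = seq_along(gen),
                            trait = "yield_kg_ha",
                            value = 500 + g_eff[gen] + block_eff[b] +
                              rnorm(4, 0, 4))
  }
  p <- met_plots(do.call(rbind, rows))
  fit <- estimate_blues(p, "yield_kg_ha", "locA", 2020, spatial = "none")

  d <- as.data.frame(p)
  d <- d[order(d$genotype), ]
  X <- model.matrix(~0 + genotype, d)
  Z <- model.matrix(~0 + block, d)
  vc <- attr(fit, "varcomp")
  or <- gls_oracle(d$value, X, list(Z), vc["block"], vc["residual"])
  expect_equal(fit$blue, unname(or$tau), tolerance = 1e-6)
  expect_equal(fit$se, unname(sqrt(diag(or$cov))), tolerance = 1e-6)
})

test_that("genotypes absent from the environment are reported, not imputed", {
  g_eff <- setNames(c(0, 10, 20), sprintf("g%02d", 1:3))
  p <- rcbd_plots(g_eff, block_eff = c(0, 0), noise_sd = 1, seed = 3)
  b <- estimate_blues(p, "yield_kg_ha", "locA", 2020, spatial = "none",
                      genotypes = c(names(g_eff), "g99"))
  expect_equal(attr(b, "excluded"), "g99")
  expect_false("g99" %in% b$genotype)
})

test_that("AIC tie-breaking prefers the smaller model and skips failed fits", {
  choose <- metstab:::choose_candidate
  expect_equal(choose(c(10, 10, 11, 12), c(2, 1, 2, 3)), 2L)
  expect_equal(choose(c(10, 10 + 5e-10, 11, 12), c(1, 0, 2, 3)), 2L)
  expect_equal(choose(c(NA, 7, 6.5, NA), c(0, 1, 2, 3)), 3L)
  expect_error(choose(c(NA, NA), c(0, 1)), "all candidate models failed")
})

test_that("spatial-term selection tracks the generating process", {
  # study-scale single trial: 50 genotypes x 3 complete blocks
  n_trials <- 200L
  base_vc <- c(G = 100, L = 0, A = 0, LA = 0, block = 25, row = 0, col = 0,
               GL = 0, GA = 0, GLA = 0, error = 50)
  run_one <- function(vc, seed) {
    cfg <- met_sim_config(n_genotypes = 50, n_locations = 1, n_years = 1,
                          n_replicates = 3, varcomp = vc, mu = 100,
                          seed = seed)
    sim <- simulate_met(cfg)
    sel <- suppressWarnings(
      select_spatial_terms(sim$plots, "yield_kg_ha", "loc1", 2017))
    # derive the stricter LRT decision from the same candidate fits
    lrt <- sel$table$spatial[metstab:::choose_candidate_lrt(sel$table,
                                                            0.05)]
    c(aic = sel$spatial, lrt = lrt)
  }
  null_sel <- vapply(seq_len(n_trials), function(s)
    run_one(base_vc, 1000 + s), c(aic = "", lrt = ""))
  # AIC's penalty of 2 tolerates ~15% spurious inclusion under the null
  # (boundary chi-bar-square); the LRT mode holds the 90% line
  expect_gte(mean(null_sel["aic", ] == "none"), 0.75)
  expect_gte(mean(null_sel["lrt", ] == "none"), 0.90)

  # row variance as large as the residual: the row term should be found
  row_vc <- base_vc; row_vc["row"] <- 50
  row_sel <- vapply(seq_len(n_trials), function(s)
    run_one(row_vc, 2000 + s), c(aic = "", lrt = ""))
  expect_gte(mean(row_sel["aic", ] %in% c("row", "row+col")), 0.90)
})
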