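test_that("FW on a hand-worked table gives slope 1, R2 1 for both genotypes", {
  vals <- matrix(c(10, 30, 20, 40, 30, 50), 2, 3,
                 dimnames = list(c("g01", "g02"),
                                 env_label("loc1", 2001:2003)))
  fw <- finlay_wilkinson(blue_matrix(vals))
  expect_equal(unname(attr(fw, "env_index")), c(-10, 0, 10))
  expect_equal(fw$slope, c(1, 1), tolerance = 1e-12)
  expect_equal(fw$r_squared, c(1, 1), tolerance = 1e-12)
  expect_equal(fw$mean, c(20, 40))
})

test_that("noise-free FW simulation is recovered exactly", {
  slopes <- c(0.5, 0.8, 1.0, 1.2, 1.5)        # mean 1
  s <- simulate_fw(5, 8, slopes, mu = 100, noise_sd = 0, seed = 6)
  fw <- finlay_wilkinson(s$blues)
  expect_equal(fw$slope, slopes, tolerance = 1e-10)
  expect_equal(fw$r_squared, rep(1, 5), tolerance = 1e-10)
  # all slopes 1, no noise: purely additive table, every W is 0
  s1 <- simulate_fw(5, 8, rep(1, 5), mu = 100, noise_sd = 0, seed = 6)
  w <- wricke_ecovalence(s1$blues)
  expect_equal(w$w, rep(0, 5), tolerance = 1e-16)
})

test_that("a genotype constant across environments has slope 0 (static)", {
  vals <- rbind(g01 = c(50, 50, 50, 50),
                g02 = c(20, 40, 60, 80),
                g03 = c(10, 50, 70, 90))
  colnames(vals) <- env_label("loc1", 2001:2004)
  fw <- finlay_wilkinson(blue_matrix(vals))
  expect_equal(fw$slope[fw$genotype == "g01"], 0, tolerance = 1e-12)
  expect_equal(fw$class[fw$genotype == "g01"], "static")
})

test_that("FW slopes average one and residuals are orthogonal to the index", {
  b <- random_blue_table(12, 7, seed = 14, sd = 5)
  fw <- finlay_wilkinson(b)
  expect_equal(mean(fw$slope), 1, tolerance = 1e-10)
  expect_equal(sum(fw$slope - 1), 0, tolerance = 1e-9)
  idx <- attr(fw, "env_index")
  x <- unclass(b)
  for (i in seq_len(nrow(x))) {
    res <- x[i, ] - fw$intercept[i] - fw$slope[i] * idx
    expect_lt(abs(sum(res * idx)), 1e-8)
  }
})

test_that("sensitivity bands classify as documented", {
  expect_equal(classify_sensitivity(0.79), "sub-sensitive")
  expect_equal(classify_sensitivity(1.0), "dynamic")
  expect_equal(classify_sensitivity(2.0), "hypersensitive")
  expect_equal(classify_sensitivity(0.2), "static")
  expect_equal(classify_sensitivity(1.2), "dynamic")  # inclusive upper edge
  expect_error(classify_sensitivity(1, bands = c(1, 0.5, 2)), "ordered")
})

test_that("ecovalence is zero for additive tables and 0.5 each on the 2x2 swap", {
  b <- additive_blue_table(g = c(0, 5, 9, 14), e = c(-3, 0, 3, 8, 12))
  w <- wricke_ecovalence(b)
  expect_equal(w$w, rep(0, 4), tolerance = 1e-16)

  swap <- matrix(c(0, 1, 1, 0), 2, 2,
                 dimnames = list(c("g01", "g02"),
                                 env_label("loc1", 2001:2002)))
  w2 <- wricke_ecovalence(blue_matrix(swap))
  expect_equal(w2$w, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(attr(w2, "total"), interaction_ss_oracle(swap),
               tolerance = 1e-12)
})

test_that("total ecovalence equals the ANOVA interaction sum of squares", {
  x <- unclass(random_blue_table(5, 6, seed = 23, sd = 3))
  w <- wricke_ecovalence(blue_matrix(x))
  expect_equal(attr(w, "total"), interaction_ss_oracle(x),
               tolerance = 1e-10)
  # duplicated genotype rows get identical W
  x2 <- rbind(x, g99 = x[2, ])
  w2 <- wricke_ecovalence(blue_matrix(x2))
  expect_equal(w2$w[w2$genotype == "g99"], w2$w[w2$genotype == "g02"],
               tolerance = 1e-10)
})

test_that("ecovalence is invariant to additive shifts and scales as c^2", {
  x <- unclass(random_blue_table(6, 5, seed = 31))
  w0 <- wricke_ecovalence(blue_matrix(x))$w
  shifted <- x + outer(rnorm(6), rep(1, 5)) + outer(rep(1, 6), rnorm(5))
  expect_equal(wricke_ecovalence(blue_matrix(shifted))$w, w0,
               tolerance = 1e-8)
  fw0 <- finlay_wilkinson(blue_matrix(x))
  scaled <- blue_matrix(x * 3)
  expect_equal(wricke_ecovalence(scaled)$w, 9 * w0, tolerance = 1e-8)
  fw3 <- finlay_wilkinson(scaled)
  expect_equal(fw3$slope, fw0$slope, tolerance = 1e-10)
  expect_equal(fw3$r_squared, fw0$r_squared, tolerance = 1e-10)
})

test_that("environment drops validate and feed the reduced re-analysis", {
  b <- random_blue_table(6, 10, seed = 40)
  expect_identical(drop_environments(b, character()), b)
  red <- drop_environments(b, colnames(b)[c(2, 9)])
  expect_equal(ncol(red), 8L)
  expect_equal(rownames(red), rownames(b))
  expect_error(drop_environments(b, "nowhere:1999"), "not present")
  expect_error(drop_environments(b, colnames(b)[1:8]), "fewer than 3")

  # inflating two environments perturbs slopes; the reduced analysis
  # reports a rank correlation against the full one
  slopes <- seq(0.7, 1.3, length.out = 10)
  s <- simulate_fw(10, 8, slopes, mu = 100, env_sd = 5, noise_sd = 1,
                   seed = 50)
  x <- unclass(s$blues)
  x[, 7:8] <- x[, 7:8] + 40
  full <- finlay_wilkinson(blue_matrix(x))
  red2 <- finlay_wilkinson(drop_environments(blue_matrix(x),
                                             colnames(x)[7:8]))
  rho <- cor(full$slope, red2$slope, method = "spearman")
  expect_true(is.finite(rho))
  tab <- stability_table(blue_matrix(x), drop = colnames(x)[7:8])
  expect_true(all(c("slope", "w", "slope_reduced", "w_reduced") %in%
                    names(tab)))
})
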