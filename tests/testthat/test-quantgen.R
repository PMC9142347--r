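test_that("variance shares partition the total genetic variance", {
  expect_equal(unname(variance_proportions(
    c(G = 1, GL = 1, GA = 1, GLA = 1))), rep(0.25, 4))
  expect_equal(unname(variance_proportions(
    c(G = 2, GL = 0, GA = 0, GLA = 2))), c(0.5, 0, 0, 0.5))
  sh <- variance_proportions(c(G = 5.4, GL = 0.9, GA = 1.2, GLA = 2.5,
                               L = 99, residual = 99))
  expect_equal(unname(sh[c("G", "GLA")]), c(0.54, 0.25))
  expect_equal(sum(sh), 1, tolerance = 1e-12)
  # scale invariance
  v <- c(G = 2.2, GL = 0.4, GA = 1.1, GLA = 0.8)
  expect_equal(variance_proportions(v * 7.3), variance_proportions(v),
               tolerance = 1e-12)
  expect_error(variance_proportions(c(G = 0, GL = 0, GA = 0, GLA = 0)),
               "> 0")
})

test_that("harmonic means behave as on the stated cases", {
  expect_equal(harmonic_mean(c(2, 3, 6)), 3)
  expect_equal(harmonic_mean(rep(4, 9)), 4)
  expect_equal(harmonic_mean(c(1, 4)), 1.6)
  expect_error(harmonic_mean(c(2, 0)), "positive")
  expect_error(harmonic_mean(numeric(0)), "empty")
})

balanced_incidence <- function(ng, nl, ny, r) {
  inc <- expand.grid(genotype = sprintf("g%02d", seq_len(ng)),
                     location = sprintf("loc%d", seq_len(nl)),
                     year = 2000L + seq_len(ny), stringsAsFactors = FALSE)
  inc$n <- r
  inc
}

test_that("heritability reproduces its closed forms", {
  # single environment, balanced r = 4: H2 = 1 / (1 + 1/4)
  h <- heritability(c(G = 1, residual = 1),
                    incidence = balanced_incidence(10, 1, 1, 4))
  expect_equal(h$H2, 0.8, tolerance = 1e-12)

  # zero genotypic variance
  h0 <- heritability(c(G = 0, residual = 1),
                     incidence = balanced_incidence(10, 1, 1, 4))
  expect_equal(h0$H2, 0)

  # full model, hand-computed: 2 / (2 + 1/5 + 1/2 + 2/10 + 4/30)
  h2 <- heritability(c(G = 2, GA = 1, GL = 1, GLA = 2, residual = 4),
                     incidence = balanced_incidence(12, 2, 5, 3))
  expect_equal(h2$n_a, 5); expect_equal(h2$n_l, 2)
  expect_equal(h2$n_al, 10); expect_equal(h2$n_alr, 30)
  expect_equal(h2$H2, 2 / (2 + 0.2 + 0.5 + 0.2 + 4 / 30),
               tolerance = 1e-12)
})

test_that("heritability is monotone in its variance components", {
  inc <- balanced_incidence(10, 2, 3, 2)
  grid_g <- seq(0.2, 5, length.out = 12)
  h_of_g <- vapply(grid_g, function(g)
    heritability(c(G = g, GA = 1, GL = 1, GLA = 1, residual = 2),
                 incidence = inc)$H2, 1)
  expect_true(all(diff(h_of_g) > 0))
  for (comp in c("GA", "GL", "GLA", "residual")) {
    h_of_c <- vapply(seq(0.1, 4, length.out = 10), function(v) {
      vc <- c(G = 1.5, GA = 1, GL = 1, GLA = 1, residual = 2)
      vc[comp] <- v
      heritability(vc, incidence = inc)$H2
    }, 1)
    expect_true(all(diff(h_of_c) < 0))
  }
})

test_that("FHB scoring follows the incidence x severity definition", {
  z <- fhb_scores(rep(0L, 20))
  expect_equal(c(z$incidence, z$severity, z$index), c(0, 0, 0))
  f <- fhb_scores(rep(5L, 20))
  expect_equal(c(f$incidence, f$severity, f$index), c(100, 100, 100))
  half <- fhb_scores(rep(c(0L, 5L), each = 10),
                     severity_map = c(`0` = 0, `1` = 20, `2` = 40,
                                      `3` = 60, `4` = 80, `5` = 100))
  expect_equal(half$incidence, 50)
  expect_equal(half$severity, 50)
  expect_equal(half$index, 25)
  # with every spike infected, the index degenerates to the severity
  m <- c(`0` = 0, `1` = 30, `2` = 40, `3` = 60, `4` = 80, `5` = 100)
  x <- fhb_scores(rep(1L, 20), severity_map = m)
  expect_equal(x$incidence, 100)
  expect_equal(x$index, x$severity)
  expect_error(fhb_scores(rep(6L, 20)), "0-5")
  expect_error(fhb_scores(rep(1L, 19)), "expected 20")
})

test_that("selection filters use strict boundaries and keep top-n ties", {
  v <- setNames(c(1, 2, 3, 4), letters[1:4])
  expect_equal(as.character(percentile_select(v, "above_percentile", 50)),
               c("c", "d"))
  fhb <- setNames(c(10, 14.9, 15, 20), c("f1", "f2", "f3", "f4"))
  expect_equal(as.character(percentile_select(fhb, "below_threshold", 15)),
               c("f1", "f2"))
  set.seed(8)
  prot <- setNames(runif(98, 9, 13), sprintf("f%03d", 1:98))
  top <- percentile_select(prot, "top_n", 50)
  expect_length(top, 50)
  expect_true(all(prot[top] >= sort(prot, decreasing = TRUE)[50]))
  # boundary ties are all retained and reported
  tied <- setNames(c(5, 4, 4, 1), c("a", "b", "c", "d"))
  t2 <- percentile_select(tied, "top_n", 2)
  expect_equal(sort(as.character(t2)), c("a", "b", "c"))
  expect_equal(sort(attr(t2, "boundary")), c("b", "c"))
})
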