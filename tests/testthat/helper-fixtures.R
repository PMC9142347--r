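# Shared fixture builders. All fixtures are generated in code; no data
# files are read from disk except those a test writes itself.

# balanced RCBD in one environment with known additive genotype and block
# effects laid out on a simple grid (one block per row band)
rcbd_plots <- function(g_eff, block_eff, mu = 100, noise_sd = 0,
                       location = "locA", year = 2020L, seed = 1L,
                       trait = "yield_kg_ha") {
  ng <- length(g_eff); nb <- length(block_eff)
  if (is.null(names(g_eff))) names(g_eff) <- sprintf("g%02d", seq_len(ng))
  set.seed(seed)
  df <- do.call(rbind, lapply(seq_len(nb), function(b) {
    data.frame(genotype = names(g_eff), location = location, year = year,
               block = sprintf("b%d", b), row = b, column = seq_len(ng),
               trait = trait,
               value = mu + g_eff + block_eff[b] + rnorm(ng, 0, noise_sd),
               stringsAsFactors = FALSE)
  }))
  met_plots(df)
}

# small complete genotype x environment table with reproducible values
random_blue_table <- function(ng, ne, seed = 1L, sd = 1) {
  set.seed(seed)
  vals <- matrix(rnorm(ng * ne, 0, sd), ng, ne,
                 dimnames = list(sprintf("g%02d", seq_len(ng)),
                                 env_label("loc1", 2000L + seq_len(ne))))
  blue_matrix(vals)
}

# additive (no-interaction) table g_i + e_j
additive_blue_table <- function(g, e) {
  vals <- outer(g, e, `+`)
  dimnames(vals) <- list(sprintf("g%02d", seq_along(g)),
                         env_label("loc1", 2000L + seq_along(e)))
  blue_matrix(vals)
}

# independent oracle: interaction sum of squares of a complete two-way
# table, via the residual SS of the additive fixed-effects ANOVA
interaction_ss_oracle <- function(x) {
  d <- expand.grid(g = rownames(x), e = colnames(x))
  d$y <- as.vector(x)
  anova(lm(y ~ g + e, data = d))["Residuals", "Sum Sq"]
}

# independent oracle: dense GLS solve of y = X tau + Zu + e at given
# variances; returns the fixed-effect estimates and their covariance
gls_oracle <- function(y, X, Z_list, sigma2, sigma2_e) {
  V <- diag(sigma2_e, length(y))
  for (i in seq_along(Z_list))
    V <- V + sigma2[i] * tcrossprod(Z_list[[i]])
  Vi <- solve(V)
  XtVi <- crossprod(X, Vi)
  cov_tau <- solve(XtVi %*% X)
  list(tau = drop(cov_tau %*% XtVi %*% y), cov = cov_tau)
}

expect_rel_equal <- function(x, y, tol) {
  expect_lt(max(abs(x - y) / pmax(abs(y), 1e-300)), tol)
}
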