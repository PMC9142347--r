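# Dunnett many-to-one comparison of genotypes against a named check within
# one trial. The trial model is the design-correction model without spatial
# terms; block enters as a fixed nuisance term, under which the exact
# multivariate-t theory of the Dunnett adjustment applies (for balanced
# blocks the genotype contrasts are identical to the random-block fit).
# The k-variate t integrals are evaluated by mvtnorm with fixed quadrature
# settings and a fixed internal RNG state, so p-values are reproducible
# bit for bit.

with_fixed_rng <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

.dunnett_quad <- function() mvtnorm::GenzBretz(abseps = 1e-4,
                                               maxpts = 1e5, releps = 0)
.dunnett_rng_seed <- 290411L

# two-sided familywise-adjusted p for |t| under a k-variate t with corr R
dunnett_p_adjust <- function(tval, df, R) {
  k <- nrow(R)
  vapply(abs(tval), function(a) {
    if (!is.finite(a)) return(0)
    if (k == 1L) return(2 * pt(-a, df))
    inside <- with_fixed_rng(.dunnett_rng_seed,
      mvtnorm::pmvt(lower = rep(-a, k), upper = rep(a, k), df = df,
                    corr = R, algorithm = .dunnett_quad()))
    max(0, min(1, 1 - as.numeric(inside)))
  }, 1)
}

# two-sided Dunnett critical point: P(max_j |T_j| <= q) = 1 - alpha
dunnett_quantile <- function(alpha, df, R) {
  k <- nrow(R)
  if (k == 1L) return(qt(1 - alpha / 2, df))
  with_fixed_rng(.dunnett_rng_seed,
    as.numeric(mvtnorm::qmvt(1 - alpha, tail = "both.tails", df = df,
                             corr = R, algorithm = .dunnett_quad())$quantile))
}

#' Dunnett comparison of genotypes against a check
#'
#' Compares every genotype's mean to a named check cultivar within one
#' trial, controlling the familywise error rate through the joint
#' multivariate-t distribution of the contrasts (two-sided). Genotypes
#' significantly above the check are labelled `"A"`, significantly below
#' `"B"`, all others `"ns"`; the check's own row has difference 0 and
#' label `"ns"`. Both the per-mean and per-difference standard errors are
#' reported, along with the critical difference at `alpha`.
#'
#' @param data a [met_plots] table (optionally pre-subset) or any data
#'   frame with columns `genotype`, `block`, `value`.
#' @param trait trait name (used when `data` is a [met_plots] table).
#' @param location,year optional environment selectors.
#' @param check genotype id of the check cultivar.
#' @param alpha familywise significance level (default 0.05).
#' @return Object of class `dunnett`: a data frame per genotype (`genotype`,
#'   `mean`, `se_mean`, `diff`, `se_diff`, `t`, `p_unadj`, `p_adj`,
#'   `label`) with attributes `check`, `alpha`, `df` (residual degrees of
#'   freedom -- small in lightly replicated on-farm trials, and reported
#'   for that reason), `crit` (the Dunnett quantile), and
#'   `critical_difference` (quantile times the median per-difference SE).
#' @export
dunnett_test <- function(data, trait = NULL, location = NULL, year = NULL,
                         check, alpha = 0.05) {
  if (inherits(data, "met_plots")) {
    d <- as.data.frame(data)
    if (!is.null(trait)) d <- d[d$trait == trait, , drop = FALSE]
    if (!is.null(location)) d <- d[d$location == location, , drop = FALSE]
    if (!is.null(year)) d <- d[d$year == as.integer(year), , drop = FALSE]
  } else d <- as.data.frame(data)
  d <- d[!is.na(d$value), , drop = FALSE]
  if (!nrow(d)) stop("no observations", call. = FALSE)
  gens <- sort(unique(d$genotype))
  if (!check %in% gens)
    stop("check '", check, "' absent from the trial", call. = FALSE)
  if (length(gens) < 2L) stop("need >= 2 genotypes", call. = FALSE)
  d$genotype <- factor(d$genotype, levels = gens)
  has_block <- "block" %in% names(d) && length(unique(d$block)) > 1L
  fml <- if (has_block) value ~ genotype + factor(block) else
    value ~ genotype
  fit <- lm(fml, data = d)
  df <- df.residual(fit)
  if (df < 1L)
    stop("no residual degrees of freedom (single replicate overall)",
         call. = FALSE)

  # genotype means at equal block weights, via the cell-means contrast
  X <- model.matrix(fit)
  b <- coef(fit)
  Vb <- vcov(fit)
  Lmk <- matrix(0, length(gens), length(b),
                dimnames = list(gens, names(b)))
  Lmk[, "(Intercept)"] <- 1
  for (g in gens[-1]) Lmk[g, paste0("genotype", g)] <- 1
  if (has_block) {
    bl_cols <- grep("^factor\\(block\\)", names(b))
    Lmk[, bl_cols] <- 1 / length(unique(d$block))
  }
  means <- drop(Lmk %*% b)
  se_mean <- sqrt(diag(Lmk %*% Vb %*% t(Lmk)))

  others <- setdiff(gens, check)
  C <- Lmk[others, , drop = FALSE] -
    matrix(Lmk[check, ], length(others), ncol(Lmk), byrow = TRUE)
  dif <- drop(C %*% b)
  Vd <- C %*% Vb %*% t(C)
  se_diff <- sqrt(diag(Vd))
  tval <- dif / se_diff
  R <- stats::cov2cor(Vd)
  p_unadj <- 2 * pt(-abs(tval), df)
  # the familywise p can never undercut the marginal p; enforcing the bound
  # also absorbs quadrature error for extreme statistics
  p_adj <- pmax(dunnett_p_adjust(tval, df, R), p_unadj)
  crit <- dunnett_quantile(alpha, df, R)

  out <- data.frame(genotype = gens, mean = means, se_mean = se_mean,
                    diff = 0, se_diff = NA_real_, t = NA_real_,
                    p_unadj = NA_real_, p_adj = NA_real_, label = "ns",
                    stringsAsFactors = FALSE)
  i <- match(others, out$genotype)
  out$diff[i] <- dif
  out$se_diff[i] <- se_diff
  out$t[i] <- tval
  out$p_unadj[i] <- p_unadj
  out$p_adj[i] <- p_adj
  out$label[i] <- ifelse(p_adj < alpha, ifelse(dif > 0, "A", "B"), "ns")
  rownames(out) <- NULL
  structure(out, check = check, alpha = alpha, df = df, crit = crit,
            contrast_corr = R,
            critical_difference = crit * median(se_diff),
            class = c("dunnett", "data.frame"))
}

#' @export
print.dunnett <- function(x, digits = 4, ...) {
  cat("Dunnett comparison vs check '", attr(x, "check"), "' (alpha = ",
      attr(x, "alpha"), ", residual df = ", attr(x, "df"), ")\n", sep = "")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], signif, digits)
  print(df, ...)
  cat("Critical difference:",
      format(attr(x, "critical_difference"), digits = digits),
      " (quantile ", format(attr(x, "crit"), digits = digits), ")\n")
  cat("A = superior to check, B = inferior, ns = not different\n")
  invisible(x)
}

#' Empirical familywise error rate of the Dunnett procedure
#'
#' Validation harness: simulates balanced one-way trials under the global
#' null (zero genotype variance), applies the Dunnett (or unadjusted t)
#' decision at level `alpha`, and reports the fraction of simulations with
#' at least one rejection, with a binomial confidence interval. The test
#' statistics are the same as [dunnett_test]'s on a blockless trial; the
#' rejection rule compares `max |t|` to the Dunnett quantile computed once
#' for the design.
#'
#' @param n_genotypes number of genotypes including the check.
#' @param n_replicates plots per genotype.
#' @param alpha familywise level.
#' @param n_sims number of simulated trials.
#' @param adjust `"dunnett"` or `"none"` (ordinary t tests; inflates the
#'   familywise error, included as a sanity contrast).
#' @param seed integer seed.
#' @return List with `fwer`, binomial 95% `ci`, `n_sims`, and the critical
#'   value used.
#' @export
fwer_simulation <- function(n_genotypes, n_replicates, alpha = 0.05,
                            n_sims = 1000L, adjust = c("dunnett", "none"),
                            seed = 1L) {
  adjust <- match.arg(adjust)
  g <- as.integer(n_genotypes); r <- as.integer(n_replicates)
  stopifnot(g >= 2L, r >= 2L)
  k <- g - 1L
  df <- g * (r - 1L)
  if (alpha <= 0) {
    return(list(fwer = 0, ci = c(0, 0), n_sims = as.integer(n_sims),
                crit = Inf))
  }
  R <- matrix(0.5, k, k); diag(R) <- 1       # balanced equicorrelation
  crit <- if (adjust == "dunnett") dunnett_quantile(alpha, df, R) else
    qt(1 - alpha / 2, df)
  set.seed(seed)
  rejected <- logical(n_sims)
  for (s in seq_len(n_sims)) {
    y <- matrix(rnorm(g * r), g, r)
    m <- rowMeans(y)
    mse <- sum((y - m)^2) / df
    tmax <- max(abs(m[-1] - m[1])) / sqrt(2 * mse / r)
    rejected[s] <- tmax > crit
  }
  fwer <- mean(rejected)
  se <- sqrt(fwer * (1 - fwer) / n_sims)
  list(fwer = fwer, ci = c(max(0, fwer - 1.96 * se),
                           min(1, fwer + 1.96 * se)),
       n_sims = as.integer(n_sims), crit = crit)
}
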