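# Per-environment genotype BLUEs, corrected for experimental design and
# spatial (row/column) variation:
#   y = mu + genotype(fixed) + block + row + column + error,
# block/row/column random. Row and column are post-blocking controls and
# enter only when they improve the REML AIC (select_spatial_terms).

env_subset <- function(plots, trait, location, year) {
  stopifnot(inherits(plots, "met_plots"))
  d <- plots[plots$trait == trait & plots$location == location &
               plots$year == as.integer(year), , drop = FALSE]
  d <- d[!is.na(d$value), , drop = FALSE]
  if (!nrow(d))
    stop("no observations of '", trait, "' in ",
         env_label(location, year), call. = FALSE)
  d <- as.data.frame(d)
  d$row_f <- factor(d$row)
  d$col_f <- factor(d$column)
  d
}

random_terms_for <- function(d, spatial) {
  rand <- character()
  if (length(unique(d$block)) > 1L) rand <- "block"
  if (spatial %in% c("row", "row+col") && nlevels(d$row_f) > 1L)
    rand <- c(rand, "row_f")
  if (spatial %in% c("col", "row+col") && nlevels(d$col_f) > 1L)
    rand <- c(rand, "col_f")
  rand
}

# lowest AIC wins; ties (to 1e-9) resolved toward the model with fewer
# random terms; NA candidates (failed fits) are never chosen
choose_candidate <- function(aic, n_random) {
  ok <- !is.na(aic)
  if (!any(ok)) stop("all candidate models failed", call. = FALSE)
  tied <- ok & aic <= min(aic[ok]) + 1e-9
  which(tied)[order(n_random[tied])][1]
}

#' Choose row/column spatial terms by REML model comparison
#'
#' Fits the four inclusion combinations of random row and column effects on
#' top of the base genotype + block model (identical fixed effects, so the
#' restricted likelihoods are comparable). Under the default `"aic"`
#' criterion the lowest REML-based AIC wins, with ties going to the model
#' with fewer terms; AIC's penalty of 2 per variance admits a spurious
#' spatial term in roughly 15% of null trials (the boundary chi-bar-square
#' mixture), so a stricter `"lrt"` mode is also provided, which includes a
#' term only when its boundary-corrected restricted likelihood-ratio test
#' is significant at `alpha`. A candidate that fails to fit is skipped with
#' a warning, never silently chosen.
#'
#' @param plots a [met_plots] table.
#' @param trait trait name.
#' @param location,year the environment to fit.
#' @param criterion `"aic"` or `"lrt"`.
#' @param alpha significance level for the `"lrt"` mode.
#' @return List with `spatial` (one of `"none"`, `"row"`, `"col"`,
#'   `"row+col"`) and `table`, the audit table of candidate fits.
#' @export
select_spatial_terms <- function(plots, trait, location, year,
                                 criterion = c("aic", "lrt"),
                                 alpha = 0.05) {
  criterion <- match.arg(criterion)
  d <- env_subset(plots, trait, location, year)
  cands <- c("none", "row", "col", "row+col")
  rows <- lapply(cands, function(sp) {
    rand <- random_terms_for(d, sp)
    fit <- tryCatch(reml_fit(d, "value", fixed = "genotype", random = rand),
                    error = function(e) e)
    if (inherits(fit, "error")) {
      warning("candidate '", sp, "' failed: ", conditionMessage(fit),
              call. = FALSE)
      return(data.frame(spatial = sp, n_random = NA_integer_,
                        loglik = NA_real_, aic = NA_real_))
    }
    data.frame(spatial = sp, n_random = length(rand),
               loglik = fit$loglik, aic = reml_aic(fit))
  })
  tab <- do.call(rbind, rows)
  sel <- if (criterion == "aic") choose_candidate(tab$aic, tab$n_random)
  else choose_candidate_lrt(tab, alpha)
  tab$selected <- seq_len(nrow(tab)) == sel
  list(spatial = tab$spatial[sel], table = tab)
}

# stepwise boundary-corrected REML LRT: row and col are each tested against
# the base model with the 50:50 chi-bar-square {0,1} mixture p-value
choose_candidate_lrt <- function(tab, alpha) {
  base_ll <- tab$loglik[tab$spatial == "none"]
  if (is.na(base_ll)) return(choose_candidate(tab$aic, tab$n_random))
  sig <- function(sp) {
    ll <- tab$loglik[tab$spatial == sp]
    if (is.na(ll)) return(FALSE)
    stat <- max(0, 2 * (ll - base_ll))
    p <- 0.5 * pchisq(stat, df = 1, lower.tail = FALSE)
    stat > 0 && p < alpha
  }
  pick <- c("row", "col")[c(sig("row"), sig("col"))]
  chosen <- if (!length(pick)) "none" else paste(pick, collapse = "+")
  match(chosen, tab$spatial)
}

#' Estimate per-genotype BLUEs within one environment
#'
#' Fits the design/spatial correction model for one location-year and
#' returns the genotype estimated marginal means (population-level, equal
#' weighting of random effects) with standard errors. Under a balanced
#' complete RCBD without spatial terms these are the arithmetic genotype
#' means; in augmented designs unreplicated entries are adjusted through the
#' block/row/column effects estimated from the replicated checks.
#'
#' @param plots a [met_plots] table.
#' @param trait trait name.
#' @param location,year the environment.
#' @param spatial `"auto"` (choose by [select_spatial_terms]), `"none"`,
#'   `"row"`, `"col"`, or `"row+col"`.
#' @return Object of class `genotype_blues`: a data frame `genotype`,
#'   `blue`, `se`, with attributes `environment`, `spatial` (the terms
#'   used), `selection` (the audit table if `spatial = "auto"`), `varcomp`,
#'   and `excluded` (genotypes absent from the environment, if a genotype
#'   list was supplied).
#' @param genotypes optional character vector of genotypes expected; those
#'   absent from the environment are reported in the `excluded` attribute
#'   (they are never imputed).
#' @export
estimate_blues <- function(plots, trait, location, year,
                           spatial = c("auto", "none", "row", "col",
                                       "row+col"),
                           genotypes = NULL) {
  spatial <- match.arg(spatial)
  d <- env_subset(plots, trait, location, year)
  excluded <- character()
  if (!is.null(genotypes))
    excluded <- setdiff(genotypes, unique(d$genotype))
  seltab <- NULL
  if (spatial == "auto") {
    sel <- select_spatial_terms(plots, trait, location, year)
    spatial <- sel$spatial
    seltab <- sel$table
  }
  rand <- random_terms_for(d, spatial)
  fit <- reml_fit(d, "value", fixed = "genotype", random = rand)
  em <- if (inherits(fit$model, "lmerMod"))
    emmeans::emmeans(fit$model, "genotype", data = fit$data,
                     lmer.df = "asymptotic")
  else emmeans::emmeans(fit$model, "genotype", data = fit$data)
  es <- as.data.frame(em)
  out <- data.frame(genotype = as.character(es$genotype),
                    blue = es$emmean, se = es$SE,
                    stringsAsFactors = FALSE)
  out <- out[order(out$genotype), , drop = FALSE]
  rownames(out) <- NULL
  structure(out,
            environment = env_label(location, as.integer(year)),
            spatial = spatial, selection = seltab,
            varcomp = fit$varcomp, excluded = excluded,
            class = c("genotype_blues", "data.frame"))
}

#' Estimate BLUEs for every environment and assemble the two-way table
#'
#' Convenience wrapper running [estimate_blues] in each location-year
#' present for the trait and assembling the results with [two_way_table].
#'
#' @inheritParams estimate_blues
#' @return A [blue_matrix] with standard errors.
#' @export
blues_matrix <- function(plots, trait, spatial = "auto") {
  stopifnot(inherits(plots, "met_plots"))
  d <- plots[plots$trait == trait & !is.na(plots$value), , drop = FALSE]
  if (!nrow(d)) stop("no observations of '", trait, "'", call. = FALSE)
  envs <- unique(data.frame(location = d$location, year = d$year,
                            stringsAsFactors = FALSE))
  envs <- envs[order_envs(envs$location, envs$year), , drop = FALSE]
  recs <- do.call(rbind, lapply(seq_len(nrow(envs)), function(i) {
    b <- estimate_blues(plots, trait, envs$location[i], envs$year[i],
                        spatial = spatial)
    data.frame(genotype = b$genotype, location = envs$location[i],
               year = envs$year[i], value = b$blue, se = b$se,
               stringsAsFactors = FALSE)
  }))
  two_way_table(recs)
}

#' @export
print.genotype_blues <- function(x, ...) {
  cat("Genotype BLUEs for environment ", attr(x, "environment"),
      " (spatial terms: ", attr(x, "spatial"), ")\n", sep = "")
  print(as.data.frame(x), ...)
  exc <- attr(x, "excluded")
  if (length(exc))
    cat("Excluded (absent from environment):", paste(exc, collapse = ", "),
        "\n")
  invisible(x)
}
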