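# Crossed variance decomposition across the whole trial series:
#   y = mu + G + L + A + LA + block(LA) + GL + GA + GLA + error,
# all terms random, fitted by REML under the nonnegativity constraint.
# Reduced forms drop the location terms (per-location series) or both
# location and year terms (single environment).

#' Estimate variance components for a multi-environment trial
#'
#' Decomposes a trait's plot-level variation into genotype (G), location
#' (L), year (A), their interactions (LA, GL, GA, GLA), block-within-
#' environment, and residual variance. Estimates at the zero boundary are
#' flagged, not hidden. The observation incidence table needed by
#' [heritability] is attached.
#'
#' @param plots a [met_plots] table.
#' @param trait trait name.
#' @param scope `"full"` (needs >= 2 locations and >= 2 years),
#'   `"per_location"` (location terms removed; fit within one location), or
#'   `"per_environment"` (location and year terms removed; one
#'   location-year).
#' @param location,year environment selectors for the reduced scopes.
#' @return Object of class `variance_components`: named variances (subset
#'   depending on scope, residual last) with attributes `boundary`,
#'   `trait`, `scope`, `n_obs`, `incidence` (per genotype x location x year
#'   replicate counts) and `fit` (the underlying [reml_fit]).
#' @export
estimate_variance_components <- function(plots, trait,
                                         scope = c("full", "per_location",
                                                   "per_environment"),
                                         location = NULL, year = NULL) {
  scope <- match.arg(scope)
  stopifnot(inherits(plots, "met_plots"))
  d <- plots[plots$trait == trait & !is.na(plots$value), , drop = FALSE]
  if (!nrow(d)) stop("no observations of '", trait, "'", call. = FALSE)
  d <- as.data.frame(d)

  if (scope == "full") {
    if (length(unique(d$location)) < 2L || length(unique(d$year)) < 2L)
      stop("full model needs >= 2 locations and >= 2 years; ",
           "use scope = 'per_location' or 'per_environment'",
           call. = FALSE)
    d$blk <- paste(d$location, d$year, d$block, sep = ":")
    random <- c("genotype", "location", "year", "location:year", "blk",
                "genotype:location", "genotype:year",
                "genotype:location:year")
    rename <- c(genotype = "G", location = "L", year = "A",
                "location:year" = "LA", blk = "block",
                "genotype:location" = "GL", "genotype:year" = "GA",
                "genotype:location:year" = "GLA", residual = "residual")
  } else if (scope == "per_location") {
    if (!is.null(location)) d <- d[d$location == location, , drop = FALSE]
    if (length(unique(d$location)) != 1L)
      stop("per_location scope needs exactly one location (use 'location=')",
           call. = FALSE)
    if (length(unique(d$year)) < 2L)
      stop("per_location model needs >= 2 years", call. = FALSE)
    d$blk <- paste(d$year, d$block, sep = ":")
    random <- c("genotype", "year", "blk", "genotype:year")
    rename <- c(genotype = "G", year = "A", blk = "block",
                "genotype:year" = "GA", residual = "residual")
  } else {
    if (!is.null(location)) d <- d[d$location == location, , drop = FALSE]
    if (!is.null(year)) d <- d[d$year == as.integer(year), , drop = FALSE]
    if (length(unique(paste(d$location, d$year))) != 1L)
      stop("per_environment scope needs exactly one location-year",
           call. = FALSE)
    random <- c("genotype", "block")
    rename <- c(genotype = "G", block = "block", residual = "residual")
    if (length(unique(d$block)) < 2L) {
      random <- "genotype"
      rename <- c(genotype = "G", residual = "residual")
    }
  }

  fit <- reml_fit(d, "value", fixed = character(), random = random)
  v <- fit$varcomp
  names(v) <- rename[names(v)]
  inc <- aggregate(list(n = d$value),
                   by = list(genotype = d$genotype, location = d$location,
                             year = d$year),
                   FUN = length)
  structure(v,
            boundary = setNames(c(fit$boundary, FALSE), names(v)),
            trait = trait, scope = scope, n_obs = fit$n_obs,
            incidence = inc, fit = fit,
            class = "variance_components")
}

#' @export
print.variance_components <- function(x, ...) {
  cat("Variance components for '", attr(x, "trait"), "' (scope: ",
      attr(x, "scope"), ", n = ", attr(x, "n_obs"), ")\n", sep = "")
  b <- attr(x, "boundary")
  df <- data.frame(variance = unclass(x),
                   boundary = ifelse(b, "*", ""))
  print(df, ...)
  tg <- tryCatch(total_genetic_variance(x), error = function(e) NA)
  if (is.finite(tg))
    cat("Total genetic variance (G + GL + GA + GLA):",
        format(tg, digits = 6), "\n")
  invisible(x)
}

#' Total genetic variance of a variance decomposition
#'
#' The sum of the genotype main effect and all genotype-by-environment
#' interaction variances present in the object.
#'
#' @param vc a `variance_components` object or named numeric vector.
#' @return Numeric scalar.
#' @export
total_genetic_variance <- function(vc) {
  v <- unclass(vc)
  sum(v[intersect(c("G", "GL", "GA", "GLA"), names(v))])
}

#' Fit the evaluator score model
#'
#' Genotype BLUEs from baker or taster panels: score = mu + genotype(fixed)
#' + evaluator(random) \[+ stage(random)\] + error. With a single evaluator
#' the evaluator variance is not identifiable and the fit falls back to
#' fixed-effects only, with a warning.
#'
#' @param scores a [score_records] table.
#' @param include_stage include a random baking-stage term (requires a
#'   `stage` column with >= 2 levels).
#' @return Object of class `score_fit`: data frame `genotype`, `blue`,
#'   `se`, with attributes `varcomp` (evaluator / stage / residual
#'   variances) and `n_evaluators`.
#' @export
fit_score_model <- function(scores, include_stage = FALSE) {
  stopifnot(inherits(scores, "score_records"))
  d <- as.data.frame(scores)
  d <- d[!is.na(d$score), , drop = FALSE]
  n_ev <- length(unique(d$evaluator))
  random <- character()
  if (n_ev >= 2L) random <- "evaluator"
  else warning("single evaluator: evaluator variance not identifiable; ",
               "fitting fixed-effects model", call. = FALSE)
  if (include_stage) {
    if (length(unique(na.omit(d$stage))) < 2L)
      stop("include_stage = TRUE needs >= 2 stages", call. = FALSE)
    random <- c(random, "stage")
  }
  fit <- reml_fit(d, "score", fixed = "genotype", random = random)
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
  structure(out, varcomp = fit$varcomp, n_evaluators = n_ev,
            class = c("score_fit", "data.frame"))
}

#' @export
print.score_fit <- function(x, ...) {
  cat("Evaluator score model (", attr(x, "n_evaluators"),
      " evaluators)\n", sep = "")
  cat("Variance components:\n")
  print(attr(x, "varcomp"))
  print(as.data.frame(x), ...)
  invisible(x)
}
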