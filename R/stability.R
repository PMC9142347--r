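# Genotype stability statistics on a BLUE table.
#
# Finlay-Wilkinson joint regression (two-stage form): each genotype's BLUEs
# are regressed by ordinary least squares on the environment index, the
# centred per-environment mean of the BLUEs across genotypes. The slope is
# the sensitivity: near 0 static stability, near 1 dynamic stability,
# above 1 hypersensitive. Wricke's ecovalence is each genotype's
# contribution to the interaction sum of squares of the double-centred
# table; the two agree in the degenerate case (all slopes 1, no residual
# variance => all W = 0).

#' Finlay-Wilkinson joint regression
#'
#' Computes the environment index as the centred per-environment mean of
#' the BLUEs over the genotypes present in every environment, then
#' regresses each genotype's values on it. Genotypes observed in fewer than
#' 3 environments are excluded and reported.
#'
#' @param blues a [blue_matrix].
#' @param bands sensitivity classification bands passed to
#'   [classify_sensitivity].
#' @return Object of class `finlay_wilkinson`: a data frame per genotype
#'   (`genotype`, `mean`, `slope`, `intercept`, `r_squared`, `resid_var`,
#'   `n_env`, `class`) with attributes `env_index` (named), `excluded`,
#'   and `index_genotypes` (the complete-case genotypes defining the
#'   index).
#' @export
finlay_wilkinson <- function(blues,
                             bands = c(static_max = 0.5, dynamic_lo = 0.8,
                                       dynamic_hi = 1.2)) {
  stopifnot(inherits(blues, "blue_matrix"))
  x <- unclass(blues)
  complete <- rowSums(is.na(x)) == 0L
  if (!any(complete))
    stop("no genotype observed in every environment; cannot form the ",
         "environment index", call. = FALSE)
  idx <- colMeans(x[complete, , drop = FALSE])
  idx <- idx - mean(idx)
  if (var(idx) == 0)
    stop("environment index has zero variance", call. = FALSE)
  n_env <- rowSums(!is.na(x))
  excluded <- rownames(x)[n_env < 3L]
  keep <- rownames(x)[n_env >= 3L]

  rows <- lapply(keep, function(g) {
    obs <- !is.na(x[g, ])
    y <- x[g, obs]
    e <- idx[obs]
    e <- e - mean(e)              # re-centre on this genotype's environments
    b <- sum(e * y) / sum(e * e)
    a <- mean(y)
    fitv <- a + b * e
    sse <- sum((y - fitv)^2)
    sst <- sum((y - mean(y))^2)
    r2 <- if (sse <= 1e-12 * max(sst, 1)) 1 else 1 - sse / sst
    data.frame(genotype = g, mean = mean(y), slope = b, intercept = a,
               r_squared = r2,
               resid_var = sse / max(sum(obs) - 2L, 1L),
               n_env = sum(obs), stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  tab$class <- vapply(tab$slope, classify_sensitivity, "", bands = bands)
  rownames(tab) <- NULL
  structure(tab, env_index = idx, excluded = excluded,
            index_genotypes = rownames(x)[complete],
            class = c("finlay_wilkinson", "data.frame"))
}

#' Classify a Finlay-Wilkinson sensitivity
#'
#' Banded labelling of the regression slope: below `static_max` the
#' genotype is statically stable (insensitive to the environment); between
#' `dynamic_lo` and `dynamic_hi` it tracks the environment mean (dynamic
#' stability); above `dynamic_hi` it is hypersensitive (low stability);
#' between the static and dynamic bands it is sub-sensitive.
#'
#' @param beta slope value.
#' @param bands ordered numeric `c(static_max, dynamic_lo, dynamic_hi)`.
#' @return One of `"static"`, `"sub-sensitive"`, `"dynamic"`,
#'   `"hypersensitive"`.
#' @export
classify_sensitivity <- function(beta,
                                 bands = c(static_max = 0.5,
                                           dynamic_lo = 0.8,
                                           dynamic_hi = 1.2)) {
  if (is.unsorted(bands)) stop("bands must be ordered", call. = FALSE)
  if (beta < bands[1]) "static"
  else if (beta < bands[2]) "sub-sensitive"
  else if (beta <= bands[3]) "dynamic"
  else "hypersensitive"
}

#' @export
print.finlay_wilkinson <- function(x, digits = 3, ...) {
  cat("Finlay-Wilkinson joint regression over", length(attr(x, "env_index")),
      "environments\n")
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, TRUE)
  df[num] <- lapply(df[num], round, digits)
  print(df, ...)
  if (length(attr(x, "excluded")))
    cat("Excluded (< 3 environments):",
        paste(attr(x, "excluded"), collapse = ", "), "\n")
  invisible(x)
}

#' @export
coef.finlay_wilkinson <- function(object, ...)
  setNames(object$slope, object$genotype)

#' @export
plot.finlay_wilkinson <- function(x, blues = NULL, ...) {
  idx <- attr(x, "env_index")
  rng <- range(idx)
  ylim <- range(x$intercept + outer(x$slope, rng), na.rm = TRUE)
  plot(NA, xlim = rng, ylim = ylim, xlab = "environment index",
       ylab = "genotype BLUE", main = "Finlay-Wilkinson regression", ...)
  for (i in seq_len(nrow(x)))
    graphics::abline(a = x$intercept[i], b = x$slope[i],
                     col = grDevices::grey(0.35))
  graphics::abline(a = mean(x$mean), b = 1, col = 2, lwd = 2, lty = 2)
  invisible(x)
}

#' Wricke's ecovalence stability coefficient
#'
#' Each genotype's contribution to the genotype-by-environment interaction
#' sum of squares of the two-way table, computed by double-centring:
#' \deqn{W_i = \sum_j (G_{ij} - \bar G_{i.} - \bar G_{.j} + \bar G_{..})^2.}
#' A genotype with no interaction has W = 0, and the W sum over genotypes
#' equals the interaction sum of squares of the table.
#'
#' @param blues a [blue_matrix]; the table must be complete, or set
#'   `na_action = "drop_environments"` to drop any environment (column)
#'   containing missing cells.
#' @param na_action `"fail"` (default) or `"drop_environments"`.
#' @return Object of class `ecovalence`: data frame `genotype`, `w`, with
#'   attributes `total` (the interaction SS), `environments`, and
#'   `dropped_environments`.
#' @export
wricke_ecovalence <- function(blues,
                              na_action = c("fail", "drop_environments")) {
  stopifnot(inherits(blues, "blue_matrix"))
  na_action <- match.arg(na_action)
  x <- unclass(blues)
  dropped <- character()
  if (anyNA(x)) {
    if (na_action == "fail")
      stop("BLUE table has missing cells; use na_action = ",
           "'drop_environments' or impute upstream", call. = FALSE)
    bad <- colSums(is.na(x)) > 0L
    dropped <- colnames(x)[bad]
    x <- x[, !bad, drop = FALSE]
  }
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("need >= 2 genotypes and >= 2 environments", call. = FALSE)
  centred <- sweep(sweep(x, 1L, rowMeans(x)), 2L, colMeans(x)) + mean(x)
  w <- rowSums(centred^2)
  structure(data.frame(genotype = rownames(x), w = w,
                       stringsAsFactors = FALSE, row.names = NULL),
            total = sum(w), environments = colnames(x),
            dropped_environments = dropped,
            class = c("ecovalence", "data.frame"))
}

#' @export
print.ecovalence <- function(x, ...) {
  cat("Wricke's ecovalence over", length(attr(x, "environments")),
      "environments (interaction SS =",
      format(attr(x, "total"), digits = 6), ")\n")
  print(as.data.frame(x), ...)
  if (length(attr(x, "dropped_environments")))
    cat("Dropped environments:",
        paste(attr(x, "dropped_environments"), collapse = ", "), "\n")
  invisible(x)
}

#' Drop environments from a BLUE matrix
#'
#' Used for sensitivity re-analyses that exclude extreme environments
#' (for example, re-running the stability statistics without
#' exceptionally high-yielding location-years).
#'
#' @param blues a [blue_matrix].
#' @param drop character vector of `"location:year"` labels to remove.
#' @return The reduced [blue_matrix]; at least 3 environments must remain.
#' @export
drop_environments <- function(blues, drop) {
  stopifnot(inherits(blues, "blue_matrix"))
  if (!length(drop)) return(blues)
  missing_envs <- setdiff(drop, colnames(blues))
  if (length(missing_envs))
    stop("environment(s) not present: ",
         paste(missing_envs, collapse = ", "), call. = FALSE)
  keep <- setdiff(colnames(blues), drop)
  if (length(keep) < 3L)
    stop("dropping would leave fewer than 3 environments", call. = FALSE)
  x <- unclass(blues)[, keep, drop = FALSE]
  se <- attr(blues, "se")
  blue_matrix(x, se = if (!is.null(se)) se[, keep, drop = FALSE])
}

#' Combined stability table
#'
#' Convenience report mirroring a standard stability summary: per-genotype
#' mean, Finlay-Wilkinson slope and R-squared, and Wricke's ecovalence,
#' optionally alongside the same statistics after dropping a set of
#' environments ("no extremes" re-analysis).
#'
#' @param blues a [blue_matrix].
#' @param drop optional environments to exclude for the second analysis.
#' @return Data frame with columns `genotype`, `mean`, `slope`,
#'   `r_squared`, `w` and, when `drop` is given, the same suffixed
#'   `_reduced`.
#' @export
stability_table <- function(blues, drop = NULL) {
  fw <- finlay_wilkinson(blues)
  w <- wricke_ecovalence(blues, na_action = "drop_environments")
  tab <- merge(fw[c("genotype", "mean", "slope", "r_squared")],
               as.data.frame(w), by = "genotype")
  if (!is.null(drop) && length(drop)) {
    red <- drop_environments(blues, drop)
    fw2 <- finlay_wilkinson(red)
    w2 <- wricke_ecovalence(red, na_action = "drop_environments")
    tab2 <- merge(fw2[c("genotype", "slope", "r_squared")],
                  as.data.frame(w2), by = "genotype")
    names(tab2)[-1] <- paste0(names(tab2)[-1], "_reduced")
    tab <- merge(tab, tab2, by = "genotype", all.x = TRUE)
  }
  tab[order(tab$genotype), , drop = FALSE]
}
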