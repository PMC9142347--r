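# Quantitative-genetics summaries on top of the fitted variance components:
# variance shares of the total genetic variance, entry-mean broad-sense
# heritability with harmonic-mean divisors, head-row FHB scoring, and the
# percentile / threshold selection filters used to advance families.

#' Genetic variance shares
#'
#' Expresses G, GL, GA and GLA as proportions of the total genetic variance
#' (G + GL + GA + GLA); non-genetic components (location, year, block,
#' residual) never enter the denominator.
#'
#' @param vc a [estimate_variance_components] result or a named numeric
#'   vector containing `G`, `GL`, `GA`, `GLA`.
#' @return Named numeric vector of shares summing to one.
#' @export
variance_proportions <- function(vc) {
  v <- unclass(vc)
  comp <- c("G", "GL", "GA", "GLA")
  miss <- setdiff(comp, names(v))
  if (length(miss))
    stop("missing genetic component(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  v <- v[comp]
  tot <- sum(v)
  if (!is.finite(tot) || tot <= 0)
    stop("total genetic variance must be > 0", call. = FALSE)
  v / tot
}

#' Harmonic mean of positive counts
#'
#' `n / sum(1/x)`. Used for the effective numbers of years, locations,
#' location-years and plots per genotype in [heritability]. A zero count is
#' an error: a genotype with no observations must be dropped from the
#' heritability computation, with a report, not averaged over.
#'
#' @param x positive numeric vector.
#' @return Positive scalar.
#' @export
harmonic_mean <- function(x) {
  if (!length(x)) stop("empty count vector", call. = FALSE)
  if (any(!is.finite(x)) || any(x <= 0))
    stop("harmonic mean requires strictly positive counts", call. = FALSE)
  length(x) / sum(1 / x)
}

#' Broad-sense heritability on an entry-mean basis
#'
#' Entry-mean heritability with harmonic-mean divisors for unbalanced data:
#' \deqn{H^2 = \sigma^2_g / (\sigma^2_g + \sigma^2_{ga}/\bar n_a +
#'   \sigma^2_{gl}/\bar n_l + \sigma^2_{gal}/\bar n_{al} +
#'   \sigma^2_e/\bar n_{alr})}
#' where the \eqn{\bar n} are harmonic means, across genotypes, of the
#' number of years, locations, location-years, and plots in which each
#' genotype was observed -- computed from the realized incidence, which
#' absorbs the unbalancedness of a selection funnel. Reduced forms apply
#' automatically when the variance decomposition was fitted per location
#' (no GL/GLA terms) or per environment (genotype and residual only).
#'
#' @param vc a [estimate_variance_components] result, or a named numeric
#'   vector of components (`G`, `residual`, and whichever of `GL`, `GA`,
#'   `GLA` apply).
#' @param incidence data frame `genotype`, `location`, `year`, `n` (number
#'   of replicate plots); taken from `vc`'s attribute when omitted.
#' @return Object of class `heritability`: list with `H2`, the harmonic
#'   means (`n_a`, `n_l`, `n_al`, `n_alr`), the components used, and any
#'   dropped genotypes.
#' @export
heritability <- function(vc, incidence = NULL) {
  v <- unclass(vc)
  if (is.null(incidence)) incidence <- attr(vc, "incidence")
  if (is.null(incidence))
    stop("an incidence table (genotype, location, year, n) is required",
         call. = FALSE)
  need <- c("genotype", "location", "year", "n")
  miss <- setdiff(need, names(incidence))
  if (length(miss))
    stop("incidence is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  bad <- incidence$n <= 0
  dropped <- unique(incidence$genotype[bad])
  incidence <- incidence[!bad, , drop = FALSE]
  if (!nrow(incidence)) stop("empty incidence table", call. = FALSE)

  per_gen <- split(incidence, incidence$genotype)
  n_years <- vapply(per_gen, function(d) length(unique(d$year)), 1)
  n_locs  <- vapply(per_gen, function(d) length(unique(d$location)), 1)
  n_envs  <- vapply(per_gen, function(d)
    nrow(unique(d[c("location", "year")])), 1)
  n_plots <- vapply(per_gen, function(d) sum(d$n), 1)
  n_a   <- harmonic_mean(n_years)
  n_l   <- harmonic_mean(n_locs)
  n_al  <- harmonic_mean(n_envs)
  n_alr <- harmonic_mean(n_plots)

  g  <- v[["G"]]
  e  <- v[["residual"]]
  ga  <- if ("GA" %in% names(v)) v[["GA"]] else 0
  gl  <- if ("GL" %in% names(v)) v[["GL"]] else 0
  gal <- if ("GLA" %in% names(v)) v[["GLA"]] else 0
  if (any(c(g, e, ga, gl, gal) < 0))
    stop("variance components must be >= 0", call. = FALSE)
  denom <- g + ga / n_a + gl / n_l + gal / n_al + e / n_alr
  if (denom <= 0) stop("zero denominator: all components are 0",
                       call. = FALSE)
  structure(list(H2 = g / denom,
                 n_a = n_a, n_l = n_l, n_al = n_al, n_alr = n_alr,
                 components = c(g = g, ga = ga, gl = gl, gal = gal, e = e),
                 dropped = dropped),
            class = "heritability")
}

#' @export
print.heritability <- function(x, ...) {
  cat(sprintf("Broad-sense heritability (entry-mean basis): H2 = %.4f\n",
              x$H2))
  cat(sprintf(
    "Harmonic means: years %.3f, locations %.3f, environments %.3f, plots %.3f\n",
    x$n_a, x$n_l, x$n_al, x$n_alr))
  if (length(x$dropped))
    cat("Dropped genotypes (zero counts):",
        paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Fusarium head blight incidence, severity and index for one head-row
#'
#' Twenty spikes per head-row are scored 0-5 (0 = no infected spikelet,
#' 5 = entire spike dead). Incidence is the percentage of nonzero scores;
#' severity is the mean of the per-score infected-spikelet percentages; the
#' FHB index is their product expressed as a percentage
#' (incidence x severity / 100).
#'
#' @param spike_scores integer vector of per-spike scores in 0-5.
#' @param severity_map named numeric mapping from score (0-5) to percent of
#'   spikelets infected. The default reads the 0-5 anchors on a 15-spikelet
#'   spike; supply your own mapping to match a different scoring guide.
#' @param n_spikes required number of spikes (default 20).
#' @return Object of class `fhb_score`: list with `incidence`, `severity`,
#'   `index` (all percentages) and the scores.
#' @export
fhb_scores <- function(spike_scores,
                       severity_map = c(`0` = 0, `1` = 6.7, `2` = 13.3,
                                        `3` = 50, `4` = 75, `5` = 100),
                       n_spikes = 20L) {
  if (length(spike_scores) != n_spikes)
    stop("expected ", n_spikes, " spike scores, got ",
         length(spike_scores), call. = FALSE)
  if (any(is.na(spike_scores)) || any(spike_scores %% 1 != 0) ||
      any(spike_scores < 0 | spike_scores > 5))
    stop("spike scores must be integers in 0-5", call. = FALSE)
  incidence <- 100 * mean(spike_scores > 0)
  severity <- mean(severity_map[as.character(spike_scores)])
  structure(list(incidence = incidence, severity = severity,
                 index = incidence * severity / 100,
                 spike_scores = as.integer(spike_scores)),
            class = "fhb_score")
}

#' @export
print.fhb_score <- function(x, ...) {
  cat(sprintf("FHB incidence %.1f%%, severity %.1f%%, index %.1f\n",
              x$incidence, x$severity, x$index))
  invisible(x)
}

#' Percentile, threshold, and top-n selection filters
#'
#' Deterministic single-trait selection rules used to advance families:
#' `above_percentile` keeps values strictly greater than the given
#' percentile (inclusive linear-interpolation convention, so "above the
#' 50th percentile" means strictly above the median); `below_threshold`
#' keeps values strictly less than the cutoff; `top_n` keeps the `k`
#' largest, retaining all boundary ties (so more than `k` ids can be
#' returned, and the ties are reported).
#'
#' @param values named numeric vector of per-family trait means.
#' @param rule one of `"above_percentile"`, `"below_threshold"`, `"top_n"`.
#' @param cutoff the percentile (0-100), threshold, or `k`.
#' @return Character vector of selected ids, with attributes `boundary`
#'   (ids tied exactly at the selection boundary) and `threshold`.
#' @export
percentile_select <- function(values,
                              rule = c("above_percentile",
                                       "below_threshold", "top_n"),
                              cutoff) {
  rule <- match.arg(rule)
  if (!length(values)) stop("empty values", call. = FALSE)
  if (is.null(names(values)))
    names(values) <- sprintf("f%03d", seq_along(values))
  sel <- switch(rule,
    above_percentile = {
      thr <- as.numeric(quantile(values, cutoff / 100, type = 7))
      list(ids = names(values)[values > thr], thr = thr)
    },
    below_threshold = list(ids = names(values)[values < cutoff],
                           thr = cutoff),
    top_n = {
      k <- as.integer(cutoff)
      if (k >= length(values)) list(ids = names(values), thr = -Inf)
      else {
        thr <- sort(values, decreasing = TRUE)[k]
        list(ids = names(values)[values >= thr], thr = thr)
      }
    })
  boundary <- names(values)[values == sel$thr]
  structure(sel$ids, boundary = intersect(boundary, sel$ids),
            threshold = sel$thr)
}
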