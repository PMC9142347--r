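# Synthetic multi-environment trial generator.
#
# The generative model mirrors the package's analysis models exactly, so
# every downstream estimator can be tested by parameter recovery:
#   plot level:  y = mu + G + L + A + LA + block + row + col
#                      + GL + GA + GLA + error,
# every effect an independent zero-mean Gaussian with its own variance.
# Each effect family is drawn from its own seed substream (derived from the
# master seed) so adding or resizing one component never perturbs another.

#' Simulation configuration for a multi-environment trial
#'
#' Defaults describe a wheat breeding programme evaluating 50 genotypes in
#' 2 locations over 5 years with 3 replicate blocks. The default yield
#' variance components put 54% of the total genetic variance on the genotype
#' main effect, 9% on genotype-by-location, 12% on genotype-by-year and 25%
#' on the three-way interaction, at field-realistic kg/ha magnitudes; the
#' absolute scale is a synthetic choice (see the package vignette).
#'
#' @param n_genotypes,n_locations,n_years,n_replicates trial dimensions.
#' @param design `"rcbd"` or `"augmented_alpha"`. The augmented layout adds
#'   one extra plot of every check to each block (checks repeat within
#'   blocks; entries appear once per block).
#' @param check_ids genotype ids treated as replicated checks; required for
#'   the augmented design.
#' @param mu grand mean, trait units.
#' @param varcomp named list/vector of variances `G, L, A, LA, block, row,
#'   col, GL, GA, GLA, error`, all `>= 0` (trait units squared).
#' @param funnel optional integer vector, one entry per year, of how many
#'   genotypes are retained in that year; must be non-increasing and start
#'   at `n_genotypes`. Dropped genotypes are the lowest ranked on their mean
#'   simulated trait value over all previous years (truncation selection).
#' @param trait trait name used for the simulated values.
#' @param seed master integer seed.
#' @return A validated list of class `met_sim_config`.
#' @export
met_sim_config <- function(n_genotypes = 50L, n_locations = 2L,
                           n_years = 5L, n_replicates = 3L,
                           design = c("rcbd", "augmented_alpha"),
                           check_ids = NULL,
                           mu = 2800,
                           varcomp = c(G = 54000, L = 40000, A = 90000,
                                       LA = 60000, block = 5000,
                                       row = 2000, col = 2000,
                                       GL = 9000, GA = 12000, GLA = 25000,
                                       error = 60000),
                           funnel = NULL,
                           trait = "yield_kg_ha",
                           seed = 1L) {
  design <- match.arg(design)
  varcomp <- unlist(varcomp)
  need <- c("G", "L", "A", "LA", "block", "row", "col", "GL", "GA", "GLA",
            "error")
  miss <- setdiff(need, names(varcomp))
  if (length(miss))
    stop("varcomp is missing component(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  varcomp <- varcomp[need]
  if (any(varcomp < 0)) stop("all variances must be >= 0", call. = FALSE)
  if (design == "augmented_alpha" && !length(check_ids))
    stop("augmented_alpha design requires non-empty check_ids",
         call. = FALSE)
  if (!is.null(funnel)) {
    funnel <- as.integer(funnel)
    if (length(funnel) != n_years)
      stop("funnel must have one entry per year", call. = FALSE)
    if (funnel[1] != n_genotypes || any(diff(funnel) > 0L))
      stop("funnel must be non-increasing and start at n_genotypes",
         call. = FALSE)
  }
  structure(list(n_genotypes = as.integer(n_genotypes),
                 n_locations = as.integer(n_locations),
                 n_years = as.integer(n_years),
                 n_replicates = as.integer(n_replicates),
                 design = design, check_ids = check_ids,
                 mu = mu, varcomp = varcomp, funnel = funnel,
                 trait = trait, seed = as.integer(seed)),
            class = "met_sim_config")
}

# deterministic substream seeds derived from the master seed
substream <- function(seed, k) (as.integer(seed) * 101L + k * 9973L) %% 2147483629L

draw_effects <- function(n, sd, seed, k, names = NULL) {
  set.seed(substream(seed, k))
  e <- rnorm(n, 0, sd)
  if (!is.null(names)) names(e) <- names
  e
}

#' Simulate a multi-environment trial at the plot level
#'
#' Generates plot observations from the crossed random-effects model and
#' returns both the data and every drawn effect, so that variance-component
#' and BLUE estimators can be checked against the truth. Output is
#' deterministic under the configured seed.
#'
#' @param config a [met_sim_config].
#' @return Object of class `met_sim`: a list with `plots` (a [met_plots]
#'   table), `truth` (named effect vectors `G, L, A, LA, block, row, col,
#'   GL, GA, GLA` plus `residual_sd` and `mu`), and `config`.
#' @export
simulate_met <- function(config = met_sim_config()) {
  stopifnot(inherits(config, "met_sim_config"))
  vc <- config$varcomp
  ng <- config$n_genotypes; nl <- config$n_locations
  ny <- config$n_years; nr <- config$n_replicates
  gens <- sprintf("g%02d", seq_len(ng))
  if (!is.null(config$check_ids) && !all(config$check_ids %in% gens)) {
    # named checks replace the tail of the genotype list
    nc <- length(config$check_ids)
    gens[(ng - nc + 1L):ng] <- config$check_ids
  }
  locs <- sprintf("loc%d", seq_len(nl))
  years <- 2016L + seq_len(ny)

  G  <- draw_effects(ng, sqrt(vc["G"]), config$seed, 1L, gens)
  L  <- draw_effects(nl, sqrt(vc["L"]), config$seed, 2L, locs)
  A  <- draw_effects(ny, sqrt(vc["A"]), config$seed, 3L, as.character(years))
  la_names <- as.vector(outer(locs, years, paste, sep = ":"))
  LA <- draw_effects(nl * ny, sqrt(vc["LA"]), config$seed, 4L, la_names)
  gl_names <- as.vector(outer(gens, locs, paste, sep = ":"))
  GL <- draw_effects(ng * nl, sqrt(vc["GL"]), config$seed, 5L, gl_names)
  ga_names <- as.vector(outer(gens, years, paste, sep = ":"))
  GA <- draw_effects(ng * ny, sqrt(vc["GA"]), config$seed, 6L, ga_names)
  gla_names <- as.vector(outer(gl_names, years, paste, sep = ":"))
  GLA <- draw_effects(ng * nl * ny, sqrt(vc["GLA"]), config$seed, 7L,
                      gla_names)

  # field grid per environment: blocks stacked vertically, each block a
  # rows_per_block x n_col rectangle holding one plot per entry (plus extra
  # check plots under the augmented design)
  is_aug <- config$design == "augmented_alpha"
  checks <- if (is_aug) config$check_ids else character()

  env_rows <- list()
  active <- gens
  for (yi in seq_len(ny)) {
    if (!is.null(config$funnel) && yi > 1L) {
      keep_n <- config$funnel[yi]
      prev <- do.call(rbind, env_rows)
      perf <- tapply(prev$value, prev$genotype, mean, na.rm = TRUE)
      perf <- perf[names(perf) %in% active]
      active <- names(sort(perf, decreasing = TRUE))[seq_len(keep_n)]
      active <- gens[gens %in% active]            # stable ordering
    }
    entries <- active
    block_list <- lapply(seq_len(nr), function(b) c(entries, checks))
    npb <- length(block_list[[1]])
    n_col <- ceiling(sqrt(npb))
    rows_per_block <- ceiling(npb / n_col)
    n_row_total <- rows_per_block * nr
    for (li in seq_len(nl)) {
      Rk <- draw_effects(n_row_total, sqrt(vc["row"]), config$seed,
                         100L + yi * 10L + li)
      Cl <- draw_effects(n_col, sqrt(vc["col"]), config$seed,
                         200L + yi * 10L + li)
      Bb <- draw_effects(nr, sqrt(vc["block"]), config$seed,
                         300L + yi * 10L + li)
      set.seed(substream(config$seed, 400L + yi * 10L + li))
      env_df <- do.call(rbind, lapply(seq_len(nr), function(b) {
        gvec <- sample(block_list[[b]])
        pos <- seq_along(gvec) - 1L
        r_local <- pos %/% n_col + 1L
        data.frame(genotype = gvec, location = locs[li], year = years[yi],
                   block = sprintf("b%d", b),
                   row = (b - 1L) * rows_per_block + r_local,
                   column = pos %% n_col + 1L,
                   stringsAsFactors = FALSE)
      }))
      eps <- draw_effects(nrow(env_df), sqrt(vc["error"]), config$seed,
                          500L + yi * 10L + li)
      env_df$value <- config$mu +
        G[env_df$genotype] +
        L[env_df$location] +
        A[as.character(env_df$year)] +
        LA[paste(env_df$location, env_df$year, sep = ":")] +
        Bb[as.integer(sub("^b", "", env_df$block))] +
        Rk[env_df$row] +
        Cl[env_df$column] +
        GL[paste(env_df$genotype, env_df$location, sep = ":")] +
        GA[paste(env_df$genotype, env_df$year, sep = ":")] +
        GLA[paste(env_df$genotype, env_df$location, env_df$year,
                  sep = ":")] +
        eps
      env_rows[[length(env_rows) + 1L]] <- env_df
    }
  }
  all_df <- do.call(rbind, env_rows)
  all_df$trait <- config$trait
  rng <- trait_range(config$trait)
  all_df$value <- pmin(pmax(all_df$value, rng[1]), rng[2])
  plots <- met_plots(all_df)
  structure(list(plots = plots,
                 truth = list(mu = config$mu, G = G, L = L, A = A, LA = LA,
                              GL = GL, GA = GA, GLA = GLA,
                              residual_sd = sqrt(vc["error"])),
                 config = config),
            class = "met_sim")
}

#' @export
print.met_sim <- function(x, ...) {
  cfg <- x$config
  cat("Simulated MET: ", cfg$n_genotypes, " genotypes, ",
      cfg$n_locations, " locations x ", cfg$n_years, " years, ",
      cfg$n_replicates, " replicates (", cfg$design, ")\n", sep = "")
  cat(nrow(x$plots), "plot observations of", cfg$trait, "\n")
  invisible(x)
}

#' Simulate a Finlay-Wilkinson structured BLUE table
#'
#' Generates `y_ij = mu + G_i + beta_i * E_j + error` with centred
#' environment effects, returning the table and the generating truth. Note
#' the identifiability of joint regression: the fitted environment index is
#' the realized environment mean, so slopes are recovered on the scale where
#' they average one -- supply `slopes` with mean 1 for exact noise-free
#' recovery.
#'
#' @param n_genotypes,n_environments table dimensions.
#' @param slopes numeric vector of true sensitivities, one per genotype.
#' @param mu grand mean.
#' @param g_sd standard deviation of genotype main effects.
#' @param env_sd standard deviation of environment effects.
#' @param noise_sd residual standard deviation.
#' @param seed integer seed.
#' @return List of class `fw_sim` with `blues` (a [blue_matrix]) and
#'   `truth` (`slopes`, `g`, `env`, `mu`).
#' @export
simulate_fw <- function(n_genotypes, n_environments, slopes,
                        mu = 0, g_sd = 1, env_sd = 1, noise_sd = 0,
                        seed = 1L) {
  if (length(slopes) != n_genotypes)
    stop("need one slope per genotype", call. = FALSE)
  gens <- sprintf("g%02d", seq_len(n_genotypes))
  years <- 2000L + seq_len(n_environments)
  g <- draw_effects(n_genotypes, g_sd, seed, 11L, gens)
  E <- draw_effects(n_environments, env_sd, seed, 12L, as.character(years))
  E <- E - mean(E)
  eps <- matrix(draw_effects(n_genotypes * n_environments, noise_sd,
                             seed, 13L),
                n_genotypes, n_environments)
  vals <- mu + outer(g, rep(1, n_environments)) + outer(slopes, E) + eps
  dimnames(vals) <- list(gens, env_label("loc1", years))
  structure(list(blues = blue_matrix(vals),
                 truth = list(slopes = setNames(slopes, gens), g = g,
                              env = E, mu = mu)),
            class = "fw_sim")
}

#' Simulate an evaluator score panel
#'
#' Generates `score = mu + G_i + evaluator_j + stage_k + error`, clips to the
#' scale bounds, and reports the clipped fraction. Intended for recovery
#' tests of [fit_score_model].
#'
#' @param n_evaluators,n_genotypes panel dimensions.
#' @param stages optional character vector of baking stages; `NULL` for a
#'   stage-free panel.
#' @param genotype_effects optional named numeric vector of true genotype
#'   effects; default draws them from `N(0, 1)`.
#' @param sigma2_evaluator,sigma2_stage,sigma2_error variances of the random
#'   terms.
#' @param mu grand mean on the score scale.
#' @param scale numeric `c(min, max)` score scale; defaults to the 10-point
#'   baker scale.
#' @param seed integer seed.
#' @return List of class `score_sim` with `scores` (a [score_records]
#'   table), `truth`, and `clip_fraction`.
#' @export
simulate_scores <- function(n_evaluators, n_genotypes, stages = NULL,
                            genotype_effects = NULL,
                            sigma2_evaluator = 1, sigma2_stage = 0,
                            sigma2_error = 1, mu = 7,
                            scale = c(1, 10), seed = 1L) {
  stopifnot(length(scale) == 2L, scale[1] < scale[2])
  gens <- sprintf("g%02d", seq_len(n_genotypes))
  evs <- sprintf("ev%02d", seq_len(n_evaluators))
  if (is.null(genotype_effects)) {
    genotype_effects <- draw_effects(n_genotypes, 1, seed, 21L, gens)
  } else {
    stopifnot(length(genotype_effects) == n_genotypes)
    genotype_effects <- setNames(as.numeric(genotype_effects), gens)
  }
  ev_eff <- draw_effects(n_evaluators, sqrt(sigma2_evaluator), seed, 22L,
                         evs)
  st <- if (is.null(stages)) NA_character_ else stages
  st_eff <- if (is.null(stages)) c(`NA` = 0) else
    draw_effects(length(stages), sqrt(sigma2_stage), seed, 23L, stages)
  grid <- expand.grid(evaluator = evs, genotype = gens, stage = st,
                      stringsAsFactors = FALSE)
  eps <- draw_effects(nrow(grid), sqrt(sigma2_error), seed, 24L)
  raw <- mu + genotype_effects[grid$genotype] + ev_eff[grid$evaluator] +
    (if (is.null(stages)) 0 else st_eff[grid$stage]) + eps
  clipped <- pmin(pmax(raw, scale[1]), scale[2])
  grid$score <- clipped
  grid$scale_min <- scale[1]
  grid$scale_max <- scale[2]
  structure(list(scores = score_records(grid),
                 truth = list(mu = mu, genotype = genotype_effects,
                              evaluator = ev_eff,
                              stage = if (is.null(stages)) NULL else st_eff,
                              residual_sd = sqrt(sigma2_error)),
                 clip_fraction = mean(clipped != raw)),
            class = "score_sim")
}
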