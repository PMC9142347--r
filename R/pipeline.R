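# End-to-end orchestration: simulate (or read) plot data, estimate BLUEs
# per environment, decompose variance, compute heritability, run the
# stability and GGE analyses (with an optional "no extremes" environment
# drop), compare genotypes to the check, and fit the evaluator score model.
# One master seed governs every stochastic stage; re-running an identical
# config yields byte-identical tables.

#' Default pipeline configuration
#'
#' @param out_dir output directory.
#' @param seed master seed for all stochastic stages.
#' @param ... overrides for any configuration entry (see Details).
#' @details Configuration entries: `trait`; `simulate` (arguments to
#'   [met_sim_config], or `NULL` when `plots_csv` is given); `plots_csv`
#'   (path to existing plot data); `spatial` (passed to [estimate_blues]);
#'   `drop_environments` (labels for the reduced stability analysis);
#'   `check` and `alpha` and `dunnett_environment` for the check
#'   comparison; `scores` (arguments to [simulate_scores], or
#'   `scores_csv`); `stages`, named logicals switching stages on and off.
#' @return Configuration list of class `met_pipeline_config`.
#' @export
pipeline_config <- function(out_dir = tempfile("metstab_"), seed = 1L,
                            ...) {
  cfg <- list(
    out_dir = out_dir, seed = as.integer(seed),
    trait = "yield_kg_ha",
    simulate = list(n_genotypes = 12L, n_locations = 2L, n_years = 3L,
                    n_replicates = 2L),
    plots_csv = NULL,
    spatial = "auto",
    drop_environments = character(),
    check = NULL, alpha = 0.05, dunnett_environment = NULL,
    scores = list(n_evaluators = 5L, n_genotypes = 5L,
                  sigma2_evaluator = 0.8, sigma2_error = 0.8),
    scores_csv = NULL,
    stages = list(blues = TRUE, varcomp = TRUE, heritability = TRUE,
                  stability = TRUE, gge = TRUE, dunnett = TRUE,
                  scores = TRUE))
  over <- list(...)
  for (nm in names(over)) {
    if (nm %in% c("simulate", "scores", "stages") && is.list(over[[nm]]))
      cfg[[nm]] <- modifyList(cfg[[nm]], over[[nm]])
    else cfg[[nm]] <- over[[nm]]
  }
  class(cfg) <- "met_pipeline_config"
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' @param path YAML file whose keys mirror [pipeline_config]'s entries.
#' @return A `met_pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  do.call(pipeline_config,
          c(y[intersect(names(y), c("out_dir", "seed"))],
            y[setdiff(names(y), c("out_dir", "seed"))]))
}

pipeline_stage <- function(log, name, enabled, expr) {
  if (!enabled) {
    log("stage", name, "skipped (disabled)")
    return(list(ran = FALSE, value = NULL))
  }
  log("stage", name, "start")
  value <- tryCatch(expr, error = function(e)
    stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
         call. = FALSE))
  log("stage", name, "done")
  list(ran = TRUE, value = value)
}

#' Run the full multi-environment trial analysis pipeline
#'
#' Executes every enabled stage in dependency order, writes one CSV per
#' stage into the output directory, and finishes with `manifest.json`
#' recording the configuration, the stages run or skipped, and an MD5
#' checksum per output file. Timestamps appear only in `run.log`, so two
#' runs of the same configuration produce identical checksums.
#'
#' @param config a `met_pipeline_config` (or a YAML path).
#' @return Invisibly, a list with the stage results and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config()) {
  if (is.character(config)) config <- read_pipeline_config(config)
  stopifnot(inherits(config, "met_pipeline_config"))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(config$out_dir, "run.log")
  con <- file(log_path, open = "wt")
  on.exit(close(con), add = TRUE)
  log <- function(...) writeLines(paste(format(Sys.time()), ...), con)
  outfile <- function(x) file.path(config$out_dir, x)
  written <- character()
  st <- config$stages
  results <- list()

  # --- input data -------------------------------------------------------
  if (!is.null(config$plots_csv)) {
    plots <- read_plot_csv(config$plots_csv)
    log("input: read", nrow(plots), "records from", config$plots_csv)
  } else {
    sim_args <- modifyList(config$simulate,
                           list(seed = config$seed, trait = config$trait))
    sim <- simulate_met(do.call(met_sim_config, sim_args))
    plots <- sim$plots
    results$simulation <- sim
    write_plot_csv(plots, outfile("plots.csv"))
    written <- c(written, "plots.csv")
    log("input: simulated", nrow(plots), "plot records")
  }
  trait <- config$trait

  # --- BLUEs per environment -------------------------------------------
  blues <- NULL
  r <- pipeline_stage(log, "blues", isTRUE(st$blues), {
    b <- blues_matrix(plots, trait, spatial = config$spatial)
    write_blues_csv(b, outfile("blues.csv"), outfile("blues_se.csv"))
    b
  })
  if (r$ran) {
    blues <- r$value
    written <- c(written, "blues.csv", "blues_se.csv")
    results$blues <- blues
  }

  # --- variance components & heritability ------------------------------
  vc <- NULL
  r <- pipeline_stage(log, "varcomp", isTRUE(st$varcomp), {
    v <- estimate_variance_components(plots, trait)
    bd <- attr(v, "boundary")
    for (nm in names(bd)[bd])
      log("varcomp: component", nm, "clamped at the zero boundary")
    df <- data.frame(component = names(unclass(v)),
                     variance = as.numeric(unclass(v)),
                     boundary = as.logical(bd))
    write.csv(df, outfile("varcomp.csv"), row.names = FALSE)
    v
  })
  if (r$ran) {
    vc <- r$value
    written <- c(written, "varcomp.csv")
    results$varcomp <- vc
  }

  r <- pipeline_stage(log, "heritability",
                      isTRUE(st$heritability) && !is.null(vc), {
    h <- heritability(vc)
    df <- data.frame(trait = trait, H2 = h$H2, n_a = h$n_a, n_l = h$n_l,
                     n_al = h$n_al, n_alr = h$n_alr)
    write.csv(df, outfile("heritability.csv"), row.names = FALSE)
    h
  })
  if (r$ran) {
    written <- c(written, "heritability.csv")
    results$heritability <- r$value
  }

  # --- stability --------------------------------------------------------
  r <- pipeline_stage(log, "stability",
                      isTRUE(st$stability) && !is.null(blues), {
    tab <- stability_table(blues, drop = config$drop_environments)
    write.csv(tab, outfile("stability.csv"), row.names = FALSE)
    tab
  })
  if (r$ran) {
    written <- c(written, "stability.csv")
    results$stability <- r$value
  }

  # --- GGE --------------------------------------------------------------
  r <- pipeline_stage(log, "gge", isTRUE(st$gge) && !is.null(blues), {
    m <- gge(blues)
    www <- which_won_where(m)
    co <- biplot_coords(m)
    df <- rbind(
      data.frame(type = "genotype", name = rownames(co$genotypes),
                 pc1 = co$genotypes[, 1], pc2 = co$genotypes[, 2],
                 winner = NA_character_, stringsAsFactors = FALSE),
      data.frame(type = "environment", name = rownames(co$environments),
                 pc1 = co$environments[, 1], pc2 = co$environments[, 2],
                 winner = www$table$winner, stringsAsFactors = FALSE))
    write.csv(df, outfile("gge.csv"), row.names = FALSE)
    log("gge:", www$n_mega, "mega-environment(s)")
    list(model = m, www = www)
  })
  if (r$ran) {
    written <- c(written, "gge.csv")
    results$gge <- r$value
  }

  # --- Dunnett ----------------------------------------------------------
  r <- pipeline_stage(log, "dunnett",
                      isTRUE(st$dunnett), {
    check <- config$check
    if (is.null(check)) check <- sort(unique(plots$genotype))[1]
    env <- config$dunnett_environment
    if (is.null(env)) {
      envs <- unique(plots[plots$trait == trait, c("location", "year")])
      envs <- envs[order_envs(envs$location, envs$year), ]
      env <- env_label(envs$location[nrow(envs)], envs$year[nrow(envs)])
    }
    ek <- parse_env(env)
    dt <- dunnett_test(plots, trait, ek$location, ek$year,
                       check = check, alpha = config$alpha)
    write.csv(as.data.frame(dt), outfile("dunnett.csv"),
              row.names = FALSE)
    log("dunnett: environment", env, "check", check,
        "critical difference",
        format(attr(dt, "critical_difference"), digits = 6))
    dt
  })
  if (r$ran) {
    written <- c(written, "dunnett.csv")
    results$dunnett <- r$value
  }

  # --- evaluator scores -------------------------------------------------
  r <- pipeline_stage(log, "scores", isTRUE(st$scores), {
    if (!is.null(config$scores_csv)) {
      sc <- read_scores_csv(config$scores_csv)
    } else {
      sargs <- modifyList(config$scores, list(seed = config$seed + 1L))
      sc <- do.call(simulate_scores, sargs)$scores
    }
    fitted <- fit_score_model(sc)
    write.csv(as.data.frame(fitted), outfile("scores_blues.csv"),
              row.names = FALSE)
    fitted
  })
  if (r$ran) {
    written <- c(written, "scores_blues.csv")
    results$scores <- r$value
  }

  # --- manifest ---------------------------------------------------------
  manifest <- list(
    package = "metstab",
    version = as.character(utils::packageVersion("metstab")),
    seed = config$seed,
    trait = trait,
    stages = lapply(st, isTRUE),
    files = as.list(tools::md5sum(file.path(config$out_dir, written))))
  names(manifest$files) <- written
  jsonlite::write_json(manifest, outfile("manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  log("pipeline complete:", length(written), "output file(s)")
  invisible(c(results, list(manifest = manifest,
                            out_dir = config$out_dir)))
}
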