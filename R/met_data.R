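#' metstab: multi-environment trial analysis and stability
#'
#' Tools for analysing multi-environment plant-breeding trials: spatially
#' corrected genotype BLUEs, crossed genotype x location x year variance
#' decomposition by REML, harmonic-mean broad-sense heritability,
#' Finlay-Wilkinson and Wricke stability statistics, GGE biplots,
#' Dunnett comparison against a check, Fusarium head blight scoring,
#' evaluator score models, and a synthetic trial generator with known truth.
#'
#' @keywords internal
#' @importFrom stats aggregate anova aov coef complete.cases cor lm logLik
#'   median model.matrix na.omit pnorm pt qt quantile rnorm sd setNames var
#'   vcov formula as.formula resid df.residual predict
#' @importFrom utils head read.csv write.csv modifyList
"_PACKAGE"

# ---------------------------------------------------------------------------
# Trait registry
# ---------------------------------------------------------------------------

#' Registry of recognised trait names and their admissible ranges
#'
#' Traits ending in `_pct` are percentages constrained to \[0, 100\];
#' `falling_number_s` must be strictly positive. Values are validated against
#' these ranges on read and on simulation output.
#'
#' @return A data frame with columns `trait`, `min`, `max`.
#' @export
met_traits <- function() {
  data.frame(
    trait = c("yield_kg_ha", "protein_pct", "falling_number_s", "ash_pct",
              "winter_survival_pct", "plant_height_cm", "fhb_score",
              "test_weight_kg_hl", "lodging_pct"),
    min = c(0, 0, 0, 0, 0, 0, 0, 0, 0),
    max = c(Inf, 100, Inf, 100, 100, Inf, 9, Inf, 100),
    stringsAsFactors = FALSE
  )
}

trait_range <- function(trait) {
  reg <- met_traits()
  i <- match(trait, reg$trait)
  if (is.na(i)) return(c(-Inf, Inf))
  c(reg$min[i], reg$max[i])
}

# strictly positive traits (zero is not a valid reading)
.strict_pos_traits <- "falling_number_s"

validate_trait_values <- function(trait, value, where = "value") {
  ok <- is.na(value) | is.finite(value)
  if (!all(ok))
    stop("non-finite ", where, " for trait '", trait, "' at records ",
         paste(which(!ok), collapse = ", "), call. = FALSE)
  rng <- trait_range(trait)
  bad <- !is.na(value) & (value < rng[1] | value > rng[2])
  if (trait %in% .strict_pos_traits)
    bad <- bad | (!is.na(value) & value <= 0)
  if (any(bad))
    stop("trait '", trait, "' has values outside [", rng[1], ", ", rng[2],
         "] at records ", paste(which(bad), collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

# ---------------------------------------------------------------------------
# Environment keys
# ---------------------------------------------------------------------------

#' Format and parse environment keys
#'
#' An environment is a location-year combination. The canonical label is
#' `"location:year"`; the canonical ordering is by year, then location, which
#' makes all tabulated output deterministic.
#'
#' @param location character vector of location names.
#' @param year integer vector of harvest years.
#' @return `env_label()` returns a character vector of labels;
#'   `parse_env()` returns a data frame with columns `location` and `year`.
#' @export
env_label <- function(location, year) paste(location, year, sep = ":")

#' @rdname env_label
#' @param label character vector of `"location:year"` labels.
#' @export
parse_env <- function(label) {
  m <- regmatches(label, regexec("^(.+):([0-9]+)$", label))
  bad <- vapply(m, length, 1L) != 3L
  if (any(bad))
    stop("malformed environment label(s): ",
         paste(label[bad], collapse = ", "), call. = FALSE)
  data.frame(location = vapply(m, `[`, "", 2L),
             year = as.integer(vapply(m, `[`, "", 3L)),
             stringsAsFactors = FALSE)
}

# canonical (year, location) ordering of environment labels
order_envs <- function(location, year) order(year, location)

# ---------------------------------------------------------------------------
# Plot observations
# ---------------------------------------------------------------------------

#' Construct a validated table of plot-level observations
#'
#' The long ("tidy") plot table is the package's central input: one row per
#' plot per trait, carrying the full design coordinates (genotype, location,
#' year, block, row, column). Genotype/block labels are kept as character;
#' row and column indices are 1-based field-book coordinates.
#'
#' @param df data frame with columns `genotype`, `location`, `year`, `block`,
#'   `row`, `column`, `trait`, `value`.
#' @return The validated data frame with class `met_plots`.
#' @export
met_plots <- function(df) {
  need <- c("genotype", "location", "year", "block", "row", "column",
            "trait", "value")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  df <- df[need]
  df$genotype <- as.character(df$genotype)
  df$location <- as.character(df$location)
  df$block    <- as.character(df$block)
  df$trait    <- as.character(df$trait)
  df$year     <- as.integer(df$year)
  df$row      <- as.integer(df$row)
  df$column   <- as.integer(df$column)
  df$value    <- as.numeric(df$value)
  if (any(!nzchar(df$location)) || any(is.na(df$year)))
    stop("location and year must be non-empty for every record",
         call. = FALSE)
  if (any(df$row < 1L, na.rm = TRUE) || any(df$column < 1L, na.rm = TRUE))
    stop("row and column indices are 1-based and must be >= 1",
         call. = FALSE)
  for (tr in unique(df$trait)) {
    sel <- df$trait == tr
    validate_trait_values(tr, df$value[sel])
  }
  key <- paste(df$location, df$year, df$row, df$column, df$trait, sep = "\r")
  dup <- duplicated(key)
  if (any(dup)) {
    lines <- which(key %in% key[dup])
    stop("duplicate (environment, row, column) plot position(s) at records ",
         paste(lines, collapse = ", "), call. = FALSE)
  }
  rownames(df) <- NULL
  class(df) <- c("met_plots", "data.frame")
  df
}

#' Read plot-level trial data from CSV
#'
#' Expects a wide field-book layout: columns `genotype,location,year,block,
#' row,column` plus one numeric column per trait. Empty cells and `NA` are
#' read as missing values (never as zero). A malformed numeric cell raises a
#' parse error naming the offending line and column; a duplicated
#' (environment, row, column) plot position raises a validation error listing
#' the colliding lines.
#'
#' @param path path to the CSV file.
#' @param traits optional character vector restricting which trait columns to
#'   keep; default: every column beyond the six design columns.
#' @return A [met_plots] data frame in long format.
#' @export
read_plot_csv <- function(path, traits = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.csv(path, colClasses = "character", check.names = FALSE,
                  strip.white = TRUE)
  design <- c("genotype", "location", "year", "block", "row", "column")
  miss <- setdiff(design, names(raw))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  trait_cols <- setdiff(names(raw), design)
  if (!is.null(traits)) trait_cols <- intersect(trait_cols, traits)
  if (!length(trait_cols))
    stop("no trait columns found in ", path, call. = FALSE)

  parse_num <- function(x, col) {
    x[!nzchar(x)] <- NA_character_
    x[x %in% c("NA", "na")] <- NA_character_
    out <- suppressWarnings(as.numeric(x))
    bad <- is.na(out) & !is.na(x)
    if (any(bad))
      stop("malformed numeric value in column '", col, "', line(s) ",
           paste(which(bad) + 1L, collapse = ", "), " of ", path,
           call. = FALSE)
    out
  }
  for (col in c("year", "row", "column"))
    raw[[col]] <- parse_num(raw[[col]], col)

  long <- do.call(rbind, lapply(trait_cols, function(tr) {
    data.frame(genotype = raw$genotype, location = raw$location,
               year = raw$year, block = raw$block,
               row = raw$row, column = raw$column,
               trait = tr, value = parse_num(raw[[tr]], tr),
               stringsAsFactors = FALSE)
  }))
  met_plots(long)
}

#' Write plot-level trial data to CSV
#'
#' Inverse of [read_plot_csv]: reshapes the long table back to the wide
#' field-book layout, with missing values as empty cells. A read-write-read
#' round trip is value identical.
#'
#' @param plots a [met_plots] data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_plot_csv <- function(plots, path) {
  stopifnot(inherits(plots, "met_plots"))
  design <- c("genotype", "location", "year", "block", "row", "column")
  wide <- stats::reshape(as.data.frame(plots), idvar = design,
                         timevar = "trait", direction = "wide")
  names(wide) <- sub("^value\\.", "", names(wide))
  wide <- wide[do.call(order, wide[c("year", "location", "row", "column")]), ]
  write.csv(wide, path, row.names = FALSE, na = "")
  invisible(path)
}

# ---------------------------------------------------------------------------
# Evaluator score records
# ---------------------------------------------------------------------------

#' Construct a validated table of evaluator score records
#'
#' One row per score an evaluator (baker or taster) assigned to a genotype,
#' optionally at a named baking stage. `scale_min`/`scale_max` carry the
#' score scale (1-10 for bakers, 1-5 for tasters) and every score must lie
#' within them.
#'
#' @param df data frame with columns `evaluator`, `genotype`, `stage`
#'   (may be `NA`), `score`, `scale_min`, `scale_max`.
#' @return The validated data frame with class `score_records`.
#' @export
score_records <- function(df) {
  need <- c("evaluator", "genotype", "stage", "score", "scale_min",
            "scale_max")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  df <- df[need]
  df$evaluator <- as.character(df$evaluator)
  df$genotype  <- as.character(df$genotype)
  df$stage     <- as.character(df$stage)
  df$score     <- as.numeric(df$score)
  df$scale_min <- as.numeric(df$scale_min)
  df$scale_max <- as.numeric(df$scale_max)
  if (any(df$scale_min >= df$scale_max))
    stop("scale_min must be < scale_max", call. = FALSE)
  out_of_scale <- !is.na(df$score) &
    (df$score < df$scale_min | df$score > df$scale_max)
  if (any(out_of_scale))
    stop("score outside its scale at records ",
         paste(which(out_of_scale), collapse = ", "), call. = FALSE)
  rownames(df) <- NULL
  class(df) <- c("score_records", "data.frame")
  df
}

#' Read or write evaluator score records
#'
#' CSV layout: `evaluator,genotype,stage,score,scale_min,scale_max`.
#' @param path path to CSV.
#' @return `read_scores_csv()` returns a [score_records] data frame.
#' @export
read_scores_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(df$stage)) df$stage[!nzchar(as.character(df$stage))] <- NA
  score_records(df)
}

#' @rdname read_scores_csv
#' @param scores a [score_records] data frame.
#' @export
write_scores_csv <- function(scores, path) {
  stopifnot(inherits(scores, "score_records"))
  write.csv(as.data.frame(scores), path, row.names = FALSE, na = "")
  invisible(path)
}

# ---------------------------------------------------------------------------
# BLUE matrix (genotype x environment two-way table)
# ---------------------------------------------------------------------------

#' Construct a genotype-by-environment BLUE matrix
#'
#' The two-way table of genotype BLUEs per environment is the input to all
#' stability and biplot analyses. Rows are genotypes (sorted), columns are
#' environments in canonical (year, location) order; cells may be missing.
#'
#' @param values numeric matrix, genotypes in rows, environments in columns;
#'   column names must be `"location:year"` labels.
#' @param se optional matching matrix of standard errors.
#' @return An object of class `blue_matrix`.
#' @export
blue_matrix <- function(values, se = NULL) {
  stopifnot(is.matrix(values), !is.null(rownames(values)),
            !is.null(colnames(values)))
  envs <- parse_env(colnames(values))
  o <- order_envs(envs$location, envs$year)
  g <- order(rownames(values))
  values <- values[g, o, drop = FALSE]
  envs <- envs[o, , drop = FALSE]
  rownames(envs) <- NULL
  if (!is.null(se)) {
    stopifnot(is.matrix(se), all(dim(se) == dim(values)))
    se <- se[g, o, drop = FALSE][rownames(values), colnames(values),
                                 drop = FALSE]
  }
  structure(values, se = se, environments = envs,
            class = c("blue_matrix", "matrix", "array"))
}

#' Assemble a BLUE matrix from per-environment records
#'
#' @param records data frame with columns `genotype`, `location`, `year`,
#'   `value` and optionally `se` -- at most one value per
#'   (genotype, environment). Conflicting duplicates are an error; exact
#'   duplicates are collapsed. Absent combinations become missing cells.
#' @return A [blue_matrix]. The result is invariant to the row order of
#'   `records`.
#' @export
two_way_table <- function(records) {
  need <- c("genotype", "location", "year", "value")
  miss <- setdiff(need, names(records))
  if (length(miss))
    stop("missing column(s): ", paste(miss, collapse = ", "), call. = FALSE)
  records$genotype <- as.character(records$genotype)
  env <- env_label(records$location, as.integer(records$year))
  key <- paste(records$genotype, env, sep = "\r")
  if (anyDuplicated(key)) {
    for (k in unique(key[duplicated(key)])) {
      v <- records$value[key == k]
      if (length(unique(v[!is.na(v)])) > 1L)
        stop("conflicting duplicate values for genotype '",
             records$genotype[key == k][1], "' in environment '",
             env[key == k][1], "'", call. = FALSE)
    }
    keep <- !duplicated(key)
    records <- records[keep, , drop = FALSE]
    env <- env[keep]
  }
  gens <- sort(unique(records$genotype))
  es <- unique(data.frame(location = records$location,
                          year = as.integer(records$year),
                          stringsAsFactors = FALSE))
  es <- es[order_envs(es$location, es$year), , drop = FALSE]
  labs <- env_label(es$location, es$year)
  vals <- matrix(NA_real_, length(gens), length(labs),
                 dimnames = list(gens, labs))
  vals[cbind(match(records$genotype, gens), match(env, labs))] <-
    records$value
  se <- NULL
  if ("se" %in% names(records)) {
    se <- matrix(NA_real_, length(gens), length(labs),
                 dimnames = list(gens, labs))
    se[cbind(match(records$genotype, gens), match(env, labs))] <-
      as.numeric(records$se)
  }
  blue_matrix(vals, se = se)
}

#' Completeness report for a BLUE matrix
#'
#' @param blues a [blue_matrix].
#' @return List with `overall` fraction of non-missing cells and per-row /
#'   per-column fractions `by_genotype`, `by_environment`.
#' @export
completeness <- function(blues) {
  stopifnot(inherits(blues, "blue_matrix"))
  obs <- !is.na(unclass(blues))
  list(overall = mean(obs),
       by_genotype = rowMeans(obs),
       by_environment = colMeans(obs))
}

#' @export
print.blue_matrix <- function(x, ...) {
  cat("Genotype x environment BLUE matrix: ", nrow(x), " genotypes x ",
      ncol(x), " environments\n", sep = "")
  cat(sprintf("Completeness: %.1f%% of cells observed\n",
              100 * completeness(x)$overall))
  print(format(round(unclass(x), 2)), quote = FALSE, ...)
  invisible(x)
}

#' Read or write a wide BLUE matrix CSV
#'
#' Layout: a `genotype` column followed by one `"location:year"` column per
#' environment. An optional parallel file carries standard errors.
#'
#' @param path path to the BLUE CSV.
#' @param se_path optional path to the matching SE CSV.
#' @return `read_blues_csv()` returns a [blue_matrix].
#' @export
read_blues_csv <- function(path, se_path = NULL) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (names(df)[1] != "genotype")
    stop("first column of a BLUE table must be 'genotype'", call. = FALSE)
  vals <- as.matrix(df[-1])
  rownames(vals) <- df$genotype
  se <- NULL
  if (!is.null(se_path)) {
    sdf <- read.csv(se_path, check.names = FALSE, stringsAsFactors = FALSE)
    se <- as.matrix(sdf[-1])
    rownames(se) <- sdf$genotype
    se <- se[rownames(vals), colnames(vals), drop = FALSE]
  }
  blue_matrix(vals, se = se)
}

#' @rdname read_blues_csv
#' @param blues a [blue_matrix].
#' @export
write_blues_csv <- function(blues, path, se_path = NULL) {
  stopifnot(inherits(blues, "blue_matrix"))
  df <- data.frame(genotype = rownames(blues), unclass(blues),
                   check.names = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  se <- attr(blues, "se")
  if (!is.null(se_path) && !is.null(se)) {
    sdf <- data.frame(genotype = rownames(blues), se, check.names = FALSE)
    write.csv(sdf, se_path, row.names = FALSE, na = "")
  }
  invisible(path)
}
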