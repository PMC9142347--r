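# GGE analysis: environment-centred SVD of the BLUE table. Column centring
# removes the environment main effects, so the retained structure is
# genotype main effect plus genotype-by-environment interaction -- exactly
# what a breeder ranks genotypes on within an environment. Winners are
# computed on the exact centred matrix; the familiar rank-2 polygon view is
# reported alongside for comparison with the visual convention.

#' Fit a GGE model (environment-centred SVD)
#'
#' Subtracts each environment's mean from its column (no scaling by
#' default), computes the singular value decomposition, and applies a
#' deterministic sign convention (the largest-magnitude entry of each
#' genotype-score axis is positive), making repeated fits identical.
#'
#' @param blues a complete [blue_matrix] (missing cells are an error; this
#'   model does no imputation).
#' @param scale divide each centred column by its standard deviation
#'   (default `FALSE`; the GGE convention is centring only).
#' @return Object of class `gge`: list with the centred matrix, singular
#'   values `d`, genotype scores `u`, environment loadings `v`,
#'   `var_explained` fractions, and the per-environment exact winners.
#' @export
gge <- function(blues, scale = FALSE) {
  stopifnot(inherits(blues, "blue_matrix"))
  x <- unclass(blues)
  if (anyNA(x))
    stop("BLUE table has missing cells; GGE requires a complete table",
         call. = FALSE)
  if (nrow(x) < 2L || ncol(x) < 2L)
    stop("need >= 2 genotypes and >= 2 environments", call. = FALSE)
  centred <- sweep(x, 2L, colMeans(x))
  if (scale) {
    s <- apply(centred, 2L, sd)
    if (any(s == 0)) stop("cannot scale a zero-variance environment",
                          call. = FALSE)
    centred <- sweep(centred, 2L, s, "/")
  }
  sv <- svd(centred)
  # deterministic sign: largest-|.| element of each genotype-score axis > 0
  for (k in seq_along(sv$d)) {
    j <- which.max(abs(sv$u[, k]))
    if (sv$u[j, k] < 0) {
      sv$u[, k] <- -sv$u[, k]
      sv$v[, k] <- -sv$v[, k]
    }
  }
  rownames(sv$u) <- rownames(x)
  rownames(sv$v) <- colnames(x)
  winners <- rownames(x)[apply(centred, 2L, which.max)]
  structure(list(centred = centred, d = sv$d, u = sv$u, v = sv$v,
                 var_explained = sv$d^2 / sum(sv$d^2),
                 winners = setNames(winners, colnames(x)),
                 scaled = scale),
            class = "gge")
}

#' @export
print.gge <- function(x, ...) {
  cat("GGE model:", nrow(x$u), "genotypes x", nrow(x$v), "environments\n")
  ve <- round(100 * x$var_explained[seq_len(min(4, length(x$d)))], 1)
  cat("Variance explained (%):", paste(ve, collapse = ", "),
      if (length(x$d) > 4) "...", "\n")
  cat("Winners:", paste(names(x$winners), x$winners, sep = "=",
                        collapse = ", "), "\n")
  invisible(x)
}

#' Biplot coordinates for the first two GGE axes
#'
#' Genotype coordinates `U D^f`, environment coordinates `V D^(1-f)`; the
#' symmetric scaling `f = 0.5` is the default. At any `f` the inner product
#' of the two coordinate sets reconstructs the rank-2 approximation of the
#' centred matrix.
#'
#' @param model a fitted [gge] model.
#' @param f scaling exponent in \[0, 1\].
#' @param k number of axes (default 2).
#' @return List with matrices `genotypes` and `environments` (k columns
#'   each) and the axis `var_explained`.
#' @export
biplot_coords <- function(model, f = 0.5, k = 2L) {
  stopifnot(inherits(model, "gge"))
  if (f < 0 || f > 1) stop("f must lie in [0, 1]", call. = FALSE)
  k <- min(k, length(model$d))
  dk <- model$d[seq_len(k)]
  list(genotypes = model$u[, seq_len(k), drop = FALSE] %*%
         diag(dk^f, k, k),
       environments = model$v[, seq_len(k), drop = FALSE] %*%
         diag(dk^(1 - f), k, k),
       var_explained = model$var_explained[seq_len(k)])
}

#' @export
plot.gge <- function(x, f = 0.5, ...) {
  co <- biplot_coords(x, f = f)
  g <- co$genotypes; e <- co$environments
  lim <- range(c(g[, 1:2], e[, 1:2])) * 1.1
  plot(g[, 1], g[, 2], xlim = lim, ylim = lim, pch = 19,
       xlab = sprintf("PC1 (%.1f%%)", 100 * co$var_explained[1]),
       ylab = sprintf("PC2 (%.1f%%)", 100 * co$var_explained[2]),
       main = "GGE biplot", ...)
  graphics::text(g[, 1], g[, 2], rownames(g), pos = 3, cex = 0.7)
  graphics::arrows(0, 0, e[, 1], e[, 2], length = 0.08, col = 4)
  graphics::text(e[, 1], e[, 2], rownames(e), pos = 4, col = 4, cex = 0.7)
  graphics::abline(h = 0, v = 0, lty = 3)
  invisible(x)
}

#' Which-won-where mega-environment partition
#'
#' Assigns each environment the genotype with the largest centred value
#' (the exact winner), and groups environments sharing a winner into
#' mega-environments. The rank-2 winner implied by the biplot polygon view
#' is reported alongside; the two coincide whenever the first two axes
#' carry all the variation.
#'
#' @param model a fitted [gge] model.
#' @return Object of class `which_won_where`: list with `table`
#'   (environment, exact winner, rank-2 winner), `mega_environments`
#'   (environments grouped by exact winner), and `n_mega`.
#' @export
which_won_where <- function(model) {
  stopifnot(inherits(model, "gge"))
  k <- min(2L, length(model$d))
  rank2 <- model$u[, seq_len(k), drop = FALSE] %*%
    diag(model$d[seq_len(k)], k, k) %*%
    t(model$v[, seq_len(k), drop = FALSE])
  w2 <- rownames(model$u)[apply(rank2, 2L, which.max)]
  tab <- data.frame(environment = colnames(model$centred),
                    winner = unname(model$winners),
                    winner_rank2 = w2, stringsAsFactors = FALSE)
  mega <- split(tab$environment, tab$winner)
  structure(list(table = tab, mega_environments = mega,
                 n_mega = length(mega)),
            class = "which_won_where")
}

#' @export
print.which_won_where <- function(x, ...) {
  cat(x$n_mega, "mega-environment(s):\n")
  for (w in names(x$mega_environments))
    cat("  ", w, ": ", paste(x$mega_environments[[w]], collapse = ", "),
        "\n", sep = "")
  invisible(x)
}
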