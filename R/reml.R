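# REML fitting surface. All three model families used by the package --
# per-environment design/spatial correction with fixed genotype, the
# all-random crossed genotype x location x year decomposition, and the
# evaluator score model -- are instances of
#   y ~ N(X tau,  sum_r sigma2_r Z_r Z_r' + sigma2_e I)
# fitted by restricted maximum likelihood (lme4), with estimated marginal
# means (emmeans) giving genotype BLUEs at population level.

lmer_quiet_control <- function() {
  lme4::lmerControl(check.nobs.vs.nlev = "ignore",
                    check.nobs.vs.rankZ = "ignore",
                    check.nobs.vs.nRE = "ignore",
                    calc.derivs = FALSE)
}

build_mixed_formula <- function(response, fixed, random) {
  rhs <- if (length(fixed)) paste(fixed, collapse = " + ") else "1"
  if (length(random))
    rhs <- paste(rhs, paste(sprintf("(1 | %s)", random), collapse = " + "),
                 sep = " + ")
  as.formula(paste(response, "~", rhs))
}

#' Fit a linear mixed model by REML
#'
#' General entry point for the package's variance-component models: a
#' response, an ordered set of fixed factors (intercept implicit), and a set
#' of random intercept terms, each mapped to one variance component.
#' Interaction terms are written `"a:b"`. With no random terms an ordinary
#' least-squares fit is returned in the same container (its residual
#' variance is then the REML estimate RSS / (n - p)).
#'
#' @param data data frame; all referenced terms are coerced to factors.
#' @param response name of the response column.
#' @param fixed character vector of fixed factor names.
#' @param random character vector of random (intercept) terms.
#' @return Object of class `reml_fit`: variance estimates (named, residual
#'   last), fixed-effect estimates and covariance, REML log-likelihood,
#'   convergence/boundary flags, and the underlying fitted model.
#' @export
reml_fit <- function(data, response, fixed = character(),
                     random = character()) {
  data <- as.data.frame(data)
  if (!response %in% names(data))
    stop("response '", response, "' not found", call. = FALSE)
  vars <- unique(unlist(strsplit(c(fixed, random), ":", fixed = TRUE)))
  miss <- setdiff(vars, names(data))
  if (length(miss))
    stop("model term column(s) not found: ", paste(miss, collapse = ", "),
         call. = FALSE)
  both <- intersect(fixed, random)
  if (length(both))
    stop("term(s) both fixed and random: ", paste(both, collapse = ", "),
         call. = FALSE)
  for (v in vars) data[[v]] <- factor(data[[v]])
  data <- data[!is.na(data[[response]]), , drop = FALSE]
  if (length(unique(data[[response]])) < 2L)
    stop("response is degenerate (constant or empty)", call. = FALSE)
  fml <- build_mixed_formula(response, fixed, random)

  if (!length(random)) {
    fit <- lm(fml, data = data)
    p <- fit$rank
    if (any(is.na(coef(fit)))) {
      al <- names(coef(fit))[is.na(coef(fit))]
      stop("singular fixed-effects design; aliased: ",
           paste(al, collapse = ", "), call. = FALSE)
    }
    s2 <- sum(resid(fit)^2) / (nrow(data) - p)
    out <- list(varcomp = c(residual = s2),
                fixef = coef(fit), vcov_fixef = vcov(fit),
                loglik = as.numeric(logLik(fit, REML = TRUE)),
                n_obs = nrow(data), n_fixed = p,
                converged = TRUE, boundary = logical(0),
                formula = fml, model = fit, data = data)
    class(out) <- "reml_fit"
    return(out)
  }

  fit <- suppressMessages(suppressWarnings(
    lme4::lmer(fml, data = data, REML = TRUE,
               control = lmer_quiet_control())))
  # optimizer return code: nonnegative codes are successes; -4 is
  # roundoff-limited termination (typical of perfect-fit boundaries, the
  # solution is still valid); everything else is a genuine failure
  code <- fit@optinfo$conv$opt
  if (!is.null(code) && length(code) && !(code >= 0L || code == -4L))
    stop("REML fit did not converge (optimizer code ", code, "): ",
         paste(unlist(fit@optinfo$conv$lme4$messages), collapse = "; "),
         call. = FALSE)
  vc <- as.data.frame(lme4::VarCorr(fit))
  v <- setNames(vc$vcov, vc$grp)
  names(v)[names(v) == "Residual"] <- "residual"
  # report in the order the terms were given, residual last
  ord <- c(random[random %in% names(v)],
           setdiff(names(v), c(random, "residual")), "residual")
  v <- v[ord]
  fe <- lme4::fixef(fit)
  out <- list(varcomp = v,
              fixef = fe, vcov_fixef = as.matrix(vcov(fit)),
              loglik = as.numeric(logLik(fit)),
              n_obs = nrow(data), n_fixed = length(fe),
              converged = TRUE,
              boundary = v[names(v) != "residual"] <
                1e-8 * max(v["residual"], 1e-300),
              formula = fml, model = fit, data = data)
  class(out) <- "reml_fit"
  out
}

#' @export
print.reml_fit <- function(x, ...) {
  cat("REML fit:", deparse(x$formula), "\n")
  cat("n =", x$n_obs, " fixed parameters =", x$n_fixed,
      " REML log-lik =", format(x$loglik, digits = 6), "\n")
  cat("Variance components:\n")
  v <- data.frame(variance = x$varcomp)
  if (length(x$boundary))
    v$boundary <- c(ifelse(x$boundary, "*", ""), "")[seq_len(nrow(v))]
  print(v, ...)
  if (any(x$boundary))
    cat("(* variance estimate at the zero boundary)\n")
  invisible(x)
}

#' @export
summary.reml_fit <- function(object, ...) {
  print(object)
  cat("\nFixed effects:\n")
  se <- sqrt(diag(object$vcov_fixef))
  print(data.frame(estimate = object$fixef, se = se))
  invisible(object)
}

#' @export
coef.reml_fit <- function(object, ...) object$fixef

#' @export
logLik.reml_fit <- function(object, ...) {
  structure(object$loglik, df = length(object$varcomp) + object$n_fixed,
            class = "logLik")
}

# REML AIC used for spatial-term selection: fixed effects are identical
# across candidates, so only the variance-parameter count enters the penalty
reml_aic <- function(fit) -2 * fit$loglik + 2 * length(fit$varcomp)
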