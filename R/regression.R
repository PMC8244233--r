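# Estimation contracts used by every analysis stage: ordinary least squares
# and maximum-likelihood logistic regression, both with covariates, both
# returning coefficient vectors with a variance-covariance matrix. Fits are
# delegated to stats::lm / stats::glm; the contracts add strict failure
# modes (rank deficiency, separation, non-convergence are errors, never
# silent warnings) and a common result container.

#' Ordinary least squares with covariates
#'
#' @param formula model formula.
#' @param data data.frame.
#' @return an object of class `vitdmr_fit` with elements `coefficients`,
#'   `se`, `vcov`, `r_squared`, `n`, `fitted`, `residuals`, `rss`,
#'   `type = "linear"`.
#' @details Rank-deficient designs raise an error naming the collinear
#'   columns. `r_squared` is the classical coefficient of determination, used
#'   downstream for instrument strength.
#' @export
linear_fit <- function(formula, data) {
  fit <- stats::lm(formula, data = data)
  if (any(is.na(stats::coef(fit))))
    stop_("rank-deficient design; collinear columns: ",
          paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                collapse = ", "))
  if (fit$df.residual < 1)
    stop_("sample size must exceed the number of predictors")
  sm <- summary(fit)
  structure(list(
    coefficients = stats::coef(fit),
    se = sm$coefficients[, "Std. Error"],
    vcov = stats::vcov(fit),
    r_squared = sm$r.squared,
    n = length(fit$residuals),
    fitted = stats::fitted(fit),
    residuals = stats::residuals(fit),
    rss = sum(stats::residuals(fit)^2),
    formula = formula,
    type = "linear"), class = "vitdmr_fit")
}

#' Maximum-likelihood logistic regression with covariates
#'
#' Iteratively reweighted least squares with relative tolerance 1e-10 and at
#' most 100 iterations; non-convergence is an error. Complete or
#' quasi-complete separation (fitted probabilities numerically 0/1 together
#' with runaway coefficients) and single-class outcomes are errors, never
#' silently diverging fits.
#'
#' @param formula model formula; the response must be binary (0/1 or
#'   logical).
#' @param data data.frame.
#' @return an object of class `vitdmr_fit` with elements `coefficients`
#'   (log-odds scale), `se`, `vcov`, `n`, `fitted`, `loglik`,
#'   `type = "logistic"`.
#' @export
logistic_fit <- function(formula, data) {
  y <- eval(formula[[2]], data)
  if (length(unique(stats::na.omit(as.integer(y)))) < 2L)
    stop_("outcome has a single class; logistic regression is undefined")
  sep_warn <- FALSE
  fit <- withCallingHandlers(
    stats::glm(formula, data = data, family = stats::binomial(),
               control = stats::glm.control(epsilon = 1e-10, maxit = 100)),
    warning = function(w) {
      if (grepl("fitted probabilities numerically 0 or 1", conditionMessage(w)))
        sep_warn <<- TRUE
      invokeRestart("muffleWarning")
    })
  if (!fit$converged)
    stop_("logistic regression did not converge in 100 iterations")
  if (any(is.na(stats::coef(fit))))
    stop_("rank-deficient design; collinear columns: ",
          paste(names(stats::coef(fit))[is.na(stats::coef(fit))],
                collapse = ", "))
  if (sep_warn && max(abs(stats::coef(fit))) > 15)
    stop_("complete or quasi-complete separation detected; ",
          "the maximum-likelihood estimate does not exist")
  sm <- summary(fit)
  structure(list(
    coefficients = stats::coef(fit),
    se = sm$coefficients[, "Std. Error"],
    vcov = stats::vcov(fit),
    n = length(fit$y),
    fitted = stats::fitted(fit),
    loglik = as.numeric(stats::logLik(fit)),
    formula = formula,
    type = "logistic"), class = "vitdmr_fit")
}

#' @export
print.vitdmr_fit <- function(x, ...) {
  cat(sprintf("%s fit (n = %d)\n", x$type, x$n))
  tab <- data.frame(beta = x$coefficients, se = x$se)
  if (x$type == "logistic") tab$or <- exp(tab$beta)
  tab$p <- wald_p(tab$beta, tab$se)
  print(round(tab, 4))
  invisible(x)
}

#' Extract one coefficient as an association estimate
#'
#' The common currency of the MR layer: a coefficient on the link scale with
#' its standard error, normal-approximation 95% CI (`beta +/- 1.96 se`),
#' two-sided Wald p-value, a role tag and the adjustment set.
#'
#' @param fit a `vitdmr_fit`.
#' @param term coefficient name.
#' @param role one of `"beta_ZX"` (instrument-exposure), `"beta_ZY"`
#'   (instrument-outcome), `"beta_XY"` (observational exposure-outcome),
#'   `"beta_GRS_VD"` (GRS-25(OH)D), or `""`.
#' @param snp optional rsid, carried for Wald-ratio bookkeeping.
#' @return an object of class `association_estimate`: list with `beta`,
#'   `se`, `ci95`, `p`, `role`, `n`, `adjusted_for`, `snp`.
#' @export
association_estimate <- function(fit, term, role = "", snp = NULL) {
  if (!term %in% names(fit$coefficients))
    stop_("no coefficient named '", term, "' in the fit")
  beta <- unname(fit$coefficients[term])
  se <- unname(fit$se[term])
  adjusted <- setdiff(names(fit$coefficients), c("(Intercept)", term))
  structure(list(beta = beta, se = se, ci95 = ci95(beta, se),
                 p = wald_p(beta, se), role = role, n = fit$n,
                 adjusted_for = adjusted, snp = snp),
            class = "association_estimate")
}

#' @export
print.association_estimate <- function(x, ...) {
  cat(sprintf("%s%s: beta = %.4f (se %.4f), 95%% CI [%.4f, %.4f], p = %.3g, n = %d\n",
              x$role, if (!is.null(x$snp)) paste0(" [", x$snp, "]") else "",
              x$beta, x$se, x$ci95[1], x$ci95[2], x$p, x$n))
  invisible(x)
}

# Build "y ~ x1 + x2" from character pieces; terms are backtick-quoted so
# CSV-dictionary column names pass through untouched.
build_formula <- function(response, terms) {
  rhs <- if (length(terms)) paste(sprintf("`%s`", terms), collapse = " + ")
         else "1"
  stats::as.formula(paste(sprintf("`%s`", response), "~", rhs))
}
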