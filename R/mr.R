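# Causal machinery of the one-sample MR analysis: instrument strength
# (Cragg-Donald F), per-SNP Wald ratios with delta-method uncertainty,
# fixed-effect inverse-variance weighted (IVW) pooling, MR-Egger regression
# for directional pleiotropy, the Wald-type GRS estimator, and the
# two-stage regression sensitivity estimator, all rescalable to odds ratios
# per 25 (or 10) nmol/L decrease in 25(OH)D.

#' Cragg-Donald F statistic for instrument strength
#'
#' `F = R^2 (n - 2) / (1 - R^2)`, where `R^2` is the proportion of exposure
#' variance explained by the instrument. F > 10 is the conventional
#' adequacy threshold for MR.
#'
#' @param r_squared proportion of exposure variance explained, in `[0, 1)`.
#' @param n sample size (> 2).
#' @return a list of class `instrument_strength`: `r_squared`, `n`,
#'   `f_statistic`, `usable_instrument` (`F > 10`).
#' @export
f_statistic <- function(r_squared, n) {
  if (!is_scalar_number(r_squared) || r_squared < 0 || r_squared >= 1)
    stop_("r_squared must lie in [0, 1); an R^2 of 1 gives an infinite F")
  if (!is_scalar_number(n) || n <= 2)
    stop_("n must exceed 2")
  f <- r_squared * (n - 2) / (1 - r_squared)
  structure(list(r_squared = r_squared, n = n, f_statistic = f,
                 usable_instrument = f > 10), class = "instrument_strength")
}

#' Per-SNP Wald ratio causal estimate
#'
#' `beta_IV = beta_ZY / beta_ZX`, the SNP-outcome coefficient divided by the
#' SNP-exposure coefficient, with the two-term delta-method standard error
#' `se_IV = sqrt(se_ZY^2 / beta_ZX^2 + beta_ZY^2 se_ZX^2 / beta_ZX^4)`.
#' The covariance between the two one-sample coefficients is ignored
#' (documented limitation; see the methods vignette).
#'
#' @param beta_zy SNP-outcome [association_estimate()] (log-odds per
#'   allele).
#' @param beta_zx SNP-exposure [association_estimate()] (nmol/L per allele,
#'   non-zero).
#' @return a list of class `wald_ratio_result`: `snp`, `beta_iv`, `se_iv`,
#'   `ci95`, `variance_weight` (`1/se_iv^2`).
#' @export
wald_ratio <- function(beta_zy, beta_zx) {
  if (!is.null(beta_zy$snp) && !is.null(beta_zx$snp) &&
      !identical(beta_zy$snp, beta_zx$snp))
    stop_("mismatched SNPs: ", beta_zy$snp, " vs ", beta_zx$snp)
  if (!is_scalar_number(beta_zx$beta) || beta_zx$beta == 0)
    stop_("beta_ZX is zero; the Wald ratio is undefined")
  b <- beta_zy$beta / beta_zx$beta
  se <- sqrt(beta_zy$se^2 / beta_zx$beta^2 +
             beta_zy$beta^2 * beta_zx$se^2 / beta_zx$beta^4)
  structure(list(snp = beta_zy$snp %||% beta_zx$snp,
                 beta_iv = b, se_iv = se, ci95 = ci95(b, se),
                 variance_weight = 1 / se^2),
            class = "wald_ratio_result")
}

#' Fixed-effect inverse-variance weighted pooling of Wald ratios
#'
#' `beta_IVW = sum(w_j beta_IV_j) / sum(w_j)` with `w_j = 1 / var(beta_IV_j)`
#' and pooled standard error `1 / sqrt(sum(w_j))`.
#'
#' @param ratios a list of [wald_ratio()] results.
#' @return a list of class `ivw_result`: `pooled_beta`, `pooled_se`, `ci95`,
#'   `p`, `n_snps`.
#' @export
ivw_pool <- function(ratios) {
  if (length(ratios) < 1L) stop_("at least one Wald ratio is required")
  b <- vapply(ratios, function(r) r$beta_iv, numeric(1))
  v <- vapply(ratios, function(r) r$se_iv^2, numeric(1))
  if (any(!is.finite(b)) || any(!is.finite(v) | v <= 0))
    stop_("all Wald ratios and variances must be finite (variances positive)")
  w <- 1 / v
  pooled <- sum(w * b) / sum(w)
  se <- 1 / sqrt(sum(w))
  structure(list(pooled_beta = pooled, pooled_se = se,
                 ci95 = ci95(pooled, se), p = wald_p(pooled, se),
                 n_snps = length(ratios)), class = "ivw_result")
}

#' MR-Egger regression for directional pleiotropy
#'
#' Weighted least squares of the SNP-outcome coefficients on the
#' SNP-exposure coefficients with an unconstrained intercept, weights
#' `1/se_ZY^2`. A non-zero intercept indicates directional pleiotropy; its
#' two-sided p-value is computed against a t reference with `n_snps - 2`
#' degrees of freedom (with four SNPs, 2 df). All `beta_ZX` must be oriented
#' to the same exposure direction (positive) before calling; negative values
#' are an error, not silently re-oriented.
#'
#' With fewer than three SNPs the regression is undefined and a result with
#' `defined = FALSE` is returned instead of numbers.
#'
#' @param per_snp a data.frame with columns `beta_zx`, `beta_zy`, `se_zy`
#'   (optionally `snp`).
#' @return a list of class `egger_result`: `defined`, `intercept`,
#'   `intercept_se`, `intercept_p`, `slope`, `slope_se`, `slope_p`, `df`.
#' @export
egger_regression <- function(per_snp) {
  need <- c("beta_zx", "beta_zy", "se_zy")
  if (!all(need %in% names(per_snp)))
    stop_("per_snp must have columns ", paste(need, collapse = ", "))
  k <- nrow(per_snp)
  if (k < 3L)
    return(structure(list(defined = FALSE, n_snps = k), class = "egger_result"))
  if (any(per_snp$beta_zx < 0))
    stop_("beta_ZX must be positive after orientation; re-orient the SNPs ",
          "to a common exposure-increasing direction first")
  if (any(!is.finite(per_snp$se_zy) | per_snp$se_zy <= 0))
    stop_("se_zy must be finite and positive")
  w <- 1 / per_snp$se_zy^2
  X <- cbind(intercept = 1, slope = per_snp$beta_zx)
  XtWX <- crossprod(X, w * X)
  XtWy <- crossprod(X, w * per_snp$beta_zy)
  beta <- drop(solve(XtWX, XtWy))
  resid <- per_snp$beta_zy - drop(X %*% beta)
  df <- k - 2L
  sigma2 <- sum(w * resid^2) / df
  covb <- sigma2 * solve(XtWX)
  se <- sqrt(diag(covb))
  tstat <- beta / se
  p <- 2 * stats::pt(-abs(tstat), df = df)
  structure(list(defined = TRUE, n_snps = k,
                 intercept = beta[["intercept"]],
                 intercept_se = se[["intercept"]],
                 intercept_p = p[["intercept"]],
                 slope = beta[["slope"]], slope_se = se[["slope"]],
                 slope_p = p[["slope"]], df = df),
            class = "egger_result")
}

#' Wald-type GRS instrumental-variable odds ratio
#'
#' Combines the GRS-outcome odds ratio with the GRS-25(OH)D linear
#' coefficient: the causal log-odds per nmol/L of 25(OH)D is
#' `ln(OR_ZY) / beta_GRS_VD`, and the reported odds ratio is
#' `exp(-scale * .)` per `scale` nmol/L *decrease* (or `exp(+scale * .)` per
#' increase). The confidence interval applies the same monotone map to the
#' CI of `ln(OR_ZY)`, treating `beta_GRS_VD` as fixed (the two-stage
#' estimator provides the alternative uncertainty treatment).
#'
#' @param or_zy odds ratio per unit GRS (> 0).
#' @param beta_grs_vd nmol/L of 25(OH)D per unit GRS (non-zero).
#' @param scale nmol/L rescaling, 25 by default (10 for per-10 estimates).
#' @param direction report per-`scale` `"decrease"` (default) or
#'   `"increase"` in 25(OH)D.
#' @param or_zy_ci optional 95% CI of `or_zy` (length 2); derived from
#'   `se_log_or` when supplied instead.
#' @param se_log_or optional standard error of `ln(or_zy)`.
#' @return a list of class `grs_iv_result`: `or_iv`, `ci95`, `p` (when an
#'   uncertainty input was given), `log_or_per_nmol`, `scale`, `direction`,
#'   `estimator = "wald_type"`.
#' @export
grs_iv_wald <- function(or_zy, beta_grs_vd, scale = 25,
                        direction = c("decrease", "increase"),
                        or_zy_ci = NULL, se_log_or = NULL) {
  direction <- match.arg(direction)
  if (!is_scalar_number(or_zy) || or_zy <= 0)
    stop_("or_zy must be a finite positive odds ratio")
  if (!is_scalar_number(beta_grs_vd) || beta_grs_vd == 0)
    stop_("beta_grs_vd must be finite and non-zero")
  s <- if (direction == "decrease") -scale else scale
  map <- function(log_or) exp(s * log_or / beta_grs_vd)
  or_iv <- map(log(or_zy))
  ci <- p <- NULL
  if (is.null(or_zy_ci) && !is.null(se_log_or))
    or_zy_ci <- exp(ci95(log(or_zy), se_log_or))
  if (!is.null(or_zy_ci)) {
    ci <- sort(map(log(or_zy_ci)))
    if (is.null(se_log_or))
      se_log_or <- (log(or_zy_ci[2]) - log(or_zy_ci[1])) / (2 * 1.96)
    p <- wald_p(log(or_zy), se_log_or)
  }
  structure(list(or_iv = or_iv, ci95 = ci, p = p,
                 log_or_per_nmol = log(or_zy) / beta_grs_vd,
                 or_zy = or_zy, beta_grs_vd = beta_grs_vd,
                 scale = scale, direction = direction,
                 estimator = "wald_type"), class = "grs_iv_result")
}

#' Two-stage regression estimator
#'
#' Stage 1 regresses 25(OH)D on the GRS (plus covariates) by least squares
#' and forms fitted 25(OH)D values; stage 2 fits a logistic regression of
#' the outcome on the fitted values (plus the same covariates). The causal
#' odds ratio per `scale` nmol/L decrease is `exp(-scale * b2)` where `b2`
#' is the stage-2 coefficient on fitted 25(OH)D.
#'
#' Instrument strength is the Cragg-Donald F computed from the partial R^2
#' of the GRS given the covariates (the simple regression R^2 when there are
#' none). An F of 10 or below attaches a prominent weak-instrument warning
#' to the result (and raises an R warning); it is not an error.
#'
#' @param cohort a phenotyped cohort data.frame.
#' @param grs numeric vector of per-person scores, or the name of a column
#'   of `cohort`.
#' @param outcome name of the binary outcome column.
#' @param covariates character vector of covariate column names.
#' @param exposure name of the exposure column (default `"vitd_nmol_l"`).
#' @param scale nmol/L rescaling of the reported odds ratio.
#' @param direction report per-`scale` `"decrease"` or `"increase"`.
#' @return a list of class `grs_iv_result` with `or_iv`, `ci95`, `p`,
#'   `log_or_per_nmol` (stage-2 coefficient), `beta_grs_vd` (stage-1 GRS
#'   coefficient), `strength` ([f_statistic()] result), `weak_instrument`,
#'   `stage1`, `stage2` (the underlying fits), `estimator = "two_stage"`.
#' @export
two_stage_estimate <- function(cohort, grs, outcome, covariates = character(),
                               exposure = "vitd_nmol_l", scale = 25,
                               direction = c("decrease", "increase")) {
  direction <- match.arg(direction)
  dat <- as.data.frame(cohort)
  if (is.character(grs) && length(grs) == 1L) {
    if (!grs %in% names(dat)) stop_("no GRS column '", grs, "'")
    dat$.grs <- dat[[grs]]
  } else {
    if (length(grs) != nrow(dat)) stop_("grs length must match the cohort")
    dat$.grs <- grs
  }
  if (anyNA(dat$.grs)) stop_("GRS contains missing values")
  stage1 <- linear_fit(build_formula(exposure, c(".grs", covariates)), dat)
  rss_without_grs <- if (length(covariates)) {
    linear_fit(build_formula(exposure, covariates), dat)$rss
  } else {
    sum((dat[[exposure]] - mean(dat[[exposure]]))^2)
  }
  partial_r2 <- 1 - stage1$rss / rss_without_grs
  strength <- f_statistic(partial_r2, stage1$n)
  weak <- !strength$usable_instrument
  if (weak)
    warning("weak instrument: Cragg-Donald F = ",
            format(strength$f_statistic, digits = 4),
            " (<= 10); IV estimates may be unreliable", call. = FALSE)
  dat$.fitted_vitd <- stage1$fitted
  stage2 <- logistic_fit(build_formula(outcome, c(".fitted_vitd", covariates)),
                         dat)
  b2 <- unname(stage2$coefficients[".fitted_vitd"])
  se2 <- unname(stage2$se[".fitted_vitd"])
  s <- if (direction == "decrease") -scale else scale
  or_iv <- exp(s * b2)
  ci <- sort(exp(s * ci95(b2, se2)))
  structure(list(or_iv = or_iv, ci95 = ci, p = wald_p(b2, se2),
                 log_or_per_nmol = b2, se_log_or_per_nmol = se2,
                 beta_grs_vd = unname(stage1$coefficients[".grs"]),
                 strength = strength, weak_instrument = weak,
                 scale = scale, direction = direction,
                 n = stage2$n, stage1 = stage1, stage2 = stage2,
                 estimator = "two_stage"), class = "grs_iv_result")
}

#' @export
print.grs_iv_result <- function(x, ...) {
  cat(sprintf("GRS IV estimate (%s): OR = %.4f per %g nmol/L %s",
              x$estimator, x$or_iv, x$scale, x$direction))
  if (!is.null(x$ci95))
    cat(sprintf(" [95%% CI %.4f, %.4f]", x$ci95[1], x$ci95[2]))
  if (!is.null(x$p)) cat(sprintf(", p = %.3g", x$p))
  cat("\n")
  if (isTRUE(x$weak_instrument))
    cat("WARNING: weak instrument (Cragg-Donald F <= 10)\n")
  invisible(x)
}

#' Per-SNP instrument-exposure and instrument-outcome associations
#'
#' For each panel SNP: the linear per-allele effect on 25(OH)D (`beta_zx`,
#' with its simple-regression R^2 and Cragg-Donald F) and the logistic
#' per-allele log-odds on the outcome (`beta_zy`). Genotypes are oriented so
#' that every counted allele raises 25(OH)D (positive `beta_zx` in
#' expectation), the orientation required by [egger_regression()].
#'
#' @param cohort a phenotyped cohort.
#' @param panel SNP panel.
#' @param outcome binary outcome column name.
#' @param covariates optional covariates for both regressions.
#' @param exposure exposure column (default `"vitd_nmol_l"`).
#' @return a data.frame with one row per SNP: `snp`, `gene`, `class`,
#'   `beta_zx`, `se_zx`, `p_zx`, `r_squared`, `f_statistic`, `beta_zy`,
#'   `se_zy`, `p_zy`.
#' @export
snp_associations <- function(cohort, panel, outcome,
                             covariates = character(),
                             exposure = "vitd_nmol_l") {
  dat <- as.data.frame(cohort)
  rows <- lapply(seq_len(nrow(panel)), function(i) {
    rsid <- panel$rsid[i]
    col <- paste0("snp_", rsid)
    if (!col %in% names(dat)) stop_("no genotype column ", col)
    g <- dat[[col]]
    if (panel$coded_allele[i] == "vitd_decreasing") g <- 2L - g
    dat$.g <- g
    fx <- linear_fit(build_formula(exposure, c(".g", covariates)), dat)
    fy <- logistic_fit(build_formula(outcome, c(".g", covariates)), dat)
    r2 <- if (length(covariates)) {
      rss0 <- linear_fit(build_formula(exposure, covariates), dat)$rss
      1 - fx$rss / rss0
    } else fx$r_squared
    data.frame(snp = rsid, gene = panel$gene[i],
               class = panel$functional_class[i],
               beta_zx = unname(fx$coefficients[".g"]),
               se_zx = unname(fx$se[".g"]),
               p_zx = wald_p(fx$coefficients[".g"], fx$se[".g"]),
               r_squared = r2,
               f_statistic = f_statistic(r2, fx$n)$f_statistic,
               beta_zy = unname(fy$coefficients[".g"]),
               se_zy = unname(fy$se[".g"]),
               p_zy = wald_p(fy$coefficients[".g"], fy$se[".g"]),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Full per-SNP MR analysis for one outcome
#'
#' Computes per-SNP associations ([snp_associations()]), per-SNP Wald
#' ratios, the fixed-effect IVW pooled estimate (all panel SNPs and the
#' synthesis SNPs alone) and the MR-Egger pleiotropy assessment.
#'
#' @inheritParams snp_associations
#' @return a list with `per_snp`, `wald_ratios`, `ivw`, `ivw_synthesis`
#'   (when >= 1 synthesis SNP), `egger`.
#' @export
snp_mr <- function(cohort, panel, outcome, covariates = character(),
                   exposure = "vitd_nmol_l") {
  per_snp <- snp_associations(cohort, panel, outcome, covariates, exposure)
  ratios <- lapply(seq_len(nrow(per_snp)), function(i) {
    zx <- structure(list(beta = per_snp$beta_zx[i], se = per_snp$se_zx[i],
                         snp = per_snp$snp[i]), class = "association_estimate")
    zy <- structure(list(beta = per_snp$beta_zy[i], se = per_snp$se_zy[i],
                         snp = per_snp$snp[i]), class = "association_estimate")
    wald_ratio(zy, zx)
  })
  synth <- per_snp$class == "synthesis"
  # MR-Egger requires a common exposure-increasing orientation; per the
  # standard convention, SNPs whose estimated beta_zx comes out negative
  # (sampling noise on a weak instrument) are sign-flipped as (x, y) pairs
  per_egger <- per_snp
  neg <- per_egger$beta_zx < 0
  per_egger$beta_zx[neg] <- -per_egger$beta_zx[neg]
  per_egger$beta_zy[neg] <- -per_egger$beta_zy[neg]
  list(per_snp = per_snp,
       wald_ratios = ratios,
       ivw = ivw_pool(ratios),
       ivw_synthesis = if (any(synth)) ivw_pool(ratios[synth]) else NULL,
       egger = egger_regression(per_egger))
}

#' GRS-based MR analysis for one panel and one outcome
#'
#' Scores the GRS (orientation `"decreasing"`: per unit higher score =
#' genetically lower 25(OH)D), estimates the GRS-outcome odds ratio
#' (`OR_ZY`, logistic) and the GRS-25(OH)D coefficient (`beta_GRS_VD`,
#' linear), then forms both the Wald-type ([grs_iv_wald()]) and the
#' two-stage ([two_stage_estimate()]) causal odds ratio per `scale` nmol/L
#' decrease in 25(OH)D.
#'
#' @param cohort a phenotyped cohort.
#' @param panel SNP panel rows forming the score (see [panel_subset()]).
#' @param outcome binary outcome column name.
#' @param covariates covariate column names.
#' @param orientation allele-counting direction for the score.
#' @param scale nmol/L rescaling.
#' @param exposure exposure column.
#' @return a list with `or_zy` ([association_estimate()] exponentiated
#'   fields), `beta_grs_vd`, `wald_type`, `two_stage`, `strength`.
#' @export
grs_mr <- function(cohort, panel, outcome, covariates = character(),
                   orientation = c("decreasing", "increasing"),
                   scale = 25, exposure = "vitd_nmol_l") {
  orientation <- match.arg(orientation)
  dat <- as.data.frame(cohort)
  dat$.grs <- compute_grs(dat, panel, orientation)
  fy <- logistic_fit(build_formula(outcome, c(".grs", covariates)), dat)
  zy <- association_estimate(fy, ".grs", role = "beta_ZY")
  fx <- linear_fit(build_formula(exposure, c(".grs", covariates)), dat)
  zx <- association_estimate(fx, ".grs", role = "beta_GRS_VD")
  direction <- "decrease"
  wald <- grs_iv_wald(exp(zy$beta), zx$beta, scale = scale,
                      direction = direction, se_log_or = zy$se)
  ts <- withCallingHandlers(
    two_stage_estimate(dat, ".grs", outcome, covariates,
                       exposure = exposure, scale = scale,
                       direction = direction),
    warning = function(w) invokeRestart("muffleWarning"))
  list(or_zy = list(or = exp(zy$beta), ci95 = exp(zy$ci95), p = zy$p,
                    se_log_or = zy$se),
       beta_grs_vd = zx,
       wald_type = wald,
       two_stage = ts,
       strength = ts$strength,
       weak_instrument = ts$weak_instrument,
       n = fy$n)
}
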