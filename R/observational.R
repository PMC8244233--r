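# Observational analyses: adjusted odds ratios for disease by 25(OH)D
# trend (per 10 / per 25 nmol/L decrease), cohort quintile and clinical
# category, and the quintile descriptive comparison table.

#' Default adjustment sets
#'
#' MS models adjust for age, BMI, WHR, income, smoking, alcohol, physical
#' activity and family history; T2D models use the same set without smoking.
#' The MR models use the full set. The presets are overridable in every
#' analysis function.
#'
#' @param outcome outcome column name.
#' @return character vector of covariate column names.
#' @export
default_covariates <- function(outcome = c("ms_case", "t2d_case",
                                           "abnormal_sbp", "abnormal_dbp")) {
  outcome <- match.arg(outcome)
  full <- c("age", "bmi", "whr", "income", "smoking", "alcohol",
            "physical_activity", "family_history")
  if (outcome == "t2d_case") setdiff(full, "smoking") else full
}

#' @rdname default_covariates
#' @export
mr_covariates <- function() {
  c("age", "bmi", "whr", "income", "smoking", "alcohol",
    "physical_activity", "family_history")
}

as_model_frame <- function(cohort) {
  dat <- as.data.frame(cohort)
  for (col in c("income", "smoking", "alcohol", "sex")) {
    if (col %in% names(dat) && !is.factor(dat[[col]])) {
      lv <- switch(col,
        income  = c("<2000", "2000-3499", "3500-4999", ">=5000"),
        smoking = c("never", "former", "current"),
        alcohol = c("never", "former", "current"),
        sex     = c("female", "male"))
      lv <- union(intersect(lv, unique(dat[[col]])),
                  unique(dat[[col]]))
      dat[[col]] <- factor(dat[[col]], levels = lv)
    }
  }
  dat
}

#' Trend odds ratio per 10 or 25 nmol/L decrease in 25(OH)D
#'
#' Fits `logistic(outcome ~ vitd + covariates)` and reports
#' `OR = exp(-scale * beta)` with the CI transformed by the same monotone
#' map, so per-10 and per-25 estimates from the same fit satisfy
#' `OR_25 = OR_10^2.5` exactly.
#'
#' @param cohort a phenotyped cohort.
#' @param outcome binary outcome column.
#' @param scale 10 or 25 (nmol/L decrease).
#' @param covariates adjustment set; defaults to [default_covariates()].
#' @return a list of class `observational_result` with `outcome`,
#'   `exposure_coding`, `or`, `ci95`, `p`, `beta_per_nmol`, `n`, `cases`,
#'   `adjusted_for`.
#' @export
trend_or <- function(cohort, outcome, scale = 25,
                     covariates = default_covariates(outcome)) {
  dat <- as_model_frame(cohort)
  fit <- logistic_fit(build_formula(outcome, c("vitd_nmol_l", covariates)),
                      dat)
  est <- association_estimate(fit, "vitd_nmol_l", role = "beta_XY")
  or <- exp(-scale * est$beta)
  ci <- sort(exp(-scale * est$ci95))
  structure(list(outcome = outcome,
                 exposure_coding = paste0("per", scale, "_decrease"),
                 or = or, ci95 = ci, p = est$p,
                 beta_per_nmol = est$beta, n = fit$n,
                 cases = sum(dat[[outcome]], na.rm = TRUE),
                 adjusted_for = covariates),
            class = "observational_result")
}

#' Categorical odds ratios by 25(OH)D quintile or clinical category
#'
#' Logistic regression with indicator contrasts; the reference is the
#' highest-concentration level (quintile Q1 / sufficiency), whose OR is
#' exactly 1 and carries no CI. Empty levels are reported as inestimable and
#' the fit proceeds on the remaining levels.
#'
#' @param cohort a phenotyped cohort.
#' @param outcome binary outcome column.
#' @param coding `"quintile"`, `"clinical_category"`, or the name of any
#'   factor column of the cohort.
#' @param covariates adjustment set.
#' @return a list of class `observational_result` with a `levels`
#'   data.frame: `level`, `n`, `cases`, `case_pct`, `or`, `ci_lo`, `ci_hi`,
#'   `p`, `reference`, `estimable`.
#' @export
categorical_or <- function(cohort, outcome, coding = "quintile",
                           covariates = default_covariates(outcome)) {
  dat <- as_model_frame(cohort)
  col <- switch(coding, quintile = "vitd_quintile",
                clinical_category = "vitd_category", coding)
  if (!col %in% names(dat)) stop_("no exposure column '", col, "'")
  f <- dat[[col]]
  if (!is.factor(f)) f <- factor(f)
  all_levels <- levels(f)
  counts <- table(factor(f, levels = all_levels))
  empty <- all_levels[counts == 0]
  f <- droplevels(f)
  if (nlevels(f) < 2L) stop_("need at least two populated exposure levels")
  dat$.exposure <- f
  fit <- logistic_fit(build_formula(outcome, c(".exposure", covariates)), dat)
  ref <- levels(f)[1]
  rows <- lapply(all_levels, function(lv) {
    n_lv <- sum(f == lv)
    cases <- sum(dat[[outcome]][f == lv], na.rm = TRUE)
    base <- data.frame(level = lv, n = n_lv, cases = cases,
                       case_pct = if (n_lv > 0) 100 * cases / n_lv else NA_real_,
                       stringsAsFactors = FALSE)
    if (lv %in% empty)
      return(cbind(base, or = NA_real_, ci_lo = NA_real_, ci_hi = NA_real_,
                   p = NA_real_, reference = FALSE, estimable = FALSE))
    if (lv == ref)
      return(cbind(base, or = 1, ci_lo = NA_real_, ci_hi = NA_real_,
                   p = NA_real_, reference = TRUE, estimable = TRUE))
    term <- paste0(".exposure", lv)
    est <- association_estimate(fit, term, role = "beta_XY")
    cbind(base, or = exp(est$beta), ci_lo = exp(est$ci95[1]),
          ci_hi = exp(est$ci95[2]), p = est$p, reference = FALSE,
          estimable = TRUE)
  })
  structure(list(outcome = outcome, exposure_coding = coding,
                 reference_level = ref,
                 levels = do.call(rbind, rows),
                 n = fit$n, adjusted_for = covariates),
            class = "observational_result")
}

#' @export
print.observational_result <- function(x, ...) {
  cat(sprintf("Observational association: %s ~ 25(OH)D [%s]\n",
              x$outcome, x$exposure_coding))
  if (!is.null(x$levels)) print(x$levels, row.names = FALSE)
  else cat(sprintf("  OR = %.3f [%.3f, %.3f], p = %.3g (n = %d)\n",
                   x$or, x$ci95[1], x$ci95[2], x$p, x$n))
  invisible(x)
}

fmt_mean_sd <- function(x) sprintf("%.2f ± %.2f", mean(x), stats::sd(x))
fmt_med_iqr <- function(x) sprintf("%.2f (%.2f)", stats::median(x),
                                   stats::quantile(x, 0.75) - stats::quantile(x, 0.25))

#' Descriptive comparison of clinical characteristics across 25(OH)D
#' quintiles
#'
#' Per quintile: n, mean +/- SD for approximately normal variables (age,
#' BMI, waist circumference, SBP, DBP), median (IQR) for skewed variables
#' (fasting glucose, insulin, HOMA-IR, triglycerides, HDL-c) and percentages
#' for categorical variables. Group comparisons use one-way ANOVA,
#' Kruskal-Wallis and Pearson chi-square tests respectively.
#'
#' @param cohort a phenotyped cohort (with `vitd_quintile`).
#' @return a data.frame with columns `variable`, `summary`, `test`, one
#'   column per quintile (Q1 highest ... Q5 lowest) and `p_value`.
#' @export
quintile_descriptives <- function(cohort) {
  dat <- as_model_frame(cohort)
  if (!"vitd_quintile" %in% names(dat))
    stop_("cohort must be phenotyped first (missing vitd_quintile)")
  q <- dat$vitd_quintile
  qs <- levels(q)
  normal_vars <- c(age = "age", bmi = "bmi", wc_cm = "wc_cm",
                   sbp_mmhg = "sbp_mmhg", dbp_mmhg = "dbp_mmhg")
  skewed_vars <- c(fbg_mmol_l = "fbg_mmol_l", insulin_uiu_ml = "insulin_uiu_ml",
                   homa_ir = "homa_ir", tg_mmol_l = "tg_mmol_l",
                   hdl_mmol_l = "hdl_mmol_l")
  cat_vars <- c(sex = "sex", ms_case = "ms_case", t2d_case = "t2d_case",
                family_history = "family_history")
  safe_p <- function(expr) tryCatch(expr, error = function(e) NA_real_)
  row_for <- function(var, type) {
    x <- dat[[var]]
    if (type == "normal") {
      cells <- vapply(qs, function(l) fmt_mean_sd(x[q == l]), character(1))
      p <- safe_p(summary(stats::aov(x ~ q))[[1]][["Pr(>F)"]][1])
      test <- "anova"
    } else if (type == "skewed") {
      cells <- vapply(qs, function(l) fmt_med_iqr(x[q == l]), character(1))
      p <- safe_p(stats::kruskal.test(x, q)$p.value)
      test <- "kruskal_wallis"
    } else {
      xf <- factor(x)
      lead <- levels(xf)[nlevels(xf)]
      cells <- vapply(qs, function(l) {
        sel <- q == l
        sprintf("%d (%.2f%%)", sum(xf[sel] == lead),
                100 * mean(xf[sel] == lead))
      }, character(1))
      p <- if (nlevels(xf) < 2L) NA_real_ else
        safe_p(suppressWarnings(stats::chisq.test(table(xf, q))$p.value))
      test <- "chi_square"
    }
    out <- data.frame(variable = var,
                      summary = switch(type, normal = "mean_sd",
                                       skewed = "median_iqr", "n_pct"),
                      test = test, stringsAsFactors = FALSE)
    for (i in seq_along(qs)) out[[qs[i]]] <- cells[i]
    out$p_value <- p
    out
  }
  header <- data.frame(variable = "n", summary = "count", test = "",
                       stringsAsFactors = FALSE)
  for (l in qs) header[[l]] <- as.character(sum(q == l))
  header$p_value <- NA_real_
  rows <- c(list(header),
            lapply(normal_vars, row_for, type = "normal"),
            lapply(skewed_vars, row_for, type = "skewed"),
            lapply(cat_vars, row_for, type = "categorical"))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
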