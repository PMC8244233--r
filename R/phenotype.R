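# Phenotype derivation: repeated-measurement averaging, anthropometric and
# insulin-resistance indices, metabolic syndrome and type 2 diabetes
# classification, vitamin-D clinical categories and cohort quintiles, and
# the abnormal blood pressure outcomes.

#' Average duplicate (or triplicate) field measurements
#'
#' Field protocol: a measurement is taken twice; if the two readings differ
#' by more than the protocol tolerance (1 cm for circumferences, 1 kg for
#' weight, 10 mmHg for blood pressure) a third reading is taken and the two
#' closest readings are averaged. When the third reading is exactly
#' equidistant from both earlier ones, it is averaged with the *earlier* of
#' the two original readings (deterministic tie rule).
#'
#' @param readings numeric vector of 2 or 3 readings, in measurement order.
#' @param tolerance maximum acceptable difference between the first two
#'   readings, in the same units.
#' @return the protocol average.
#' @examples
#' average_repeated(c(80.0, 80.5), tolerance = 1)       # 80.25
#' average_repeated(c(80.0, 82.0, 80.6), tolerance = 1) # 80.3
#' @export
average_repeated <- function(readings, tolerance) {
  if (!is.numeric(readings) || length(readings) < 2L)
    stop_("at least two readings are required")
  if (!is_scalar_number(tolerance) || tolerance <= 0)
    stop_("tolerance must be a positive number")
  if (length(readings) == 2L) {
    if (abs(readings[1] - readings[2]) > tolerance)
      stop_("first two readings differ by more than the tolerance; ",
            "a third reading is required")
    return(mean(readings))
  }
  if (length(readings) > 3L) stop_("at most three readings are allowed")
  d12 <- abs(readings[1] - readings[2])
  d13 <- abs(readings[1] - readings[3])
  d23 <- abs(readings[2] - readings[3])
  # closest pair wins; on a (r1,r3) vs (r2,r3) tie, keep the earlier original
  pairs <- list(c(1, 3), c(2, 3), c(1, 2))
  dist <- c(d13, d23, d12)
  mean(readings[pairs[[which.min(dist)]]])
}

#' Homeostasis model assessment of insulin resistance
#'
#' `HOMA-IR = FBG (mmol/L) x insulin (uIU/mL) / 22.5`.
#'
#' @param fbg fasting blood glucose, mmol/L (> 0).
#' @param insulin fasting insulin, uIU/mL (> 0).
#' @return the HOMA-IR index.
#' @export
homa_ir <- function(fbg, insulin) {
  if (any(!is.finite(fbg) | fbg <= 0) || any(!is.finite(insulin) | insulin <= 0))
    stop_("fbg and insulin must be finite and strictly positive")
  fbg * insulin / 22.5
}

#' Insulin unit conversion
#'
#' Descriptive tables often report insulin in pmol/L while HOMA-IR requires
#' uIU/mL; 1 uIU/mL = 6.945 pmol/L.
#'
#' @param x insulin concentration.
#' @return converted concentration.
#' @export
insulin_uiu_to_pmol <- function(x) x * 6.945

#' @rdname insulin_uiu_to_pmol
#' @export
insulin_pmol_to_uiu <- function(x) x / 6.945

#' Body mass index and waist-hip ratio
#'
#' @param weight kg (> 0).
#' @param height m (> 0).
#' @param wc waist circumference, cm (> 0).
#' @param hc hip circumference, cm (> 0).
#' @return `bmi()`: kg/m^2; `whr()`: waist/hip ratio.
#' @export
bmi <- function(weight, height) {
  if (any(!is.finite(weight) | weight <= 0) || any(!is.finite(height) | height <= 0))
    stop_("weight and height must be finite and strictly positive")
  weight / height^2
}

#' @rdname bmi
#' @export
whr <- function(wc, hc) {
  if (any(!is.finite(wc) | wc <= 0) || any(!is.finite(hc) | hc <= 0))
    stop_("waist and hip circumference must be finite and strictly positive")
  wc / hc
}

#' Metabolic syndrome component flags (joint interim statement, Asian waist
#' cutoffs)
#'
#' The five components: central obesity (WC >= 85 cm men / >= 80 cm women);
#' triglycerides >= 1.7 mmol/L or TG-lowering medication; HDL-c < 1.0 mmol/L
#' men / < 1.3 mmol/L women or HDL-raising treatment; blood pressure SBP >=
#' 130 or DBP >= 85 mmHg or antihypertensive medication; fasting glucose >=
#' 5.6 mmol/L or anti-diabetic medication. MS is >= 3 of the 5. Medication
#' always implies the component abnormal, even with a normal measured value.
#'
#' Records missing a required field are flagged unclassifiable (`NA` flags),
#' never silently dropped.
#'
#' @param sex `"male"` / `"female"`.
#' @param wc waist circumference, cm.
#' @param tg triglycerides, mmol/L.
#' @param hdl HDL cholesterol, mmol/L.
#' @param sbp,dbp blood pressure, mmHg.
#' @param fbg fasting glucose, mmol/L.
#' @param med_tg,med_hdl,med_bp,med_dm medication flags (logical/0-1).
#' @return a `data.frame` with logical columns `central_obesity`, `high_tg`,
#'   `low_hdl`, `high_bp`, `high_glucose`, integer `n_abnormal`, logical
#'   `ms_case` and `unclassifiable`.
#' @export
classify_ms <- function(sex, wc, tg, hdl, sbp, dbp, fbg,
                        med_tg = FALSE, med_hdl = FALSE,
                        med_bp = FALSE, med_dm = FALSE) {
  n <- max(length(sex), length(wc))
  args <- list(sex = sex, wc = wc, tg = tg, hdl = hdl, sbp = sbp, dbp = dbp,
               fbg = fbg, med_tg = med_tg, med_hdl = med_hdl,
               med_bp = med_bp, med_dm = med_dm)
  args <- lapply(args, rep_len, n)
  if (any(!args$sex %in% c("male", "female") & !is.na(args$sex)))
    stop_("sex must be 'male' or 'female'")
  male <- args$sex == "male"
  flags <- data.frame(
    central_obesity = ifelse(male, args$wc >= 85, args$wc >= 80),
    high_tg      = args$tg >= 1.7 | as.logical(args$med_tg),
    low_hdl      = ifelse(male, args$hdl < 1.0, args$hdl < 1.3) |
                   as.logical(args$med_hdl),
    high_bp      = args$sbp >= 130 | args$dbp >= 85 | as.logical(args$med_bp),
    high_glucose = args$fbg >= 5.6 | as.logical(args$med_dm))
  unclassifiable <- apply(is.na(flags), 1, any) | is.na(args$sex)
  flags[unclassifiable, ] <- NA
  flags$n_abnormal <- as.integer(rowSums(flags))
  flags$ms_case <- flags$n_abnormal >= 3L
  flags$unclassifiable <- unclassifiable
  flags
}

#' Type 2 diabetes classification
#'
#' A case is fasting glucose >= 7.0 mmol/L, and/or 2-h OGTT >= 11.1 mmol/L,
#' and/or anti-diabetic treatment, and/or a prior physician diagnosis. A
#' missing OGTT contributes nothing; a missing FBG yields `NA` unless another
#' criterion already classifies the person as a case.
#'
#' @param fbg fasting glucose, mmol/L.
#' @param ogtt 2-h oral glucose tolerance test, mmol/L (may be `NA`).
#' @param med_dm anti-diabetic medication flag.
#' @param prior_diagnosis prior physician diagnosis flag.
#' @return logical vector of case status.
#' @export
classify_t2d <- function(fbg, ogtt = NA_real_, med_dm = FALSE,
                         prior_diagnosis = FALSE) {
  n <- max(length(fbg), length(ogtt), length(med_dm), length(prior_diagnosis))
  fbg <- rep_len(fbg, n); ogtt <- rep_len(ogtt, n)
  med_dm <- rep_len(as.logical(med_dm), n)
  prior_diagnosis <- rep_len(as.logical(prior_diagnosis), n)
  by_fbg  <- !is.na(fbg) & fbg >= 7.0
  by_ogtt <- !is.na(ogtt) & ogtt >= 11.1
  case <- by_fbg | by_ogtt | med_dm | prior_diagnosis
  case[is.na(fbg) & !case] <- NA
  case
}

#' Vitamin D clinical category
#'
#' Half-open intervals partitioning the positive axis: severe deficiency
#' `[0, 25)`, deficiency `[25, 50)`, insufficiency `[50, 75)`, sufficiency
#' `[75, Inf)` nmol/L. The factor levels are ordered from sufficiency
#' (modelling reference) down to severe deficiency.
#'
#' @param vitd serum 25(OH)D, nmol/L (> 0).
#' @return a factor with levels `sufficiency`, `insufficiency`,
#'   `deficiency`, `severe_deficiency`.
#' @export
vitd_category <- function(vitd) {
  if (any(!is.finite(vitd) | vitd <= 0))
    stop_("25(OH)D concentrations must be finite and strictly positive")
  f <- cut(vitd, breaks = c(0, 25, 50, 75, Inf), right = FALSE,
           labels = c("severe_deficiency", "deficiency", "insufficiency",
                      "sufficiency"))
  factor(f, levels = c("sufficiency", "insufficiency", "deficiency",
                       "severe_deficiency"))
}

#' Cohort quintiles of 25(OH)D
#'
#' Quintile boundaries are the empirical 20/40/60/80th percentiles of the
#' analysis cohort. Labels run from Q1 = highest concentration (the
#' modelling reference) to Q5 = lowest. A value equal to a boundary is
#' assigned to the lower-concentration quintile.
#'
#' @param vitd serum 25(OH)D, nmol/L.
#' @return a factor with levels `Q1` (highest) ... `Q5` (lowest).
#' @export
vitd_quintiles <- function(vitd) {
  if (any(!is.finite(vitd) | vitd <= 0))
    stop_("25(OH)D concentrations must be finite and strictly positive")
  breaks <- stats::quantile(vitd, probs = seq(0, 1, 0.2), names = FALSE)
  idx <- cut(vitd, breaks = breaks, include.lowest = TRUE, right = TRUE,
             labels = FALSE)
  factor(paste0("Q", 6L - idx), levels = paste0("Q", 1:5))
}

#' Abnormal systolic / diastolic blood pressure outcomes
#'
#' Abnormal SBP is SBP >= 130 mmHg, abnormal DBP is DBP >= 85 mmHg. With
#' `med_rule = "include"` (default) antihypertensive medication marks both
#' outcomes abnormal regardless of the measured value; `"exclude"` applies
#' the thresholds only. Both modes are provided because published binary
#' blood pressure outcomes do not always state whether the medication clause
#' is applied.
#'
#' @param sbp,dbp blood pressure, mmHg.
#' @param med_bp antihypertensive medication flag.
#' @param med_rule `"include"` or `"exclude"` the medication clause.
#' @return a `data.frame` with logical columns `abnormal_sbp`,
#'   `abnormal_dbp`.
#' @export
abnormal_bp <- function(sbp, dbp, med_bp = FALSE,
                        med_rule = c("include", "exclude")) {
  med_rule <- match.arg(med_rule)
  n <- max(length(sbp), length(dbp), length(med_bp))
  sbp <- rep_len(sbp, n); dbp <- rep_len(dbp, n)
  med <- rep_len(as.logical(med_bp), n)
  if (med_rule == "exclude") med <- rep(FALSE, n)
  data.frame(abnormal_sbp = sbp >= 130 | med,
             abnormal_dbp = dbp >= 85 | med)
}

#' Derive all analysis variables for a cohort
#'
#' Adds `bmi`, `whr`, `homa_ir`, the five MS component flags with
#' `n_abnormal` and `ms_case`, `t2d_case`, `abnormal_sbp`/`abnormal_dbp`,
#' `vitd_category` and `vitd_quintile` to a raw cohort table.
#'
#' @param cohort a cohort data.frame (see [generate_cohort()] /
#'   [read_cohort()]).
#' @param bp_med_rule medication rule for the binary blood pressure
#'   outcomes, see [abnormal_bp()].
#' @return the cohort with phenotype columns appended.
#' @export
phenotype_cohort <- function(cohort, bp_med_rule = c("include", "exclude")) {
  bp_med_rule <- match.arg(bp_med_rule)
  out <- cohort
  out$bmi <- bmi(cohort$weight_kg, cohort$height_m)
  out$whr <- whr(cohort$wc_cm, cohort$hc_cm)
  out$homa_ir <- homa_ir(cohort$fbg_mmol_l, cohort$insulin_uiu_ml)
  ms <- classify_ms(cohort$sex, cohort$wc_cm, cohort$tg_mmol_l,
                    cohort$hdl_mmol_l, cohort$sbp_mmhg, cohort$dbp_mmhg,
                    cohort$fbg_mmol_l, cohort$med_tg_lowering,
                    cohort$med_hdl_raising, cohort$med_antihypertensive,
                    cohort$med_antidiabetic)
  out$ms_components_n <- ms$n_abnormal
  out$ms_case <- as.integer(ms$ms_case)
  out$t2d_case <- as.integer(classify_t2d(cohort$fbg_mmol_l,
                                          cohort$ogtt_2h_mmol_l,
                                          cohort$med_antidiabetic,
                                          cohort$prior_t2d_diagnosis))
  bp <- abnormal_bp(cohort$sbp_mmhg, cohort$dbp_mmhg,
                    cohort$med_antihypertensive, med_rule = bp_med_rule)
  out$abnormal_sbp <- as.integer(bp$abnormal_sbp)
  out$abnormal_dbp <- as.integer(bp$abnormal_dbp)
  out$vitd_category <- vitd_category(cohort$vitd_nmol_l)
  out$vitd_quintile <- vitd_quintiles(cohort$vitd_nmol_l)
  class(out) <- c("mr_cohort", "data.frame")
  attr(out, "clipping") <- attr(cohort, "clipping")
  out
}
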