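# Orchestration and I/O: cohort CSV round-trips, the Table-4-style MR
# results table, Fig-2-style scatter data, and the end-to-end pipeline
# (simulate -> phenotype -> observational -> MR) with a JSON run manifest.

cohort_required_columns <- function() {
  c("id", "age", "sex", "income", "smoking", "alcohol", "physical_activity",
    "family_history", "vitd_nmol_l", "fbg_mmol_l", "insulin_uiu_ml",
    "tg_mmol_l", "hdl_mmol_l", "sbp_mmhg", "dbp_mmhg", "weight_kg",
    "height_m", "wc_cm", "hc_cm", "ogtt_2h_mmol_l", "med_tg_lowering",
    "med_hdl_raising", "med_antihypertensive", "med_antidiabetic",
    "prior_t2d_diagnosis", "outcome")
}

#' Write / read a cohort as CSV
#'
#' RFC-4180 CSV with a header row and empty fields for missing values.
#' Column names follow the documented dictionary (`snp_<rsid>`,
#' `vitd_nmol_l`, `fbg_mmol_l`, ...). The latent confounder — unobservable
#' in a real study — is excluded from export unless `export_latent = TRUE`
#' (used by oracle tests).
#'
#' Reading validates the dictionary: missing required columns are listed in
#' an explicit error, genotype values outside {0, 1, 2} are rejected naming
#' the row and column, and an empty file is an error rather than an empty
#' cohort.
#'
#' @param cohort a cohort data.frame.
#' @param path file path.
#' @param export_latent include the `latent_confounder` column.
#' @return `read_cohort()` returns the validated cohort (`mr_cohort`).
#' @export
write_cohort <- function(cohort, path, export_latent = FALSE) {
  out <- as.data.frame(cohort)
  if (!export_latent) out$latent_confounder <- NULL
  utils::write.csv(out, path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_cohort
#' @export
read_cohort <- function(path) {
  if (!file.exists(path)) stop_("cohort file not found: ", path)
  if (file.size(path) == 0) stop_("cohort file is empty: ", path)
  dat <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(dat) == 0) stop_("cohort file has a header but no rows: ", path)
  missing_cols <- setdiff(cohort_required_columns(), names(dat))
  if (length(missing_cols))
    stop_("cohort file is missing required columns: ",
          paste(missing_cols, collapse = ", "))
  snp_cols <- grep("^snp_", names(dat), value = TRUE)
  if (!length(snp_cols)) stop_("cohort file has no snp_<rsid> genotype columns")
  for (col in snp_cols) {
    bad <- which(!is.na(dat[[col]]) & !dat[[col]] %in% 0:2)
    if (length(bad))
      stop_("invalid genotype value ", dat[[col]][bad[1]], " in column ",
            col, ", row ", bad[1], " (genotypes must be 0, 1 or 2)")
  }
  num_cols <- c("age", "vitd_nmol_l", "fbg_mmol_l", "insulin_uiu_ml",
                "tg_mmol_l", "hdl_mmol_l", "sbp_mmhg", "dbp_mmhg",
                "weight_kg", "height_m", "wc_cm", "hc_cm")
  for (col in num_cols)
    if (!is.numeric(dat[[col]]))
      stop_("column ", col, " must be numeric")
  class(dat) <- c("mr_cohort", "data.frame")
  dat
}

#' Table-4-style MR results for all GRS panels and outcomes
#'
#' For each GRS panel (synthesis, metabolism, combined) and each outcome
#' (MS, T2D, abnormal SBP, abnormal DBP by default): the GRS-outcome odds
#' ratio per unit higher GRS (`OR_ZY`), and the causal odds ratio per 25
#' nmol/L decrease in 25(OH)D (`OR_IV`) from both the Wald-type and the
#' two-stage estimator, with instrument F statistics.
#'
#' @param cohort a phenotyped cohort.
#' @param panel SNP panel.
#' @param outcomes outcome column names.
#' @param covariates adjustment set (one set for all MR models).
#' @param orientation allele-counting direction for the scores.
#' @param scale nmol/L rescaling of `OR_IV`.
#' @return a data.frame with one row per (panel, outcome, estimator).
#' @export
mr_table <- function(cohort, panel = default_snp_panel(),
                     outcomes = c("ms_case", "t2d_case", "abnormal_sbp",
                                  "abnormal_dbp"),
                     covariates = mr_covariates(),
                     orientation = "decreasing", scale = 25) {
  dat <- as_model_frame(cohort)
  rows <- list()
  for (grs_name in c("synthesis", "metabolism", "combined")) {
    sub <- panel_subset(panel, grs_name)
    for (oc in outcomes) {
      res <- grs_mr(dat, sub, oc, covariates = covariates,
                    orientation = orientation, scale = scale)
      common <- data.frame(
        grs = grs_name, outcome = oc, n = res$n,
        or_zy = res$or_zy$or, or_zy_lo = res$or_zy$ci95[1],
        or_zy_hi = res$or_zy$ci95[2], or_zy_p = res$or_zy$p,
        beta_grs_vd = res$beta_grs_vd$beta,
        f_statistic = res$strength$f_statistic,
        weak_instrument = res$weak_instrument,
        stringsAsFactors = FALSE)
      rows[[length(rows) + 1L]] <- cbind(common, data.frame(
        estimator = "wald_type", or_iv = res$wald_type$or_iv,
        or_iv_lo = res$wald_type$ci95[1], or_iv_hi = res$wald_type$ci95[2],
        or_iv_p = res$wald_type$p))
      rows[[length(rows) + 1L]] <- cbind(common, data.frame(
        estimator = "two_stage", or_iv = res$two_stage$or_iv,
        or_iv_lo = res$two_stage$ci95[1], or_iv_hi = res$two_stage$ci95[2],
        or_iv_p = res$two_stage$p))
    }
  }
  do.call(rbind, rows)
}

#' Fig-2-style scatter data: per-allele 25(OH)D effects vs outcome log-odds
#'
#' One row per SNP and outcome with `beta_zx` (nmol/L per allele) and
#' `ln_or_zy` (log-odds per allele), plus the inverse-variance weighted
#' slopes through the origin for all SNPs and for the synthesis SNPs alone
#' (the IVW pooled causal estimates).
#'
#' @param cohort a phenotyped cohort.
#' @param panel SNP panel.
#' @param outcomes outcome column names.
#' @return a data.frame of scatter-ready points and slopes.
#' @export
fig_scatter_data <- function(cohort, panel = default_snp_panel(),
                             outcomes = c("ms_case", "t2d_case")) {
  rows <- lapply(outcomes, function(oc) {
    res <- snp_mr(cohort, panel, oc)
    df <- res$per_snp[, c("snp", "gene", "class", "beta_zx", "se_zx",
                          "beta_zy", "se_zy", "f_statistic")]
    names(df)[names(df) == "beta_zy"] <- "ln_or_zy"
    names(df)[names(df) == "se_zy"] <- "se_ln_or_zy"
    df$outcome <- oc
    df$ivw_slope_all <- res$ivw$pooled_beta
    df$ivw_slope_synthesis <- if (!is.null(res$ivw_synthesis))
      res$ivw_synthesis$pooled_beta else NA_real_
    df
  })
  do.call(rbind, rows)
}

observational_table <- function(phen, outcomes = c("ms_case", "t2d_case")) {
  rows <- list()
  for (oc in outcomes) {
    covs <- default_covariates(oc)
    for (sc in c(10, 25)) {
      tr <- trend_or(phen, oc, scale = sc, covariates = covs)
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = oc, exposure_coding = tr$exposure_coding, level = "",
        n = tr$n, cases = tr$cases, case_pct = 100 * tr$cases / tr$n,
        or = tr$or, ci_lo = tr$ci95[1], ci_hi = tr$ci95[2], p = tr$p,
        reference = FALSE, stringsAsFactors = FALSE)
    }
    for (coding in c("quintile", "clinical_category")) {
      ct <- categorical_or(phen, oc, coding = coding, covariates = covs)
      lv <- ct$levels
      rows[[length(rows) + 1L]] <- data.frame(
        outcome = oc, exposure_coding = coding, level = lv$level,
        n = lv$n, cases = lv$cases, case_pct = lv$case_pct,
        or = lv$or, ci_lo = lv$ci_lo, ci_hi = lv$ci_hi, p = lv$p,
        reference = lv$reference, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the full analysis pipeline
#'
#' simulate -> phenotype -> descriptives -> observational -> per-SNP MR ->
#' GRS MR, writing every artifact to `out_dir` together with a JSON run
#' manifest (config digest, seed, package version, artifact list, warnings,
#' and the analysis conventions in force).
#'
#' Artifacts: `cohort.csv`, `phenotyped.csv`, `quintile_descriptives.csv`,
#' `observational_or.csv`, `snp_associations.csv`, `fig_scatter.csv`,
#' `mr_results.csv`, plus `manifest.json` and the canonical
#' `config.yaml`.
#'
#' @param config a [simulation_config()] or the path to a YAML config file.
#' @param out_dir output directory (created if needed).
#' @param seed optional integer overriding the config seed.
#' @param export_latent include the latent confounder in `cohort.csv`.
#' @param bp_med_rule medication rule for abnormal SBP/DBP, see
#'   [abnormal_bp()].
#' @param orientation GRS allele-counting direction.
#' @param grs_weights optional per-SNP external GRS weights.
#' @return the manifest, invisibly (a named list).
#' @export
run_pipeline <- function(config, out_dir, seed = NULL,
                         export_latent = FALSE,
                         bp_med_rule = c("include", "exclude"),
                         orientation = c("decreasing", "increasing"),
                         grs_weights = NULL) {
  bp_med_rule <- match.arg(bp_med_rule)
  orientation <- match.arg(orientation)
  if (is.character(config)) config <- read_config(config)
  if (!is.null(seed)) config$seed <- as.integer(seed)
  if (!is.null(grs_weights)) config$snps$grs_weight <- grs_weights
  validate_config(config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- list()
  warnings_log <- character()
  stage <- function(name, fn) {
    tryCatch(fn(), error = function(e)
      stop_("pipeline stage '", name, "' failed: ", conditionMessage(e)))
  }

  config_path <- file.path(out_dir, "config.yaml")
  write_config(config, config_path)
  digest <- unname(tools::md5sum(config_path))

  cohort <- stage("simulate", function() generate_cohort(config))
  clip <- attr(cohort, "clipping")
  if (any(clip > 0))
    warnings_log <- c(warnings_log, paste0(
      "clipped to positivity: ",
      paste(sprintf("%s=%d", names(clip)[clip > 0], clip[clip > 0]),
            collapse = ", ")))
  paths$cohort <- file.path(out_dir, "cohort.csv")
  write_cohort(cohort, paths$cohort, export_latent = export_latent)

  phen <- stage("phenotype", function()
    phenotype_cohort(cohort, bp_med_rule = bp_med_rule))
  paths$phenotyped <- file.path(out_dir, "phenotyped.csv")
  write_cohort(phen, paths$phenotyped, export_latent = export_latent)

  paths$quintile_descriptives <- file.path(out_dir, "quintile_descriptives.csv")
  utils::write.csv(stage("descriptives", function() quintile_descriptives(phen)),
                   paths$quintile_descriptives, row.names = FALSE, na = "")

  paths$observational_or <- file.path(out_dir, "observational_or.csv")
  utils::write.csv(stage("observational", function() observational_table(phen)),
                   paths$observational_or, row.names = FALSE, na = "")

  panel <- config$snps
  snp_tabs <- stage("associate", function() {
    lapply(c("ms_case", "t2d_case"), function(oc) {
      res <- snp_mr(phen, panel, oc)
      df <- res$per_snp
      df$outcome <- oc
      df$wald_beta_iv <- vapply(res$wald_ratios, `[[`, numeric(1), "beta_iv")
      df$wald_se_iv <- vapply(res$wald_ratios, `[[`, numeric(1), "se_iv")
      df$ivw_beta <- res$ivw$pooled_beta
      df$ivw_se <- res$ivw$pooled_se
      df$egger_intercept <- res$egger$intercept
      df$egger_intercept_p <- res$egger$intercept_p
      df
    })
  })
  paths$snp_associations <- file.path(out_dir, "snp_associations.csv")
  utils::write.csv(do.call(rbind, snp_tabs), paths$snp_associations,
                   row.names = FALSE, na = "")

  paths$fig_scatter <- file.path(out_dir, "fig_scatter.csv")
  utils::write.csv(stage("scatter", function() fig_scatter_data(phen, panel)),
                   paths$fig_scatter, row.names = FALSE, na = "")

  mr_res <- stage("mr", function()
    mr_table(phen, panel, orientation = orientation))
  if (any(mr_res$weak_instrument))
    warnings_log <- c(warnings_log, paste0(
      "weak instrument (F <= 10) for GRS panel(s): ",
      paste(unique(mr_res$grs[mr_res$weak_instrument]), collapse = ", ")))
  paths$mr_results <- file.path(out_dir, "mr_results.csv")
  utils::write.csv(mr_res, paths$mr_results, row.names = FALSE, na = "")

  manifest <- list(
    package = "vitdmr",
    version = as.character(utils::packageVersion("vitdmr")),
    seed = config$seed,
    config_digest = digest,
    config_file = config_path,
    artifacts = lapply(paths, identity),
    n_artifacts = length(paths),
    warnings = warnings_log,
    conventions = list(
      grs_orientation = orientation,
      grs_weights = stats::setNames(as.list(panel$grs_weight), panel$rsid),
      bp_medication_rule = bp_med_rule,
      ci_convention = "wald_normal_1.96_se",
      wald_type_ci = "beta_grs_vd treated as fixed",
      egger_reference = "t with n_snps - 2 df",
      quintile_reference = "Q1 = highest concentration"))
  manifest_path <- file.path(out_dir, "manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(manifest)
}
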