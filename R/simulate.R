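# Synthetic cohort generator: the generative counterpart of the study design.
# Genotypes are drawn per SNP under Hardy-Weinberg proportions; 25(OH)D is a
# linear function of allele counts, a latent standard-normal confounder and
# normal noise (truncated at 1 nmol/L); a generic binary outcome follows a
# logistic model with causal, confounder and optional direct (pleiotropic)
# SNP effects; biomarkers and covariates are drawn with 25(OH)D- and
# confounder-dependent means so that phenotype-derived outcomes (MS, T2D,
# abnormal blood pressure) show realistic observational gradients.

#' Hardy-Weinberg genotype probabilities
#'
#' @param p effect-allele frequency, strictly inside (0, 1).
#' @return numeric vector `c(p0, p1, p2)` of probabilities of carrying 0, 1
#'   or 2 effect alleles: `(1-p)^2`, `2p(1-p)`, `p^2`.
#' @examples
#' genotype_probabilities(0.5)  # 0.25 0.50 0.25
#' @export
genotype_probabilities <- function(p) {
  if (!is_scalar_number(p) || p <= 0 || p >= 1)
    stop_("allele frequency must be a finite number strictly inside (0, 1), got ",
          format(p))
  c((1 - p)^2, 2 * p * (1 - p), p^2)
}

#' Default distributional specification for questionnaire covariates
#'
#' Age is normal truncated at 45 years (a middle-aged and elderly cohort);
#' income, smoking and alcohol are categorical with documented level order
#' (first level is the modelling reference); physical activity and family
#' history are Bernoulli flags.
#'
#' @return a named list of covariate distribution parameters.
#' @export
default_covariate_spec <- function() {
  list(
    age_mean = 59, age_sd = 7, age_min = 45,
    p_female = 0.60,
    income_levels  = c("<2000", "2000-3499", "3500-4999", ">=5000"),
    income_probs   = c(0.35, 0.30, 0.20, 0.15),
    smoking_levels = c("never", "former", "current"),
    smoking_probs  = c(0.60, 0.12, 0.28),
    alcohol_levels = c("never", "former", "current"),
    alcohol_probs  = c(0.62, 0.08, 0.30),
    p_physical_activity = 0.35,
    p_family_history    = 0.15
  )
}

#' Default distributional specification for biomarkers
#'
#' Skewed biomarkers (fasting glucose, insulin, triglycerides, HDL-c, 2-h
#' OGTT) are log-normal; anthropometry and blood pressure are normal. Each
#' mean depends linearly on 25(OH)D (centred at `vitd_ref` nmol/L) and on the
#' latent confounder, so that low vitamin D status is accompanied by the
#' adverse biomarker profile seen in population cohorts (higher glucose,
#' insulin, triglycerides and waist circumference; lower HDL-c). Medication
#' flags are independent Bernoulli draws.
#'
#' @return a named list of biomarker distribution parameters.
#' @export
default_biomarker_spec <- function() {
  list(
    vitd_ref = 42,
    fbg     = list(dist = "lognormal", log_mean = log(5.40), vitd_slope = -0.0015,
                   conf_slope = 0.010, log_sd = 0.15),
    insulin = list(dist = "lognormal", log_mean = log(11.5), vitd_slope = -0.0055,
                   conf_slope = 0.060, log_sd = 0.40),
    tg      = list(dist = "lognormal", log_mean = log(0.95), vitd_slope = -0.0070,
                   conf_slope = 0.080, log_sd = 0.45),
    hdl     = list(dist = "lognormal", log_mean = log(1.27), vitd_slope = 0.0030,
                   conf_slope = -0.050, log_sd = 0.25),
    ogtt    = list(dist = "lognormal", log_mean = log(6.50), vitd_slope = -0.0030,
                   conf_slope = 0.060, log_sd = 0.30, p_missing = 0.60),
    sbp     = list(dist = "normal", mean = 124,  vitd_slope = -0.05, conf_slope = 4.0, sd = 15),
    dbp     = list(dist = "normal", mean = 77,    vitd_slope = -0.04, conf_slope = 2.5, sd = 9),
    wc      = list(dist = "normal", mean = 78,    vitd_slope = -0.25, conf_slope = 3.0, sd = 8),
    weight  = list(dist = "normal", mean = 61,   vitd_slope = -0.10, conf_slope = 2.0, sd = 10),
    height  = list(dist = "normal", mean = 1.62, vitd_slope = 0,     conf_slope = 0,   sd = 0.08),
    hip_offset = list(mean = 10, sd = 4),
    med_probs = c(tg_lowering = 0.05, hdl_raising = 0.01, antihypertensive = 0.22,
                  antidiabetic = 0.05, prior_t2d_diagnosis = 0.04)
  )
}

#' Build a simulation configuration
#'
#' The defaults define the reference study conditions: n = 2393 participants,
#' the four-SNP vitamin-D instrument panel with effect-allele frequencies
#' 0.45/0.40/0.30/0.25 and per-allele 25(OH)D effects 2.14/1.10/2.94/0.74
#' nmol/L; a 25(OH)D intercept and noise standard deviation chosen so the
#' marginal distribution has median near 42 nmol/L and empirical quintile
#' cutpoints near 28/37/46/57 nmol/L; a latent confounder that lowers
#' 25(OH)D by 5 nmol/L per SD while raising disease risk (log-odds 0.3 per
#' SD); and a protective causal effect of 25(OH)D on the generic binary
#' outcome of -0.004 log-odds per nmol/L (odds ratio about 1.10 per
#' 25 nmol/L decrease).
#'
#' @param n_individuals cohort size (>= 1).
#' @param snps SNP panel, see [default_snp_panel()].
#' @param allele_freqs per-SNP effect-allele frequencies, in (0, 1).
#' @param vitd_intercept baseline 25(OH)D (nmol/L) at zero alleles and
#'   average confounder.
#' @param per_allele_effects per-SNP 25(OH)D increase (nmol/L) per coded
#'   allele.
#' @param vitd_noise_sd residual 25(OH)D standard deviation (nmol/L).
#' @param confounder_effect_on_vitd nmol/L change in 25(OH)D per confounder
#'   SD (negative by default: the confounder depresses vitamin D).
#' @param causal_log_or_per_nmol causal log-odds per nmol/L of 25(OH)D
#'   (negative = protective).
#' @param confounder_log_or log-odds per confounder SD on the outcome.
#' @param pleiotropy_log_or per-SNP direct log-odds per allele on the
#'   outcome, bypassing 25(OH)D (default all zero: valid instruments).
#' @param outcome_baseline_log_odds intercept of the outcome logit.
#' @param covariate_spec see [default_covariate_spec()].
#' @param biomarker_spec see [default_biomarker_spec()].
#' @param seed integer global seed; all random streams derive from it.
#' @return an object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_individuals = 2393,
                              snps = default_snp_panel(),
                              allele_freqs = c(0.45, 0.40, 0.30, 0.25),
                              vitd_intercept = 37.1,
                              per_allele_effects = c(2.14, 1.10, 2.94, 0.74),
                              vitd_noise_sd = 16,
                              confounder_effect_on_vitd = -5,
                              causal_log_or_per_nmol = -0.004,
                              confounder_log_or = 0.3,
                              pleiotropy_log_or = rep(0, nrow(snps)),
                              outcome_baseline_log_odds = -1.6,
                              covariate_spec = default_covariate_spec(),
                              biomarker_spec = default_biomarker_spec(),
                              seed = 1L) {
  config <- structure(
    list(n_individuals = n_individuals, snps = snps,
         allele_freqs = allele_freqs, vitd_intercept = vitd_intercept,
         per_allele_effects = per_allele_effects, vitd_noise_sd = vitd_noise_sd,
         confounder_effect_on_vitd = confounder_effect_on_vitd,
         causal_log_or_per_nmol = causal_log_or_per_nmol,
         confounder_log_or = confounder_log_or,
         pleiotropy_log_or = pleiotropy_log_or,
         outcome_baseline_log_odds = outcome_baseline_log_odds,
         covariate_spec = covariate_spec, biomarker_spec = biomarker_spec,
         seed = as.integer(seed)),
    class = "simulation_config")
  validate_config(config)
  config
}

#' Validate a simulation configuration
#'
#' @param config a `simulation_config`.
#' @return the config, invisibly, or an error.
#' @export
validate_config <- function(config) {
  n_snp <- nrow(config$snps)
  if (!is_scalar_number(config$n_individuals) || config$n_individuals < 1)
    stop_("n_individuals must be a finite number >= 1")
  for (fld in c("vitd_intercept", "vitd_noise_sd", "confounder_effect_on_vitd",
                "causal_log_or_per_nmol", "confounder_log_or",
                "outcome_baseline_log_odds"))
    if (!is_scalar_number(config[[fld]]))
      stop_(fld, " must be a finite scalar")
  if (config$vitd_noise_sd < 0) stop_("vitd_noise_sd must be non-negative")
  for (fld in c("allele_freqs", "per_allele_effects", "pleiotropy_log_or")) {
    v <- config[[fld]]
    if (length(v) != n_snp || !all(is.finite(v)))
      stop_(fld, " must be a finite vector with one entry per panel SNP")
  }
  if (any(config$allele_freqs <= 0 | config$allele_freqs >= 1))
    stop_("allele frequencies must lie strictly inside (0, 1)")
  if (any(config$allele_freqs <= 0.05 | config$allele_freqs >= 0.95))
    warning("allele frequency outside (0.05, 0.95): rare alleles give weak, ",
            "unstable instruments", call. = FALSE)
  invisible(config)
}

draw_marker <- function(spec, n, vitd_c, U, seed, stream) {
  mu_shift <- spec$vitd_slope * vitd_c + spec$conf_slope * U
  if (spec$dist == "lognormal") {
    with_stream(seed, stream, function()
      stats::rlnorm(n, meanlog = spec$log_mean + mu_shift, sdlog = spec$log_sd))
  } else {
    with_stream(seed, stream, function()
      stats::rnorm(n, mean = spec$mean + mu_shift, sd = spec$sd))
  }
}

#' Generate a synthetic individual-level cohort
#'
#' Draws genotypes independently per SNP from Hardy-Weinberg proportions,
#' builds 25(OH)D as `intercept + sum(effect_j * g_j) + confounder_effect * U
#' + noise` with `U ~ N(0,1)`, draws the generic binary `outcome` from a
#' logistic model `logit = baseline + causal * vitd + confounder_log_or * U +
#' sum(pleiotropy_j * g_j)`, then draws biomarkers, covariates, medication
#' flags and an optionally-missing 2-h OGTT. Values that must be positive are
#' clipped (25(OH)D at 1 nmol/L); clip counts are recorded in the
#' `"clipping"` attribute.
#'
#' The same config and seed always give a byte-identical cohort; each
#' variable uses its own deterministic random substream.
#'
#' @param config a [simulation_config()].
#' @return a `data.frame` of class `mr_cohort`, one row per participant, with
#'   genotype columns `snp_<rsid>`, `vitd_nmol_l`, biomarkers, covariates,
#'   medication flags, `outcome` and `latent_confounder` (simulation-only;
#'   dropped from CSV export unless requested).
#' @export
generate_cohort <- function(config) {
  validate_config(config)
  n <- as.integer(config$n_individuals)
  seed <- config$seed
  rsids <- config$snps$rsid

  g <- matrix(0L, nrow = n, ncol = length(rsids),
              dimnames = list(NULL, paste0("snp_", rsids)))
  for (j in seq_along(rsids)) {
    pr <- genotype_probabilities(config$allele_freqs[j])
    g[, j] <- with_stream(seed, paste0("genotype_", rsids[j]), function()
      sample(0:2, n, replace = TRUE, prob = pr))
  }

  U   <- with_stream(seed, "confounder", function() stats::rnorm(n))
  eps <- with_stream(seed, "vitd_noise", function()
    stats::rnorm(n, 0, config$vitd_noise_sd))
  vitd_raw <- config$vitd_intercept +
    drop(g %*% config$per_allele_effects) +
    config$confounder_effect_on_vitd * U + eps
  vitd <- pmax(vitd_raw, 1)
  clipping <- c(vitd_nmol_l = sum(vitd_raw < 1))

  logit <- config$outcome_baseline_log_odds +
    config$causal_log_or_per_nmol * vitd +
    config$confounder_log_or * U +
    drop(g %*% config$pleiotropy_log_or)
  outcome <- with_stream(seed, "outcome", function()
    as.integer(stats::runif(n) < stats::plogis(logit)))

  cs <- config$covariate_spec
  age <- with_stream(seed, "age", function()
    pmax(cs$age_min, stats::rnorm(n, cs$age_mean, cs$age_sd)))
  sex <- with_stream(seed, "sex", function()
    sample(c("female", "male"), n, replace = TRUE,
           prob = c(cs$p_female, 1 - cs$p_female)))
  income <- with_stream(seed, "income", function()
    sample(cs$income_levels, n, replace = TRUE, prob = cs$income_probs))
  smoking <- with_stream(seed, "smoking", function()
    sample(cs$smoking_levels, n, replace = TRUE, prob = cs$smoking_probs))
  alcohol <- with_stream(seed, "alcohol", function()
    sample(cs$alcohol_levels, n, replace = TRUE, prob = cs$alcohol_probs))
  physical_activity <- with_stream(seed, "physical_activity", function()
    stats::rbinom(n, 1, cs$p_physical_activity))
  family_history <- with_stream(seed, "family_history", function()
    stats::rbinom(n, 1, cs$p_family_history))

  bs <- config$biomarker_spec
  vitd_c <- vitd - bs$vitd_ref
  fbg     <- draw_marker(bs$fbg,     n, vitd_c, U, seed, "fbg")
  insulin <- draw_marker(bs$insulin, n, vitd_c, U, seed, "insulin")
  tg      <- draw_marker(bs$tg,      n, vitd_c, U, seed, "tg")
  hdl     <- draw_marker(bs$hdl,     n, vitd_c, U, seed, "hdl")
  sbp     <- draw_marker(bs$sbp,     n, vitd_c, U, seed, "sbp")
  dbp     <- draw_marker(bs$dbp,     n, vitd_c, U, seed, "dbp")
  wc      <- draw_marker(bs$wc,      n, vitd_c, U, seed, "wc")
  weight  <- draw_marker(bs$weight,  n, vitd_c, U, seed, "weight")
  height  <- draw_marker(bs$height,  n, vitd_c, U, seed, "height")
  hc <- wc + with_stream(seed, "hip_offset", function()
    stats::rnorm(n, bs$hip_offset$mean, bs$hip_offset$sd))

  # positivity clips for normally-drawn anthropometry / blood pressure
  for (nm in c("sbp", "dbp", "wc", "weight", "height", "hc")) {
    v <- get(nm)
    clipping[nm] <- sum(v <= 0)
    assign(nm, pmax(v, 0.01))
  }

  ogtt <- draw_marker(bs$ogtt, n, vitd_c, U, seed, "ogtt")
  miss <- with_stream(seed, "ogtt_missing", function()
    stats::runif(n) < bs$ogtt$p_missing)
  ogtt[miss] <- NA_real_

  mp <- bs$med_probs
  meds <- vapply(names(mp), function(nm)
    with_stream(seed, paste0("med_", nm), function()
      stats::rbinom(n, 1, mp[[nm]])), integer(n))

  cohort <- data.frame(
    id = sprintf("id%06d", seq_len(n)),
    age = age, sex = sex, income = income, smoking = smoking,
    alcohol = alcohol, physical_activity = physical_activity,
    family_history = family_history,
    g,
    vitd_nmol_l = vitd, fbg_mmol_l = fbg, insulin_uiu_ml = insulin,
    tg_mmol_l = tg, hdl_mmol_l = hdl, sbp_mmhg = sbp, dbp_mmhg = dbp,
    weight_kg = weight, height_m = height, wc_cm = wc, hc_cm = hc,
    ogtt_2h_mmol_l = ogtt,
    med_tg_lowering = meds[, "tg_lowering"],
    med_hdl_raising = meds[, "hdl_raising"],
    med_antihypertensive = meds[, "antihypertensive"],
    med_antidiabetic = meds[, "antidiabetic"],
    prior_t2d_diagnosis = meds[, "prior_t2d_diagnosis"],
    outcome = outcome,
    latent_confounder = U,
    stringsAsFactors = FALSE)
  class(cohort) <- c("mr_cohort", "data.frame")
  attr(cohort, "clipping") <- clipping
  cohort
}

#' Write / read a simulation configuration as YAML
#'
#' One canonical example ships with the package at
#' `system.file("extdata", "config_example.yaml", package = "vitdmr")`.
#'
#' @param config a `simulation_config`.
#' @param path file path.
#' @return `read_config()` returns a validated `simulation_config`.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$snps <- lapply(seq_len(nrow(config$snps)), function(i)
    as.list(config$snps[i, , drop = FALSE]))
  x$biomarker_spec$med_probs <- as.list(x$biomarker_spec$med_probs)
  # %.17g keeps doubles exact so a config round-trip reproduces cohorts
  # byte-identically
  yaml::write_yaml(x, path, handlers = list(
    numeric = function(v) {
      if (length(v) == 1 && v == round(v) && abs(v) < 2^31) return(v)
      structure(sprintf("%.17g", v), class = "verbatim")
    }))
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  snps <- do.call(rbind, lapply(x$snps, function(s)
    data.frame(s, stringsAsFactors = FALSE)))
  x$biomarker_spec$med_probs <- unlist(x$biomarker_spec$med_probs)
  simulation_config(
    n_individuals = x$n_individuals, snps = snps,
    allele_freqs = unlist(x$allele_freqs),
    vitd_intercept = x$vitd_intercept,
    per_allele_effects = unlist(x$per_allele_effects),
    vitd_noise_sd = x$vitd_noise_sd,
    confounder_effect_on_vitd = x$confounder_effect_on_vitd,
    causal_log_or_per_nmol = x$causal_log_or_per_nmol,
    confounder_log_or = x$confounder_log_or,
    pleiotropy_log_or = unlist(x$pleiotropy_log_or),
    outcome_baseline_log_odds = x$outcome_baseline_log_odds,
    covariate_spec = x$covariate_spec,
    biomarker_spec = x$biomarker_spec,
    seed = x$seed)
}
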