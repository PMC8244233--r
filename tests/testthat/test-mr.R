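make_est <- function(beta, se, snp = NULL) {
  structure(list(beta = beta, se = se, snp = snp),
            class = "association_estimate")
}

test_that("the Cragg-Donald F statistic follows its closed form", {
  expect_equal(f_statistic(0, 100)$f_statistic, 0)
  expect_equal(f_statistic(0.5, 4)$f_statistic, 2.0)
  f <- f_statistic(0.01, 1002)
  expect_equal(f$f_statistic, 0.01 * 1000 / 0.99)
  expect_true(f$usable_instrument)
  expect_false(f_statistic(0.001, 100)$usable_instrument)
  expect_error(f_statistic(1, 100), "infinite")
  expect_error(f_statistic(0.5, 2), "exceed")
})

test_that("Wald ratios divide coefficients and propagate delta-method error", {
  r <- wald_ratio(make_est(0.1, 0.05), make_est(2.0, 0.2))
  expect_equal(r$beta_iv, 0.05)
  expect_equal(r$se_iv, sqrt(0.05^2 / 2^2 + 0.1^2 * 0.2^2 / 2^4),
               tolerance = 1e-8)
  expect_equal(r$variance_weight, 1 / r$se_iv^2)
  r0 <- wald_ratio(make_est(0, 0.05), make_est(2.94, 0.2))
  expect_equal(r0$beta_iv, 0)
  expect_equal(r0$se_iv, 0.05 / 2.94)
  expect_error(wald_ratio(make_est(0.1, 0.05), make_est(0, 0.2)), "undefined")
  expect_error(wald_ratio(make_est(0.1, 0.05, "rs1"),
                          make_est(2, 0.2, "rs2")), "mismatched")
})

test_that("IVW pooling is the fixed-effect weighted mean", {
  one <- wald_ratio(make_est(0.1, 0.05), make_est(2.0, 0.2))
  pooled1 <- ivw_pool(list(one))
  expect_equal(pooled1$pooled_beta, one$beta_iv)
  expect_equal(pooled1$pooled_se, one$se_iv)
  mk <- function(b, v) structure(list(beta_iv = b, se_iv = sqrt(v)),
                                 class = "wald_ratio_result")
  eq <- ivw_pool(list(mk(0.1, 0.01), mk(0.3, 0.01)))
  expect_equal(eq$pooled_beta, 0.2)
  expect_equal(eq$pooled_se, sqrt(1 / 200), tolerance = 1e-8)
  uneq <- ivw_pool(list(mk(0.1, 0.01), mk(0.3, 0.04)))
  expect_equal(uneq$pooled_beta, (0.1 / 0.01 + 0.3 / 0.04) / (100 + 25))
  # k identical ratios: same estimate, se shrunk by 1/sqrt(k)
  k <- 5
  same <- ivw_pool(replicate(k, mk(0.12, 0.02), simplify = FALSE))
  expect_equal(same$pooled_beta, 0.12)
  expect_equal(same$pooled_se, sqrt(0.02) / sqrt(k))
  expect_error(ivw_pool(list()), "at least one")
  expect_error(ivw_pool(list(mk(0.1, Inf))), "finite")
})

test_that("IVW pooling matches independent fixed-effect meta-analysis code paths", {
  set.seed(55)
  for (i in 1:20) {
    k <- sample(2:6, 1)
    b <- rnorm(k); v <- runif(k, 0.005, 0.1)
    ratios <- lapply(seq_len(k), function(j)
      structure(list(beta_iv = b[j], se_iv = sqrt(v[j])),
                class = "wald_ratio_result"))
    res <- ivw_pool(ratios)
    # brute force
    expect_equal(res$pooled_beta, sum(b / v) / sum(1 / v), tolerance = 1e-12)
    expect_equal(res$pooled_se, 1 / sqrt(sum(1 / v)), tolerance = 1e-12)
  }
  # external cross-check: metafor fixed-effect model
  b <- c(0.05, -0.02, 0.11, 0.03); v <- c(0.01, 0.02, 0.015, 0.03)
  ratios <- lapply(1:4, function(j)
    structure(list(beta_iv = b[j], se_iv = sqrt(v[j])),
              class = "wald_ratio_result"))
  res <- ivw_pool(ratios)
  rma <- metafor::rma(yi = b, vi = v, method = "FE")
  expect_equal(res$pooled_beta, as.numeric(rma$beta), tolerance = 1e-10)
  expect_equal(res$pooled_se, as.numeric(rma$se), tolerance = 1e-10)
})

test_that("MR-Egger regression recovers exact lines and flags pleiotropy", {
  x <- c(0.8, 1.5, 2.2, 3.0)
  exact <- data.frame(beta_zx = x, beta_zy = 0.02 + 0.05 * x,
                      se_zy = rep(0.1, 4))
  e <- egger_regression(exact)
  expect_true(e$defined)
  expect_equal(e$intercept, 0.02, tolerance = 1e-12)
  expect_equal(e$slope, 0.05, tolerance = 1e-12)
  origin <- data.frame(beta_zx = x, beta_zy = 0.05 * x, se_zy = rep(0.1, 4))
  expect_equal(egger_regression(origin)$intercept, 0, tolerance = 1e-12)
  short <- egger_regression(exact[1:2, ])
  expect_false(short$defined)
  neg <- exact; neg$beta_zx[1] <- -0.8
  expect_error(egger_regression(neg), "positive after orientation")
})

test_that("MR-Egger matches weighted least squares from an independent fitter", {
  set.seed(66)
  d <- data.frame(beta_zx = runif(6, 0.5, 3), beta_zy = rnorm(6, 0.1, 0.05),
                  se_zy = runif(6, 0.02, 0.2))
  e <- egger_regression(d)
  ref <- lm(beta_zy ~ beta_zx, data = d, weights = 1 / d$se_zy^2)
  sm <- summary(ref)
  expect_equal(e$intercept, unname(coef(ref)[1]), tolerance = 1e-10)
  expect_equal(e$slope, unname(coef(ref)[2]), tolerance = 1e-10)
  expect_equal(e$intercept_se, sm$coefficients[1, 2], tolerance = 1e-10)
  expect_equal(e$intercept_p, sm$coefficients[1, 4], tolerance = 1e-10)
})

test_that("the Wald-type GRS estimator rescales to per-25 nmol/L odds ratios", {
  expect_equal(grs_iv_wald(1.0, 12.5)$or_iv, 1.0)
  expect_equal(grs_iv_wald(0.95, 12.5)$or_iv, exp(-25 * log(0.95) / 12.5),
               tolerance = 1e-12)
  expect_equal(grs_iv_wald(0.95, 12.5)$or_iv, 1.1080, tolerance = 1e-4)
  expect_equal(grs_iv_wald(1.07, -17.756)$or_iv,
               exp(25 * log(1.07) / 17.756), tolerance = 1e-12)
  expect_equal(grs_iv_wald(1.07, -17.756)$or_iv, 1.1000, tolerance = 1e-3)
  # reciprocal symmetry between decrease and increase reporting
  dec <- grs_iv_wald(1.18, 9.7, direction = "decrease")
  inc <- grs_iv_wald(1.18, 9.7, direction = "increase")
  expect_equal(dec$or_iv * inc$or_iv, 1, tolerance = 1e-12)
  # CI transported through the same monotone map, properly ordered
  res <- grs_iv_wald(1.07, -17.756, or_zy_ci = c(1.01, 1.42))
  expect_true(res$ci95[1] < res$ci95[2])
  expect_equal(res$ci95,
               sort(exp(-25 * log(c(1.01, 1.42)) / -17.756)),
               tolerance = 1e-12)
  expect_error(grs_iv_wald(0, 12.5), "positive")
  expect_error(grs_iv_wald(1.1, 0), "non-zero")
})

test_that("two-stage and Wald-type estimators coincide without covariates", {
  co <- generate_cohort(test_config(n = 20000, seed = 41L))
  panel <- default_snp_panel()
  res <- grs_mr(co, panel, "outcome")
  # identical GRS -> identical stage-2 coefficient up to numerics
  expect_equal(res$wald_type$or_iv, res$two_stage$or_iv, tolerance = 1e-8)
  expect_equal(res$two_stage$log_or_per_nmol,
               log(res$or_zy$or) / res$beta_grs_vd$beta, tolerance = 1e-8)
})

test_that("the two-stage estimator covers the null and flags weak instruments", {
  co <- generate_cohort(test_config(n = 20000, seed = 1L,
                                    causal_log_or_per_nmol = 0))
  grs <- compute_grs(co, default_snp_panel())
  ts <- two_stage_estimate(co, grs, "outcome")
  expect_true(ts$ci95[1] < 1 && ts$ci95[2] > 1)
  expect_false(ts$weak_instrument)
  # shrink the genetic effects until F <= 10
  weak_cfg <- test_config(n = 2000, seed = 2L,
                          per_allele_effects = c(0.2, 0.1, 0.3, 0.1))
  co_w <- generate_cohort(weak_cfg)
  grs_w <- compute_grs(co_w, default_snp_panel())
  expect_warning(ts_w <- two_stage_estimate(co_w, grs_w, "outcome"),
                 "weak instrument")
  expect_true(ts_w$weak_instrument)
  expect_lte(ts_w$strength$f_statistic, 10)
})

test_that("per-SNP MR assembles associations, ratios, IVW and Egger", {
  co <- generate_cohort(test_config(n = 4000, seed = 51L))
  res <- snp_mr(co, default_snp_panel(), "outcome")
  expect_equal(nrow(res$per_snp), 4)
  expect_true(all(res$per_snp$beta_zx > 0))  # oriented vitamin-D-increasing
  expect_length(res$wald_ratios, 4)
  expect_equal(res$ivw$n_snps, 4)
  expect_equal(res$egger$n_snps, 4)
  expect_equal(res$egger$df, 2)
  # pooled estimate lies within the range of the per-SNP ratios
  b <- vapply(res$wald_ratios, `[[`, numeric(1), "beta_iv")
  expect_gte(res$ivw$pooled_beta, min(b))
  expect_lte(res$ivw$pooled_beta, max(b))
  expect_lte(res$ivw$pooled_se,
             min(vapply(res$wald_ratios, `[[`, numeric(1), "se_iv")))
})
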