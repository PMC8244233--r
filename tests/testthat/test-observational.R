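test_that("per-10 and per-25 trend ORs come from the same coefficient", {
  co <- phenotype_cohort(generate_cohort(test_config(n = 3000, seed = 61L)))
  or10 <- trend_or(co, "ms_case", scale = 10)
  or25 <- trend_or(co, "ms_case", scale = 25)
  expect_equal(or25$or, or10$or^2.5, tolerance = 1e-12)
  expect_equal(or25$beta_per_nmol, or10$beta_per_nmol)
  expect_equal(or25$exposure_coding, "per25_decrease")
})

test_that("trend OR recovers a pure direct effect with confounding off", {
  # causal and confounder paths off; direct vitamin D log-OR -0.004/nmol
  cfg <- test_config(n = 100000, seed = 62L,
                     causal_log_or_per_nmol = -0.004,
                     confounder_effect_on_vitd = 0, confounder_log_or = 0)
  ph <- phenotype_cohort(generate_cohort(cfg))
  res <- trend_or(ph, "outcome", scale = 25, covariates = character())
  expect_equal(log(res$or), 0.1, tolerance = 3 * 25 * 0.004)
  expect_true(res$ci95[1] < exp(0.1) && exp(0.1) < res$ci95[2])
})

test_that("trend OR covers the null when the exposure is unrelated to outcome", {
  cfg <- test_config(n = 20000, seed = 63L, causal_log_or_per_nmol = 0,
                     confounder_effect_on_vitd = 0, confounder_log_or = 0)
  ph <- phenotype_cohort(generate_cohort(cfg))
  res <- trend_or(ph, "outcome", scale = 25, covariates = character())
  expect_true(res$ci95[1] < 1 && res$ci95[2] > 1)
})

test_that("categorical ORs reproduce the 2x2 cross-product oracle", {
  d <- expand_2x2(20, 80, 10, 90)
  d$grp <- factor(ifelse(d$x == 1, "exposed", "reference"),
                  levels = c("reference", "exposed"))
  res <- categorical_or(d, "y", coding = "grp", covariates = character())
  lv <- res$levels
  expect_equal(lv$or[lv$level == "reference"], 1)
  expect_true(lv$reference[lv$level == "reference"])
  expect_true(is.na(lv$ci_lo[lv$level == "reference"]))
  expect_equal(lv$or[lv$level == "exposed"], 2.25, tolerance = 1e-6)
  expect_equal(lv$cases, c(10, 20))
  expect_equal(lv$case_pct, c(10, 20))
})

test_that("quintile ORs rise monotonically as 25(OH)D falls under a protective effect", {
  ph <- phenotype_cohort(generate_cohort(test_config(n = 100000, seed = 64L)))
  res <- categorical_or(ph, "ms_case", coding = "quintile",
                        covariates = character())
  or <- res$levels$or
  expect_equal(res$levels$level, paste0("Q", 1:5))
  expect_equal(or[1], 1)
  expect_true(all(diff(or) > -0.02))  # non-decreasing up to estimation noise
  expect_gt(or[5], or[1])
  # case counts across quintiles account for every case
  expect_equal(sum(res$levels$cases), sum(ph$ms_case))
})

test_that("empty exposure levels are reported inestimable, not dropped silently", {
  set.seed(65)
  d <- data.frame(y = rbinom(300, 1, 0.3),
                  grp = factor(sample(c("a", "b"), 300, TRUE),
                               levels = c("a", "b", "c")))
  res <- categorical_or(d, "y", coding = "grp", covariates = character())
  lv <- res$levels
  expect_false(lv$estimable[lv$level == "c"])
  expect_true(is.na(lv$or[lv$level == "c"]))
  expect_true(all(lv$estimable[lv$level %in% c("a", "b")]))
})

test_that("quintile descriptives use the appropriate tests and are deterministic", {
  ph <- phenotype_cohort(generate_cohort(test_config(n = 2393, seed = 66L)))
  t1 <- quintile_descriptives(ph)
  t2 <- quintile_descriptives(ph)
  expect_identical(t1, t2)
  expect_true(all(c("variable", "Q1", "Q5", "p_value") %in% names(t1)))
  expect_equal(t1$test[t1$variable == "age"], "anova")
  expect_equal(t1$test[t1$variable == "fbg_mmol_l"], "kruskal_wallis")
  expect_equal(t1$test[t1$variable == "sex"], "chi_square")
  # the generator builds in a waist-circumference gradient across quintiles
  expect_lt(t1$p_value[t1$variable == "wc_cm"], 0.05)
})

test_that("identical groups give null comparison statistics", {
  block <- data.frame(
    age = rep(c(50, 60, 70), 4), bmi = rep(c(22, 25, 28), 4),
    wc_cm = rep(c(70, 80, 90), 4), sbp_mmhg = rep(c(110, 120, 130), 4),
    dbp_mmhg = rep(c(70, 80, 90), 4), fbg_mmol_l = rep(c(4.5, 5.5, 6.5), 4),
    insulin_uiu_ml = rep(c(8, 10, 12), 4), homa_ir = rep(c(1.5, 2, 2.5), 4),
    tg_mmol_l = rep(c(1, 1.5, 2), 4), hdl_mmol_l = rep(c(1, 1.2, 1.4), 4),
    sex = rep(c("male", "female", "female"), 4),
    ms_case = rep(c(0, 1, 0), 4), t2d_case = rep(c(0, 0, 1), 4),
    family_history = rep(c(0, 1, 0), 4))
  five <- do.call(rbind, replicate(5, block, simplify = FALSE))
  five$vitd_quintile <- factor(rep(paste0("Q", 1:5), each = nrow(block)),
                               levels = paste0("Q", 1:5))
  tab <- quintile_descriptives(five)
  expect_equal(tab$p_value[tab$variable == "age"], 1)        # ANOVA F = 0
  expect_equal(tab$p_value[tab$variable == "sex"], 1)        # chi-square = 0
  expect_gt(tab$p_value[tab$variable == "fbg_mmol_l"], 0.99) # Kruskal-Wallis
})

test_that("a built-in glucose gradient is detectable by Kruskal-Wallis at study scale", {
  # stated effect size for the power check: FBG log-slope -0.004 per nmol/L
  bs <- default_biomarker_spec()
  bs$fbg$vitd_slope <- -0.004
  hits <- vapply(1:100, function(r) {
    ph <- phenotype_cohort(generate_cohort(
      test_config(n = 2393, seed = 7000L + r, biomarker_spec = bs)))
    stats::kruskal.test(ph$fbg_mmol_l, ph$vitd_quintile)$p.value < 0.05
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})
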