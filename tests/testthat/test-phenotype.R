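test_that("repeated-measurement averaging follows the field protocol", {
  expect_equal(average_repeated(c(80.0, 80.5), tolerance = 1), 80.25)
  # third reading taken: average of the two closest measurements
  expect_equal(average_repeated(c(80.0, 82.0, 80.6), tolerance = 1), 80.3)
  expect_equal(average_repeated(c(120, 132, 124), tolerance = 10), 122.0)
  # tie: third reading equidistant from both originals pairs with the earlier
  expect_equal(average_repeated(c(80, 82, 81), tolerance = 1), 80.5)
  expect_error(average_repeated(c(80, 82), tolerance = 1), "third reading")
  expect_error(average_repeated(80, tolerance = 1), "two readings")
  expect_error(average_repeated(c(1, 2, 3, 4), tolerance = 10), "at most three")
})

test_that("HOMA-IR, BMI and WHR follow their defining formulas", {
  expect_equal(homa_ir(4.5, 10), 2.0)
  expect_equal(homa_ir(22.5, 1), 1.0)
  expect_equal(homa_ir(5.6, 12), 67.2 / 22.5)
  expect_error(homa_ir(0, 10), "positive")
  expect_error(homa_ir(5, -1), "positive")
  expect_equal(bmi(81, 1.8), 25.0)
  expect_equal(bmi(60, 1.5), 60 / 2.25)
  expect_error(bmi(70, 0), "positive")
  expect_equal(whr(90, 100), 0.9)
  expect_error(whr(90, 0), "positive")
  expect_equal(insulin_pmol_to_uiu(insulin_uiu_to_pmol(12.3)), 12.3)
  expect_equal(insulin_uiu_to_pmol(1), 6.945)
})

test_that("metabolic syndrome classification applies the printed cutoffs", {
  # three abnormalities -> case
  r1 <- classify_ms("male", wc = 90, tg = 1.8, hdl = 0.9, sbp = 120,
                    dbp = 70, fbg = 5.0)
  expect_equal(r1$n_abnormal, 3L)
  expect_true(r1$ms_case)
  # all normal
  r2 <- classify_ms("female", wc = 70, tg = 1.0, hdl = 1.5, sbp = 110,
                    dbp = 70, fbg = 4.8)
  expect_equal(r2$n_abnormal, 0L)
  expect_false(r2$ms_case)
  # boundary semantics: WC >= 85, TG >= 1.7 abnormal; HDL 1.0 is NOT < 1.0;
  # BP 129/84 and FBG 5.5 below their cutoffs
  r3 <- classify_ms("male", wc = 85, tg = 1.7, hdl = 1.0, sbp = 129,
                    dbp = 84, fbg = 5.5)
  expect_true(r3$central_obesity)
  expect_true(r3$high_tg)
  expect_false(r3$low_hdl)
  expect_false(r3$high_bp)
  expect_false(r3$high_glucose)
  expect_false(r3$ms_case)
  # medication implies the component abnormal despite normal values
  r4 <- classify_ms("female", wc = 70, tg = 1.0, hdl = 1.5, sbp = 110,
                    dbp = 70, fbg = 4.8, med_tg = TRUE, med_bp = TRUE,
                    med_dm = TRUE)
  expect_equal(r4$n_abnormal, 3L)
  expect_true(r4$ms_case)
})

test_that("records missing a required field are flagged unclassifiable", {
  r <- classify_ms(c("male", "male"), wc = c(NA, 90), tg = 1.8, hdl = 0.9,
                   sbp = 120, dbp = 70, fbg = 5.0)
  expect_true(r$unclassifiable[1])
  expect_true(is.na(r$ms_case[1]))
  expect_false(r$unclassifiable[2])
  expect_true(r$ms_case[2])
})

test_that("type 2 diabetes classification honors its inclusive thresholds", {
  expect_true(classify_t2d(7.0))
  expect_true(classify_t2d(6.0, ogtt = 11.1))
  expect_false(classify_t2d(5.0))
  expect_true(classify_t2d(5.0, med_dm = TRUE))
  expect_true(classify_t2d(5.0, prior_diagnosis = TRUE))
  expect_true(is.na(classify_t2d(NA)))
  expect_true(classify_t2d(NA, ogtt = 12))  # case by OGTT despite missing FBG
  # monotone in FBG: raising glucose never declassifies a case
  set.seed(77)
  fbg <- runif(200, 3, 9)
  ogtt <- ifelse(runif(200) < 0.5, NA, runif(200, 5, 13))
  med <- runif(200) < 0.1
  before <- classify_t2d(fbg, ogtt, med)
  after <- classify_t2d(fbg + runif(200, 0, 3), ogtt, med)
  expect_false(any(before & !after, na.rm = TRUE))
})

test_that("vitamin D categories partition the positive axis at 25/50/75", {
  expect_equal(as.character(vitd_category(24.9)), "severe_deficiency")
  expect_equal(as.character(vitd_category(25.0)), "deficiency")
  expect_equal(as.character(vitd_category(49.999)), "deficiency")
  expect_equal(as.character(vitd_category(50.0)), "insufficiency")
  expect_equal(as.character(vitd_category(75.0)), "sufficiency")
  expect_error(vitd_category(0), "positive")
  expect_error(vitd_category(-5), "positive")
  # partition: every positive value gets exactly one category
  set.seed(4)
  x <- exp(runif(500, log(0.5), log(200)))
  expect_false(anyNA(vitd_category(x)))
  expect_equal(levels(vitd_category(x))[1], "sufficiency")
})

test_that("quintiles label Q1 as highest concentration and break ties downward", {
  vitd <- c(10, 20, 30, 40, 50, 60, 70, 80, 90, 100)
  q <- vitd_quintiles(vitd)
  expect_equal(as.character(q[vitd == 100]), "Q1")
  expect_equal(as.character(q[vitd == 10]), "Q5")
  expect_equal(levels(q), paste0("Q", 1:5))
  # a value equal to a quintile boundary joins the lower-concentration side
  vitd2 <- 1:101  # the 80th percentile (81) is attained exactly
  q2 <- vitd_quintiles(vitd2)
  b <- quantile(vitd2, 0.8, names = FALSE)
  expect_equal(b, 81)
  expect_equal(as.character(q2[vitd2 == 81]), "Q2")
})

test_that("abnormal blood pressure outcomes support both medication rules", {
  r <- abnormal_bp(130, 80)
  expect_true(r$abnormal_sbp); expect_false(r$abnormal_dbp)
  r <- abnormal_bp(120, 85)
  expect_false(r$abnormal_sbp); expect_true(r$abnormal_dbp)
  r <- abnormal_bp(110, 70, med_bp = TRUE)
  expect_true(r$abnormal_sbp); expect_true(r$abnormal_dbp)
  r <- abnormal_bp(110, 70, med_bp = TRUE, med_rule = "exclude")
  expect_false(r$abnormal_sbp); expect_false(r$abnormal_dbp)
})

test_that("phenotype_cohort derives every analysis column", {
  co <- generate_cohort(test_config(n = 800, seed = 12L))
  ph <- phenotype_cohort(co)
  for (col in c("bmi", "whr", "homa_ir", "ms_case", "t2d_case",
                "abnormal_sbp", "abnormal_dbp", "vitd_category",
                "vitd_quintile", "ms_components_n"))
    expect_true(col %in% names(ph))
  expect_equal(ph$homa_ir, co$fbg_mmol_l * co$insulin_uiu_ml / 22.5)
  expect_true(all(ph$ms_case %in% 0:1))
  expect_equal(as.vector(table(ph$vitd_quintile)), rep(160L, 5))
})
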