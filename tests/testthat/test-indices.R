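test_that("fatty liver index matches its published logistic formula", {
  # independent single-expression oracle
  fli_oracle <- function(tg, bmi, ggt, wc) {
    100 * stats::plogis(0.953 * log(tg) + 0.139 * bmi + 0.718 * log(ggt) +
                          0.053 * wc - 15.745)
  }
  expect_equal(fatty_liver_index(98, 32.1, 30, 97),
               fli_oracle(98, 32.1, 30, 97), tolerance = 1e-12)

  set.seed(1)
  tg <- runif(100, 40, 300); bmi <- runif(100, 18, 55)
  ggt <- runif(100, 5, 300); wc <- runif(100, 60, 140)
  expect_equal(fatty_liver_index(tg, bmi, ggt, wc),
               fli_oracle(tg, bmi, ggt, wc), tolerance = 1e-12)

  # low-risk profile is below the rule-out threshold
  low <- fatty_liver_index(43, 18, 5, 60)
  expect_lt(low, 30)
  expect_equal(fli_class(low), "fatty liver excluded")
  expect_equal(fli_class(75), "fatty liver indicated")
  expect_equal(fli_class(45), "indeterminate")

  expect_error(fatty_liver_index(-1, 30, 30, 90),
               class = "autocmap_invalid_argument")
})

test_that("fatty liver index is bounded and monotone", {
  set.seed(2)
  grid <- tibble::tibble(tg = runif(1e4, 40, 300), bmi = runif(1e4, 18, 55),
                         ggt = runif(1e4, 5, 300), wc = runif(1e4, 60, 140))
  f <- fatty_liver_index(grid$tg, grid$bmi, grid$ggt, grid$wc)
  expect_true(all(f >= 0 & f <= 100))
  # raising any single argument raises the index
  expect_true(all(fatty_liver_index(grid$tg * 1.1, grid$bmi, grid$ggt, grid$wc) > f))
  expect_true(all(fatty_liver_index(grid$tg, grid$bmi + 1, grid$ggt, grid$wc) > f))
  expect_true(all(fatty_liver_index(grid$tg, grid$bmi, grid$ggt * 1.1, grid$wc) > f))
  expect_true(all(fatty_liver_index(grid$tg, grid$bmi, grid$ggt, grid$wc + 1) > f))
})

test_that("visceral adiposity index matches the sex-specific formula", {
  # male construction with every ratio term equal to 1
  bmi <- 30
  expect_equal(visceral_adiposity_index("male", wc = 39.68 + 1.88 * bmi,
                                        bmi = bmi, tg = 1.03, hdl = 1.31),
               1.0, tolerance = 1e-12)

  vai_oracle_f <- function(wc, bmi, tg, hdl) {
    (wc / (36.58 + 1.89 * bmi)) * (tg / 0.81) * (1.52 / hdl)
  }
  expect_equal(visceral_adiposity_index("female", 99, 32.7, 1.24, 1.35),
               vai_oracle_f(99, 32.7, 1.24, 1.35), tolerance = 1e-12)

  vai_oracle_m <- function(wc, bmi, tg, hdl) {
    (wc / (39.68 + 1.88 * bmi)) * (tg / 1.03) * (1.31 / hdl)
  }
  set.seed(3)
  wc <- runif(50, 70, 140); bmi <- runif(50, 20, 50)
  tg <- runif(50, 0.5, 5); hdl <- runif(50, 0.7, 2.5)
  expect_equal(visceral_adiposity_index("male", wc, bmi, tg, hdl),
               vai_oracle_m(wc, bmi, tg, hdl), tolerance = 1e-12)
  expect_equal(visceral_adiposity_index("female", wc, bmi, tg, hdl),
               vai_oracle_f(wc, bmi, tg, hdl), tolerance = 1e-12)

  # linear in TG
  v1 <- visceral_adiposity_index("female", 99, 32.7, 1.24, 1.35)
  v2 <- visceral_adiposity_index("female", 99, 32.7, 2.48, 1.35)
  expect_equal(v2 / v1, 2, tolerance = 1e-12)

  # mg/dL passed where mmol/L expected
  expect_error(visceral_adiposity_index("male", 99, 32.7, 109, 1.35),
               class = "autocmap_unit_error")
})

test_that("VAI age cutoffs follow the printed bands", {
  expect_equal(vai_reference_cutoff(35), 2.23)
  expect_equal(vai_reference_cutoff(51), 1.92)
  expect_equal(vai_reference_cutoff(52), 1.93)
  expect_equal(vai_reference_cutoff(66), 2.0)
  expect_equal(vai_reference_cutoff(c(30, 41, 42, 65, 80)),
               c(2.23, 2.23, 1.92, 1.93, 2.0))
  expect_error(vai_reference_cutoff(29), class = "autocmap_not_defined")
})

test_that("Framingham points reproduce hand-summed table profiles", {
  # youngest band, all protective: -9 (age) + 0 + 0 - 1 (HDL >= 60) + 0 = -10
  r <- framingham_risk(25, "male", 150, 65, 110, FALSE, FALSE, FALSE)
  expect_equal(r$points, -10L)

  # man 55y, chol 220, smoker, HDL 45, SBP 135 untreated:
  # 8 + 3 + 3 + 1 + 1 = 16 points -> 25%
  r <- framingham_risk(55, "male", 220, 45, 135, FALSE, TRUE, FALSE)
  expect_equal(r$points, 16L)
  expect_equal(r$risk_percent, 25)

  # woman 62y, chol 250, non-smoker, HDL 55, SBP 145 treated:
  # 10 + 3 + 0 + 0 + 5 = 18 points -> 6%
  r <- framingham_risk(62, "female", 250, 55, 145, TRUE, FALSE, FALSE)
  expect_equal(r$points, 18L)
  expect_equal(r$risk_percent, 6)

  # raising the SBP band never lowers points
  for (sex in c("male", "female")) {
    pts <- framingham_risk(rep(50, 5), sex, 200, 45, c(110, 125, 135, 150, 165),
                           FALSE, FALSE, FALSE)$points
    expect_true(all(diff(pts) >= 0))
  }
  expect_error(framingham_risk(85, "male", 200, 50, 120, FALSE, FALSE, FALSE),
               class = "autocmap_invalid_argument")
})

test_that("MetS requires at least three ATP III components", {
  # all five normal
  expect_false(mets_atpiii(80, "male", 100, 55, 118, 75, FALSE, 90))
  # exactly three abnormal (WC, TG, glucose for a woman)
  expect_true(mets_atpiii(95, "female", 160, 55, 120, 80, FALSE, 105))
  # exactly two abnormal (TG, glucose)
  expect_false(mets_atpiii(80, "female", 160, 55, 120, 80, FALSE, 105))
  # treated blood pressure counts as the BP component
  expect_true(mets_atpiii(95, "female", 160, 55, 118, 75, TRUE, 90))

  # named-argument order does not matter
  expect_identical(
    mets_atpiii(95, "female", 160, 55, 120, 80, FALSE, 105),
    mets_atpiii(glucose = 105, sex = "female", wc = 95, hdl = 55, tg = 160,
                bp_treated = FALSE, dbp = 80, sbp = 120))

  expect_error(mets_atpiii(95, "female", NA, 55, 120, 80, FALSE, 105),
               class = "autocmap_missing_component")
})

test_that("obesity flag is strict at BMI 30", {
  expect_false(obesity_flag(30.0))
  expect_true(obesity_flag(30.1))
  expect_true(obesity_flag(54.7))
  expect_error(obesity_flag(0), class = "autocmap_invalid_argument")
})

test_that("toxicity index is a weighted average with the stated invariances", {
  tox <- toxic_elements()
  w <- default_toxicity_weights()
  zero <- setNames(rep(0, 13), tox)
  expect_equal(toxicity_index(zero, w), 0)

  # single nonzero element: c * w / sum(w)
  one <- zero; one["Hg"] <- 2.5
  expect_equal(toxicity_index(one, w), 2.5 * w[["Hg"]] / sum(w),
               tolerance = 1e-12)

  # equal weights on the published medians -> arithmetic mean of the medians
  schema <- element_schema()
  med <- setNames(schema$median[schema$class == "toxic"],
                  schema$symbol[schema$class == "toxic"])
  expect_equal(toxicity_index(med, setNames(rep(1, 13), tox)), mean(med),
               tolerance = 1e-12)

  set.seed(4)
  conc <- setNames(runif(13, 0, 5), tox)
  ti <- toxicity_index(conc, w)
  # independent single-expression oracle
  expect_equal(ti, sum(w[tox] * conc[tox]) / sum(w), tolerance = 1e-12)
  # homogeneity and weight-scale invariance
  expect_equal(toxicity_index(conc * 3, w), 3 * ti, tolerance = 1e-12)
  expect_equal(toxicity_index(conc, w * 17), ti, tolerance = 1e-12)

  expect_error(toxicity_index(conc[-1], w), class = "autocmap_missing_component")
  bad <- conc; bad["Pb"] <- -1
  expect_error(toxicity_index(bad, w), class = "autocmap_invalid_argument")
})

test_that("reference flagging matches the published exceedances", {
  fl <- flag_out_of_reference(c(Ba = 1.29, Zn = 176.6, Sr = 9.70, Co = 0.05,
                                Mo = 0.03))
  expect_equal(fl$status[fl$symbol == "Ba"], "high")
  expect_equal(fl$status[fl$symbol == "Zn"], "normal")
  expect_equal(fl$status[fl$symbol == "Sr"], "high")
  expect_equal(fl$status[fl$symbol == "Co"], "high")
  expect_equal(fl$status[fl$symbol == "Mo"], "low")

  # toxic metals have no lower limit: zero is still "normal"
  fl0 <- flag_out_of_reference(setNames(rep(0, 13), toxic_elements()))
  expect_true(all(fl0$status == "normal"))

  expect_error(flag_out_of_reference(c(Xx = 1)), class = "autocmap_schema_error")
})

test_that("cohort_indices computes a complete per-subject index table", {
  co <- simulate_cohort(default_study_spec(), n = 30, seed = 9)
  idx <- cohort_indices(co)
  expect_equal(nrow(idx), 30)
  expect_equal(idx$fli, co$fli)
  expect_equal(as.integer(idx$mets), co$mets)
  expect_equal(idx$ti, co$ti)
  expect_true(all(idx$vai_cutoff %in% c(2.23, 1.92, 1.93, 2.0)))
})
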