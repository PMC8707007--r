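# Independent re-evaluations of the vendored score equations, written in a
# deliberately different (scalar, lookup-by-hand) style so they can serve as
# dual-implementation oracles.

frs_cad_oracle <- function(p) {
  cf <- frs_coefficients("cad")
  get <- function(sex, term, level)
    cf$value[cf$sex == sex & cf$term == term & cf$level == level]
  tc <- p$total_chol * 38.67
  hdl <- p$hdl * 38.67
  tc_lv <- if (tc < 160) "lt160" else if (tc < 200) "160_199" else
    if (tc < 240) "200_239" else if (tc < 280) "240_279" else "ge280"
  hdl_lv <- if (hdl < 35) "lt35" else if (hdl < 45) "35_44" else
    if (hdl < 50) "45_49" else if (hdl < 60) "50_59" else "ge60"
  bp_lv <- if (p$sbp >= 160 || p$dbp >= 100) "stage2plus" else
    if (p$sbp >= 140 || p$dbp >= 90) "stage1" else
      if (p$sbp >= 130 || p$dbp >= 85) "high_normal" else
        if (p$sbp >= 120 || p$dbp >= 80) "normal" else "optimal"
  sx <- p$sex
  L <- get(sx, "age", "linear") * p$age + get(sx, "tc", tc_lv) +
    get(sx, "hdl", hdl_lv) + get(sx, "bp", bp_lv) +
    get(sx, "diabetes", "yes") * isTRUE(p$dx_t2d) +
    get(sx, "smoker", "yes") *
      (p$smoking %in% c("current", "quit_lt1y"))
  if (sx == "female") L <- L + get(sx, "age_sq", "linear") * p$age^2
  1 - get(sx, "meta", "s0_10y")^exp(L - get(sx, "meta", "lmean"))
}

frs_logistic_oracle <- function(p, condition) {
  cf <- frs_coefficients(condition)
  v <- setNames(cf$value, cf$term)
  inputs <- c(age = p$age, male = as.numeric(p$sex == "male"),
              parental_history = as.numeric(
                p[[paste0("fh_", condition)]] >= 1),
              bmi = p$bmi, fasting_glucose = p$fasting_glucose,
              sbp = p$sbp, dbp = p$dbp, hdl = p$hdl,
              triglycerides = p$triglycerides,
              smoker = as.numeric(p$smoking %in% c("current", "quit_lt1y")))
  lp <- v[["intercept"]]
  for (term in setdiff(names(v), "intercept"))
    lp <- lp + v[[term]] * inputs[[term]]
  1 / (1 + exp(-lp))
}

random_profiles <- function(n, seed) {
  set.seed(seed)
  make_profiles(
    n,
    age = runif(n, 31, 73), sex = sample(c("female", "male"), n, TRUE),
    sbp = runif(n, 95, 139), dbp = runif(n, 60, 89),
    total_chol = runif(n, 3, 9), ldl = runif(n, 1.5, 5.5),
    hdl = runif(n, 0.6, 2.5), triglycerides = runif(n, 0.5, 4),
    hscrp = runif(n, 0.2, 8), fasting_glucose = runif(n, 3.8, 6.9),
    hba1c_pct = runif(n, 4.2, 6.9), bmi = runif(n, 18, 40),
    smoking = sample(c("never_or_quit_gt1y", "quit_lt1y", "current"), n, TRUE),
    fh_cad = sample(0:2, n, TRUE), fh_t2d = sample(0:2, n, TRUE),
    fh_htn = sample(0:2, n, TRUE))
}

test_that("each score equals its independent re-evaluation on 100 profiles", {
  prof <- random_profiles(100, seed = 7)
  got_cad <- frs_cad(prof)
  got_t2d <- frs_t2d(prof)
  got_htn <- frs_htn(prof)
  for (i in seq_len(100)) {
    p <- as.list(prof[i, ])
    expect_equal(got_cad[i], frs_cad_oracle(p), tolerance = 1e-10)
    expect_equal(got_t2d[i], frs_logistic_oracle(p, "t2d"), tolerance = 1e-10)
    expect_equal(got_htn[i], frs_logistic_oracle(p, "htn"), tolerance = 1e-10)
  }
  expect_true(all(got_cad >= 0 & got_cad <= 1))
  expect_true(all(got_t2d >= 0 & got_t2d <= 1))
  expect_true(all(got_htn >= 0 & got_htn <= 1))
})

test_that("the CHD equation reproduces a hand-evaluated reference profile", {
  # man aged 50, TC 180 mg/dL, HDL 47 mg/dL, BP normal, non-smoker,
  # no diabetes: L = 0.04826*50; risk = 1 - 0.90015^exp(L - 3.0975)
  p <- make_profiles(1, sex = "male", age = 50, total_chol = 180 / 38.67,
                     hdl = 47 / 38.67, sbp = 125, dbp = 82)
  expect_equal(frs_cad(p), 1 - 0.90015^exp(0.04826 * 50 - 3.0975),
               tolerance = 1e-12)
})

test_that("risks are monotone in their positive risk factors", {
  base <- make_profiles(1, age = 55, sex = "male")
  smoker <- make_profiles(1, age = 55, sex = "male", smoking = "current")
  expect_gt(frs_cad(smoker), frs_cad(base))
  basef <- make_profiles(1, age = 55)
  smokerf <- make_profiles(1, age = 55, smoking = "current")
  expect_gt(frs_cad(smokerf), frs_cad(basef))

  hi_glu <- make_profiles(1, age = 55, fasting_glucose = 6.4)
  lo_glu <- make_profiles(1, age = 55, fasting_glucose = 4.6)
  expect_gt(frs_t2d(hi_glu), frs_t2d(lo_glu))

  hi_sbp <- make_profiles(1, age = 55, sbp = 128)
  lo_sbp <- make_profiles(1, age = 55, sbp = 108)
  expect_gt(frs_htn(hi_sbp), frs_htn(lo_sbp))
})

test_that("out-of-range ages are clamped with a warning", {
  p <- make_profiles(1, age = 80, sex = "male")
  expect_warning(r80 <- frs_cad(p), "clamped")
  p74 <- make_profiles(1, age = 74, sex = "male")
  expect_equal(r80, frs_cad(p74))
})

test_that("probability categorisation follows the stated cutpoints", {
  expect_equal(as.character(categorize_clinical(c(0.09, 0.02, 0.03, 0.08),
                                                "t2d")),
               c("high", "low", "intermediate", "intermediate"))
  expect_equal(as.character(categorize_clinical(c(0.04, 0.11, 0.05, 0.10),
                                                "htn")),
               c("low", "high", "intermediate", "intermediate"))
  expect_error(categorize_clinical(1.2, "t2d"), "\\[0, 1\\]")
})

test_that("CAD tertiles are computed within sex and split evenly", {
  p <- seq(0.05, 0.45, length.out = 9)
  cat1 <- categorize_clinical(p, "cad", sex = rep("female", 9))
  expect_equal(as.integer(table(cat1)), c(3, 3, 3))
  expect_true(all(diff(as.integer(cat1)) >= 0))  # monotone in probability
  # sex-specific: the same probability can land in different tertiles
  sex <- rep(c("female", "male"), c(9, 9))
  probs <- c(p, p / 10)
  mixed <- categorize_clinical(probs, "cad", sex = sex)
  expect_equal(as.integer(table(mixed[1:9])), c(3, 3, 3))
  expect_equal(as.integer(table(mixed[10:18])), c(3, 3, 3))
})
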