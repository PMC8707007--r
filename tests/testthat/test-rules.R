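# Truth-table equivalence: every combination of clause states is realised as
# a concrete profile and the engine is compared against the independent
# clause evaluators in helper-profiles.R.

clin_states <- c("low", "intermediate", "high")
prs_states <- c("reference", "elevated", "high")

test_that("the CAD engine matches the brute-force clause evaluator", {
  flags <- expand.grid(tc_hi = c(FALSE, TRUE), sbp_hi = c(FALSE, TRUE),
                       ldl_hi = c(FALSE, TRUE), tg_out = c(FALSE, TRUE),
                       crp_out = c(FALSE, TRUE), hdl_out = c(FALSE, TRUE),
                       fh = c(FALSE, TRUE), clin = clin_states,
                       prs = prs_states, stringsAsFactors = FALSE)
  n <- nrow(flags)
  prof <- make_profiles(n)
  prof$total_chol <- ifelse(flags$tc_hi, 8.5, 4.6)
  prof$sbp <- ifelse(flags$sbp_hi, 185, 118)
  prof$ldl <- ifelse(flags$ldl_hi, 5.2, 2.6)
  prof$triglycerides <- ifelse(flags$tg_out, 2.0, 1.2)
  prof$hscrp <- ifelse(flags$crp_out, 4.0, 1.0)
  prof$hdl <- ifelse(flags$hdl_out, 0.8, 1.5)
  prof$fh_cad <- as.integer(flags$fh)
  got <- stratify_cad(prof, risk_factor(flags$clin), prs_factor(flags$prs))
  want <- vapply(seq_len(n), function(i)
    oracle_cad(as.list(prof[i, ]), flags$clin[i], flags$prs[i]), character(1))
  expect_equal(as.character(got$stratum), want)
  # fired_rules is empty exactly for NOT_ELEVATED
  expect_equal(got$fired_rules == "", want == "NOT_ELEVATED")
})

test_that("the T2D engine matches the brute-force clause evaluator", {
  flags <- expand.grid(a1c = c(5.0, 6.0, 6.6), glu = c(4.8, 5.8, 6.3, 7.4),
                       bmi = c(23, 27), age = c(40, 50), hdl = c(1.5, 0.8),
                       tg = c(1.2, 3.0), clin = clin_states,
                       prs = prs_states, stringsAsFactors = FALSE)
  n <- nrow(flags)
  prof <- make_profiles(n)
  prof$hba1c_pct <- flags$a1c
  prof$fasting_glucose <- flags$glu
  prof$bmi <- flags$bmi
  prof$age <- flags$age
  prof$hdl <- flags$hdl
  prof$triglycerides <- flags$tg
  got <- stratify_t2d(prof, risk_factor(flags$clin), prs_factor(flags$prs))
  want <- vapply(seq_len(n), function(i)
    oracle_t2d(as.list(prof[i, ]), flags$clin[i], flags$prs[i]), character(1))
  expect_equal(as.character(got$stratum), want)
  expect_equal(got$fired_rules == "", want == "NOT_ELEVATED")
})

test_that("the hypertension engine matches the brute-force clause evaluator", {
  flags <- expand.grid(sbp = c(118, 130, 134, 139, 142),
                       dbp = c(72, 80, 84, 89, 92), bmi = c(23, 27),
                       clin = clin_states, prs = prs_states,
                       stringsAsFactors = FALSE)
  n <- nrow(flags)
  prof <- make_profiles(n)
  prof$sbp <- flags$sbp
  prof$dbp <- pmin(flags$dbp, flags$sbp - 5)  # keep sbp > dbp valid
  prof$bmi <- flags$bmi
  got <- stratify_htn(prof, risk_factor(flags$clin), prs_factor(flags$prs))
  want <- vapply(seq_len(n), function(i)
    oracle_htn(as.list(prof[i, ]), flags$clin[i], flags$prs[i]), character(1))
  expect_equal(as.character(got$stratum), want)
})

test_that("single-clause anchor cases classify as stated", {
  low <- risk_factor("low"); ref <- prs_factor("reference")
  # CAD
  expect_equal(as.character(stratify_cad(
    make_profiles(1, total_chol = 8.5), low, ref)$stratum), "HIGH")
  expect_equal(as.character(stratify_cad(
    make_profiles(1), low, ref)$stratum), "NOT_ELEVATED")
  expect_equal(as.character(stratify_cad(      # decile 9, all else normal
    make_profiles(1), low, prs_factor("elevated"))$stratum), "ELEVATED")
  # T2D
  expect_equal(as.character(stratify_t2d(
    make_profiles(1, fasting_glucose = 6.3), low, ref)$stratum), "HIGH")
  expect_equal(as.character(stratify_t2d(
    make_profiles(1, hba1c_pct = 6.0, bmi = 27), low, ref)$stratum), "HIGH")
  expect_equal(as.character(stratify_t2d(
    make_profiles(1), low, ref)$stratum), "NOT_ELEVATED")
  # hypertension
  expect_equal(as.character(stratify_htn(
    make_profiles(1, sbp = 134, dbp = 70), low, ref)$stratum), "HIGH")
  expect_equal(as.character(stratify_htn(
    make_profiles(1, sbp = 118, dbp = 76), low, prs_factor("reference"))$stratum),
    "NOT_ELEVATED")
  expect_equal(as.character(stratify_htn(
    make_profiles(1, sbp = 118, dbp = 76), risk_factor("intermediate"),
    prs_factor("high"))$stratum), "HIGH")
})

test_that("worsening a HIGH-triggering marker never lowers the stratum", {
  low <- risk_factor("low"); ref <- prs_factor("reference")
  base <- make_profiles(1, total_chol = 8.5)
  worse <- make_profiles(1, total_chol = 9.5, ldl = 5.5, sbp = 190)
  s <- factor(c("NOT_ELEVATED", "ELEVATED", "HIGH", "CLINICAL"),
              levels = c("NOT_ELEVATED", "ELEVATED", "HIGH", "CLINICAL"),
              ordered = TRUE)
  expect_gte(as.integer(stratify_cad(worse, low, ref)$stratum),
             as.integer(stratify_cad(base, low, ref)$stratum))
  b2 <- make_profiles(1, fasting_glucose = 6.3)
  w2 <- make_profiles(1, fasting_glucose = 6.9, hba1c_pct = 6.8)
  expect_gte(as.integer(stratify_t2d(w2, low, ref)$stratum),
             as.integer(stratify_t2d(b2, low, ref)$stratum))
})

test_that("the disjunctive reading of the compound T2D clause is switchable", {
  prof <- make_profiles(1)  # all markers normal
  cfg <- rule_config(t2d_high_disjunctive = TRUE)
  # clinical high alone is enough under the disjunctive reading
  expect_equal(as.character(stratify_t2d(prof, risk_factor("high"),
                                         prs_factor("reference"),
                                         cfg)$stratum), "HIGH")
  # but not under the default conjunctive reading
  expect_equal(as.character(stratify_t2d(prof, risk_factor("high"),
                                         prs_factor("reference"))$stratum),
               "ELEVATED")
})

test_that("clinical-threshold crossings map to CLINICAL, and advice is HIGH-only", {
  low <- risk_factor("low"); ref <- prs_factor("reference")
  st <- stratify_t2d(make_profiles(1, fasting_glucose = 7.4), low, ref)
  expect_equal(as.character(st$stratum), "CLINICAL")
  expect_equal(st$fired_rules, "clinical_threshold")
  st2 <- stratify_htn(make_profiles(1, sbp = 145, dbp = 95), low, ref)
  expect_equal(as.character(st2$stratum), "CLINICAL")
  expect_equal(advised_intervention(c("HIGH", "ELEVATED", "CLINICAL",
                                      "NOT_ELEVATED")),
               c(TRUE, FALSE, FALSE, FALSE))
})

test_that("missing rule inputs fail rather than classify", {
  prof <- make_profiles(1)
  prof$hdl <- NA
  expect_error(stratify_cad(prof, risk_factor("low"), prs_factor("reference")),
               "missing values")
  prof2 <- make_profiles(1)
  prof2$bmi <- NULL
  expect_error(stratify_htn(prof2, risk_factor("low"),
                            prs_factor("reference")), "bmi")
})
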