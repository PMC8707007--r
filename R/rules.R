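# The three decision-rules classifiers. Each maps a participant profile,
# a Framingham clinical-risk category and a genetic risk group to one of four
# ordinal strata: NOT_ELEVATED < ELEVATED < HIGH < CLINICAL. HIGH is the
# stratum for which lifestyle intervention is advised; CLINICAL marks
# participants past a clinical threshold, who are referred to care rather
# than advised lifestyle change.

.strata_levels <- c("NOT_ELEVATED", "ELEVATED", "HIGH", "CLINICAL")

#' Decision-rule threshold configuration
#'
#' Every numeric comparison used by the three engines, named and overridable.
#' Interval conventions: "above x"/"below x" are strict; bands such as SBP
#' 130--139 are closed. `ranges` give the per-condition reference ("normal")
#' ranges used by the not-elevated arm, as `c(lower, upper)` with inclusive
#' lower and exclusive upper bound; these are conventional guideline values
#' and are configurable because the defining study left them verbal.
#'
#' @param ... named overrides of the defaults listed below.
#' @return a `rule_config` list.
#' @export
rule_config <- function(...) {
  cfg <- list(
    # CAD high-risk clauses
    cad_tc_high = 8, cad_sbp_high = 180, cad_ldl_high = 4.9,
    tg_max = 1.7, crp_max = 3,
    # T2D clauses
    t2d_hba1c_high = 6.5, t2d_glucose_high = 6.1,
    t2d_glyc_hba1c = c(5.5, 6.4), t2d_glyc_glucose = c(5.6, 6.1),
    t2d_overweight_bmi = 25, t2d_age_min = 45, t2d_hdl_low = 0.9,
    t2d_tg_high = 2.8,
    # alternative (disjunctive) reading of the compound T2D clause
    t2d_high_disjunctive = FALSE,
    # hypertension clauses (closed bands)
    htn_sbp_band = c(130, 139), htn_dbp_band = c(80, 89),
    # clinical thresholds (mirror the baseline exclusion rules)
    clin_sbp = 140, clin_dbp = 90, clin_glucose = 7.0,
    # not-elevated-arm reference ranges [lower, upper)
    ranges = list(
      cad = list(total_chol = c(0, 5.0), ldl = c(0, 3.0), hdl = c(1.0, Inf),
                 triglycerides = c(0, 1.7), hscrp = c(0, 3.0),
                 sbp = c(0, 130)),
      t2d = list(fasting_glucose = c(0, 5.6), hba1c_pct = c(0, 5.5),
                 bmi = c(0, 25), triglycerides = c(0, 1.7),
                 hdl = c(1.0, Inf)),
      htn = list(sbp = c(0, 130), dbp = c(0, 80), bmi = c(0, 25))))
  override <- list(...)
  unknown <- setdiff(names(override), names(cfg))
  if (length(unknown) > 0)
    stop("unknown rule_config field(s): ", paste(unknown, collapse = ", "))
  cfg[names(override)] <- override
  class(cfg) <- "rule_config"
  cfg
}

# markers out of their reference range; returns list(any = logical vector,
# fired = per-participant character of offending markers)
.out_of_range <- function(profile, ranges) {
  n <- nrow(profile)
  fired <- rep("", n)
  any_out <- rep(FALSE, n)
  for (marker in names(ranges)) {
    r <- ranges[[marker]]
    out <- profile[[marker]] < r[1] | profile[[marker]] >= r[2]
    any_out <- any_out | out
    fired <- ifelse(out, paste0(fired, ifelse(fired == "", "", ";"),
                                "out_of_range:", marker), fired)
  }
  list(any = any_out, fired = fired)
}

.check_rule_inputs <- function(profile, clinical, prs_group, fields) {
  miss <- setdiff(fields, names(profile))
  if (length(miss) > 0)
    stop("profile missing required field(s): ", paste(miss, collapse = ", "))
  if (anyNA(profile[, fields, drop = FALSE]))
    stop("missing values in rule inputs; apply eligibility exclusions first")
  stopifnot(length(clinical) == nrow(profile),
            length(prs_group) == nrow(profile))
}

.assemble_strata <- function(clinical_cross, high, low, fired_high,
                             fired_elevated) {
  stratum <- ifelse(clinical_cross, "CLINICAL",
                    ifelse(high, "HIGH",
                           ifelse(low, "NOT_ELEVATED", "ELEVATED")))
  fired <- ifelse(stratum == "CLINICAL", "clinical_threshold",
                  ifelse(stratum == "HIGH", fired_high,
                         ifelse(stratum == "NOT_ELEVATED", "",
                                fired_elevated)))
  data.frame(stratum = factor(stratum, levels = .strata_levels,
                              ordered = TRUE),
             fired_rules = fired, stringsAsFactors = FALSE)
}

.join_fired <- function(...) {
  parts <- list(...)
  out <- rep("", length(parts[[1]]$flag))
  for (p in parts)
    out <- ifelse(p$flag, paste0(out, ifelse(out == "", "", ";"), p$label),
                  out)
  out
}

#' Decision-rules stratum for coronary artery disease
#'
#' HIGH if any of: total cholesterol above 8 mmol/L; SBP above 180 mmHg; LDL
#' above 4.9 mmol/L; triglycerides and/or hs-CRP out of range together with a
#' high Framingham category or a high genetic risk group. NOT_ELEVATED if no
#' CAD-relevant biomarker is out of its reference range, the PRS decile is
#' below the eighth (reference group) and family history is negative.
#' Otherwise ELEVATED. Fasting glucose past the clinical threshold marks
#' CLINICAL (referred to care); baseline blood-pressure exclusions are the
#' eligibility module's job, and SBP above 180 is this rule set's own HIGH
#' trigger.
#'
#' @param profile data frame of participant records (post-exclusion).
#' @param clinical Framingham category factor (`low`/`intermediate`/`high`).
#' @param prs_group genetic risk group factor
#'   (`reference`/`elevated`/`high`), see [bin_deciles()].
#' @param config a [rule_config()].
#' @return data frame with ordered factor `stratum` and `fired_rules`
#'   (semicolon-joined clause labels; empty only for NOT_ELEVATED).
#' @export
stratify_cad <- function(profile, clinical, prs_group,
                         config = rule_config()) {
  .check_rule_inputs(profile, clinical, prs_group,
                     c("total_chol", "ldl", "hdl", "triglycerides", "hscrp",
                       "sbp", "dbp", "fasting_glucose", "fh_cad"))
  tc_hit <- profile$total_chol > config$cad_tc_high
  sbp_hit <- profile$sbp > config$cad_sbp_high
  ldl_hit <- profile$ldl > config$cad_ldl_high
  tgcrp <- (profile$triglycerides > config$tg_max |
              profile$hscrp > config$crp_max) &
    (clinical == "high" | prs_group == "high")
  high <- tc_hit | sbp_hit | ldl_hit | tgcrp

  oor <- .out_of_range(profile, config$ranges$cad)
  low <- !oor$any & prs_group == "reference" & profile$fh_cad == 0
  # SBP above 180 is a HIGH trigger of this rule set, so the blood-pressure
  # exclusion threshold is not re-applied here; the glucose threshold marks
  # participants who belong in medical care rather than lifestyle advice.
  clin_cross <- profile$fasting_glucose > config$clin_glucose

  fired_high <- .join_fired(
    list(flag = tc_hit, label = "total_chol_gt_8"),
    list(flag = sbp_hit, label = "sbp_gt_180"),
    list(flag = ldl_hit, label = "ldl_gt_4.9"),
    list(flag = tgcrp, label = "tg_or_crp_out_with_high_risk"))
  fired_elev <- .join_fired(
    list(flag = oor$any, label = oor$fired),
    list(flag = prs_group != "reference", label = "prs_decile_ge_8"),
    list(flag = profile$fh_cad > 0, label = "family_history"))
  .assemble_strata(clin_cross, high, low, fired_high, fired_elev)
}

#' Decision-rules stratum for type 2 diabetes
#'
#' HIGH if any of: HbA1c above 6.5% with fasting glucose below 6.1 mmol/L;
#' fasting glucose above 6.1 mmol/L; an elevated glycaemic variable (HbA1c
#' 5.5--6.4% or glucose 5.6--6.1 mmol/L) together with overweight/obesity
#' (BMI >= 25); high clinical risk with unregulated glucose (the same
#' elevated glycaemic state) and high genetic risk (one conjunctive clause by
#' default; `t2d_high_disjunctive = TRUE` reads the three as separate rules);
#' or intermediate clinical risk with age over 45, HDL below 0.9 mmol/L and
#' triglycerides above 2.8 mmol/L. NOT_ELEVATED if all reference-range
#' markers are in range, the PRS group is `reference` and clinical risk is
#' low. Otherwise ELEVATED; glucose above 7.0 mmol/L is CLINICAL.
#'
#' @inheritParams stratify_cad
#' @return see [stratify_cad()].
#' @export
stratify_t2d <- function(profile, clinical, prs_group,
                         config = rule_config()) {
  .check_rule_inputs(profile, clinical, prs_group,
                     c("age", "fasting_glucose", "hba1c_pct", "bmi", "hdl",
                       "triglycerides"))
  g <- profile$fasting_glucose
  a1c <- profile$hba1c_pct
  glyc_elev <- (a1c >= config$t2d_glyc_hba1c[1] &
                  a1c <= config$t2d_glyc_hba1c[2]) |
    (g >= config$t2d_glyc_glucose[1] & g <= config$t2d_glyc_glucose[2])

  a1c_hit <- a1c > config$t2d_hba1c_high & g < config$t2d_glucose_high
  glu_hit <- g > config$t2d_glucose_high
  ow_hit <- glyc_elev & profile$bmi >= config$t2d_overweight_bmi
  if (isTRUE(config$t2d_high_disjunctive)) {
    compound <- clinical == "high" | glyc_elev | prs_group == "high"
  } else {
    compound <- clinical == "high" & glyc_elev & prs_group == "high"
  }
  lipid_hit <- clinical == "intermediate" & profile$age > config$t2d_age_min &
    profile$hdl < config$t2d_hdl_low &
    profile$triglycerides > config$t2d_tg_high
  high <- a1c_hit | glu_hit | ow_hit | compound | lipid_hit

  oor <- .out_of_range(profile, config$ranges$t2d)
  low <- !oor$any & prs_group == "reference" & clinical == "low"
  clin_cross <- g > config$clin_glucose

  fired_high <- .join_fired(
    list(flag = a1c_hit, label = "hba1c_gt_6.5_glucose_lt_6.1"),
    list(flag = glu_hit, label = "glucose_gt_6.1"),
    list(flag = ow_hit, label = "glycaemic_elevated_and_overweight"),
    list(flag = compound, label = "clinical_high_glucose_unregulated_prs_high"),
    list(flag = lipid_hit, label = "clinical_intermediate_age_hdl_tg"))
  fired_elev <- .join_fired(
    list(flag = oor$any, label = oor$fired),
    list(flag = prs_group != "reference", label = "prs_decile_ge_8"),
    list(flag = clinical != "low", label = "clinical_risk_elevated"))
  .assemble_strata(clin_cross, high, low, fired_high, fired_elev)
}

#' Decision-rules stratum for hypertension
#'
#' HIGH if any of: high-normal SBP (130--139 mmHg); DBP 80--89 mmHg; high
#' clinical risk; intermediate clinical risk together with a high PRS group.
#' NOT_ELEVATED if SBP, DBP and BMI are in their reference ranges, the PRS
#' group is `reference` and clinical risk is low. Otherwise ELEVATED;
#' SBP >= 140 or DBP >= 90 is CLINICAL (such participants are excluded from
#' the analysis cohort at baseline).
#'
#' @inheritParams stratify_cad
#' @return see [stratify_cad()].
#' @export
stratify_htn <- function(profile, clinical, prs_group,
                         config = rule_config()) {
  .check_rule_inputs(profile, clinical, prs_group, c("sbp", "dbp", "bmi"))
  sbp_hit <- profile$sbp >= config$htn_sbp_band[1] &
    profile$sbp <= config$htn_sbp_band[2]
  dbp_hit <- profile$dbp >= config$htn_dbp_band[1] &
    profile$dbp <= config$htn_dbp_band[2]
  clin_hit <- clinical == "high"
  combo_hit <- clinical == "intermediate" & prs_group == "high"
  high <- sbp_hit | dbp_hit | clin_hit | combo_hit

  oor <- .out_of_range(profile, config$ranges$htn)
  low <- !oor$any & prs_group == "reference" & clinical == "low"
  clin_cross <- profile$sbp >= config$clin_sbp | profile$dbp >= config$clin_dbp

  fired_high <- .join_fired(
    list(flag = sbp_hit, label = "sbp_130_139"),
    list(flag = dbp_hit, label = "dbp_80_89"),
    list(flag = clin_hit, label = "clinical_high"),
    list(flag = combo_hit, label = "clinical_intermediate_prs_high"))
  fired_elev <- .join_fired(
    list(flag = oor$any, label = oor$fired),
    list(flag = prs_group != "reference", label = "prs_decile_ge_8"),
    list(flag = clinical != "low", label = "clinical_risk_elevated"))
  .assemble_strata(clin_cross, high, low, fired_high, fired_elev)
}

#' Is lifestyle intervention advised for a stratum?
#'
#' `TRUE` only for HIGH. CLINICAL participants have crossed a clinical
#' threshold and are referred to medical care, not advised lifestyle
#' intervention; ELEVATED and NOT_ELEVATED are below the advice cutoff. This
#' dichotomy underlies all sensitivity/specificity and reclassification
#' statistics.
#'
#' @param stratum factor/character vector of strata.
#' @return logical vector.
#' @export
advised_intervention <- function(stratum) {
  as.character(stratum) == "HIGH"
}
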