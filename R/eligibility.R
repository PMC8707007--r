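# Baseline eligibility: forms the per-condition analysis cohorts by removing
# participants already diagnosed, those past a clinical threshold at
# baseline, those with impaired kidney function, and incomplete records.

#' Baseline exclusion thresholds
#'
#' Clinical thresholds: at least grade-1 hypertension (SBP >= 140 mmHg and/or
#' DBP >= 90 mmHg) and fasting glucose above 7.0 mmol/L. Kidney impairment
#' defaults follow KDIGO-style guideline cutpoints (eGFR < 60 mL/min/1.73m2
#' or albumin-creatinine ratio > 3 mg/mmol); both are configurable because
#' guideline operationalisations vary. When `clinical_global` is `TRUE`
#' (default) the blood-pressure and glucose thresholds exclude from all three
#' condition cohorts; otherwise each applies only to its matching condition.
#'
#' @param sbp_max,dbp_max exclusion at `sbp >= sbp_max` or `dbp >= dbp_max`.
#' @param glucose_max exclusion at fasting glucose strictly above this value.
#' @param egfr_min exclusion at eGFR strictly below this value.
#' @param acr_max exclusion at ACR strictly above this value.
#' @param clinical_global apply BP/glucose thresholds to all cohorts.
#' @return named list of thresholds.
#' @export
exclusion_thresholds <- function(sbp_max = 140, dbp_max = 90,
                                 glucose_max = 7.0, egfr_min = 60,
                                 acr_max = 3, clinical_global = TRUE) {
  list(sbp_max = sbp_max, dbp_max = dbp_max, glucose_max = glucose_max,
       egfr_min = egfr_min, acr_max = acr_max,
       clinical_global = clinical_global)
}

# fields whose completeness is required for analysis
.mandatory_fields <- c(
  "age", "sex", "sbp", "dbp", "total_chol", "ldl", "hdl", "triglycerides",
  "hscrp", "fasting_glucose", "hba1c_pct", "bmi", "waist", "smoking",
  "bp_treatment", "egfr", "acr",
  paste0("fh_", .conditions), paste0("dx_", .conditions),
  paste0("event_", .conditions), paste0("time_", .conditions))

#' Apply baseline exclusion rules
#'
#' Per condition, removes (in order, logging the first matching rule):
#' records with any missing mandatory field; participants with a baseline
#' physician diagnosis of that condition; those at or past the
#' blood-pressure threshold; those above the fasting-glucose threshold;
#' those with impaired kidney function. Kidney exclusions are always global;
#' BP/glucose follow `thresholds$clinical_global`.
#'
#' @param cohort a `cohort`.
#' @param thresholds see [exclusion_thresholds()].
#' @return list with `cohorts` (named list of per-condition cohorts),
#'   `report` (per-participant kept flags and first exclusion reason per
#'   condition) and `summary` (counts per rule per condition).
#' @export
apply_baseline_exclusions <- function(cohort,
                                      thresholds = exclusion_thresholds()) {
  required <- c("sbp_max", "dbp_max", "glucose_max", "egfr_min", "acr_max",
                "clinical_global")
  miss <- setdiff(required, names(thresholds))
  if (length(miss) > 0)
    stop("thresholds missing required key(s): ", paste(miss, collapse = ", "))
  df <- as.data.frame(cohort)
  n <- nrow(df)

  incomplete <- rowSums(is.na(df[, .mandatory_fields, drop = FALSE])) > 0
  bp_cross <- !incomplete & (df$sbp >= thresholds$sbp_max |
                               df$dbp >= thresholds$dbp_max)
  glu_cross <- !incomplete & df$fasting_glucose > thresholds$glucose_max
  kidney <- !incomplete & (df$egfr < thresholds$egfr_min |
                             df$acr > thresholds$acr_max)

  report <- data.frame(id = df$id, stringsAsFactors = FALSE)
  cohorts <- list()
  summary <- list()
  for (cond in .conditions) {
    reason <- character(n)
    hit <- function(flag, label) {
      reason[flag & reason == ""] <<- label
    }
    hit(incomplete, "missing mandatory field")
    hit(df[[paste0("dx_", cond)]] %in% TRUE, "diagnosed at baseline")
    if (thresholds$clinical_global || cond == "htn")
      hit(bp_cross, "blood pressure >= 140/90")
    if (thresholds$clinical_global || cond == "t2d")
      hit(glu_cross, "fasting glucose > 7.0 mmol/L")
    hit(kidney, "impaired kidney function")
    kept <- reason == ""
    report[[paste0("kept_", cond)]] <- kept
    report[[paste0("reason_", cond)]] <- ifelse(kept, NA_character_, reason)
    sub <- df[kept, , drop = FALSE]
    cohorts[[cond]] <- .as_cohort(sub, source = attr(cohort, "source"))
    summary[[cond]] <- c(table(factor(reason[!kept])), kept = sum(kept))
  }
  list(cohorts = cohorts, report = report, summary = summary)
}

#' Write an exclusion report
#'
#' TSV of per-participant kept flags and reasons plus a JSON summary of
#' counts per rule.
#'
#' @param exclusions result of [apply_baseline_exclusions()].
#' @param tsv_path,json_path output paths.
#' @export
write_exclusion_report <- function(exclusions, tsv_path, json_path) {
  utils::write.table(exclusions$report, tsv_path, sep = "\t",
                     row.names = FALSE, quote = FALSE, na = "")
  jsonlite::write_json(exclusions$summary, json_path, auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(NULL)
}
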