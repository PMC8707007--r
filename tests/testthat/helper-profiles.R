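# Shared fixture builders: an all-in-range participant profile, a full
# cohort frame, and independent brute-force evaluators of the three
# decision-rule clause sets (used as oracles against the engines).

make_profiles <- function(n = 1, ...) {
  df <- data.frame(
    id = sprintf("x%04d", seq_len(max(n, 1))),
    age = 40, sex = "female", sbp = 118, dbp = 72,
    total_chol = 4.6, ldl = 2.6, hdl = 1.5, triglycerides = 1.2,
    hscrp = 1.0, fasting_glucose = 4.8, hba1c_pct = 5.0,
    bmi = 23, waist = 80, smoking = "never_or_quit_gt1y",
    bp_treatment = FALSE, egfr = 95, acr = 1.0,
    fh_cad = 0, fh_t2d = 0, fh_htn = 0,
    dx_cad = FALSE, dx_t2d = FALSE, dx_htn = FALSE,
    event_cad = FALSE, event_t2d = FALSE, event_htn = FALSE,
    time_cad = 8.8, time_t2d = 8.8, time_htn = 8.8,
    array = "axiom", pc1 = 0, pc2 = 0, pc3 = 0, pc4 = 0,
    stringsAsFactors = FALSE
  )
  df <- df[seq_len(n), , drop = FALSE]
  rownames(df) <- NULL
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  df
}

risk_factor <- function(x) factor(x, levels = c("low", "intermediate", "high"),
                                  ordered = TRUE)
prs_factor <- function(x) factor(x, levels = c("reference", "elevated", "high"))

# Brute-force clause evaluators, written directly from the rule text and kept
# independent of the engine implementation. All take scalar inputs.

oracle_cad <- function(p, clinical, prs_group) {
  if (p$fasting_glucose > 7.0) return("CLINICAL")
  high <- (p$total_chol > 8) || (p$sbp > 180) || (p$ldl > 4.9) ||
    ((p$triglycerides > 1.7 || p$hscrp > 3) &&
       (clinical == "high" || prs_group == "high"))
  if (high) return("HIGH")
  in_range <- p$total_chol < 5.0 && p$ldl < 3.0 && p$hdl >= 1.0 &&
    p$triglycerides < 1.7 && p$hscrp < 3.0 && p$sbp < 130
  if (in_range && prs_group == "reference" && p$fh_cad == 0)
    return("NOT_ELEVATED")
  "ELEVATED"
}

oracle_t2d <- function(p, clinical, prs_group) {
  g <- p$fasting_glucose; a1c <- p$hba1c_pct
  if (g > 7.0) return("CLINICAL")
  glyc <- (a1c >= 5.5 && a1c <= 6.4) || (g >= 5.6 && g <= 6.1)
  high <- (a1c > 6.5 && g < 6.1) || (g > 6.1) || (glyc && p$bmi >= 25) ||
    (clinical == "high" && glyc && prs_group == "high") ||
    (clinical == "intermediate" && p$age > 45 && p$hdl < 0.9 &&
       p$triglycerides > 2.8)
  if (high) return("HIGH")
  in_range <- g < 5.6 && a1c < 5.5 && p$bmi < 25 && p$triglycerides < 1.7 &&
    p$hdl >= 1.0
  if (in_range && prs_group == "reference" && clinical == "low")
    return("NOT_ELEVATED")
  "ELEVATED"
}

oracle_htn <- function(p, clinical, prs_group) {
  if (p$sbp >= 140 || p$dbp >= 90) return("CLINICAL")
  high <- (p$sbp >= 130 && p$sbp <= 139) || (p$dbp >= 80 && p$dbp <= 89) ||
    clinical == "high" || (clinical == "intermediate" && prs_group == "high")
  if (high) return("HIGH")
  in_range <- p$sbp < 130 && p$dbp < 80 && p$bmi < 25
  if (in_range && prs_group == "reference" && clinical == "low")
    return("NOT_ELEVATED")
  "ELEVATED"
}

# Realise every combination of clause states for a condition as concrete
# profiles and return engine vs oracle strata, for truth-table equivalence.
run_truth_table <- function(condition) {
  clin <- c("low", "intermediate", "high")
  prs <- c("reference", "elevated", "high")
  if (condition == "cad") {
    flags <- expand.grid(tc = c(4.6, 8.5), sbp = c(118, 185),
                         ldl = c(2.6, 5.2), tg = c(1.2, 2.0),
                         crp = c(1.0, 4.0), hdl = c(1.5, 0.8),
                         fh = c(0, 1), clin = clin, prs = prs,
                         stringsAsFactors = FALSE)
    prof <- make_profiles(nrow(flags), total_chol = flags$tc, sbp = flags$sbp,
                          ldl = flags$ldl, triglycerides = flags$tg,
                          hscrp = flags$crp, hdl = flags$hdl,
                          fh_cad = flags$fh)
    engine <- stratify_cad
    oracle <- oracle_cad
  } else if (condition == "t2d") {
    flags <- expand.grid(a1c = c(5.0, 6.0, 6.6), glu = c(4.8, 5.8, 6.3, 7.4),
                         bmi = c(23, 27), age = c(40, 50), hdl = c(1.5, 0.8),
                         tg = c(1.2, 3.0), clin = clin, prs = prs,
                         stringsAsFactors = FALSE)
    prof <- make_profiles(nrow(flags), hba1c_pct = flags$a1c,
                          fasting_glucose = flags$glu, bmi = flags$bmi,
                          age = flags$age, hdl = flags$hdl,
                          triglycerides = flags$tg)
    engine <- stratify_t2d
    oracle <- oracle_t2d
  } else {
    flags <- expand.grid(sbp = c(118, 130, 134, 139, 142),
                         dbp = c(72, 80, 84, 89, 92), bmi = c(23, 27),
                         clin = clin, prs = prs, stringsAsFactors = FALSE)
    prof <- make_profiles(nrow(flags), sbp = flags$sbp,
                          dbp = pmin(flags$dbp, flags$sbp - 5),
                          bmi = flags$bmi)
    engine <- stratify_htn
    oracle <- oracle_htn
  }
  got <- engine(prof, risk_factor(flags$clin), prs_factor(flags$prs))
  want <- vapply(seq_len(nrow(prof)), function(i)
    oracle(as.list(prof[i, ]), flags$clin[i], flags$prs[i]), character(1))
  list(got = as.character(got$stratum), want = want)
}

# brute-force AUROC by pair counting
pair_count_auc <- function(scores, events) {
  s1 <- scores[events]; s0 <- scores[!events]
  tot <- 0
  for (a in s1) for (b in s0) tot <- tot + (a > b) + 0.5 * (a == b)
  tot / (length(s1) * length(s0))
}
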