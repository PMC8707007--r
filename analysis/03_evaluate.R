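#!/usr/bin/env Rscript
# Stage 3: evaluation of the decision rules against the Framingham scores on
# the synthetic cohort.
#
# For each condition: confusion counts and sensitivity/specificity at the
# advised-intervention dichotomy, bootstrap AUROCs (rules stratum as an
# ordinal predictor, Framingham probability as a continuous one), a DeLong
# comparison, the reclassification table and NRI, Cox hazard ratios per
# stratum with absolute risks, PRS decile contrasts, and the per-decile
# incidence table. Writes results/evaluation/.

library(riskrules)

seed <- 1
B <- 200
stratadir <- "results/strata"
datadir <- "results/data"
outdir <- "results/evaluation"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

cohort <- read_cohort(file.path(datadir, "cohort.tsv"))
cdf <- as.data.frame(cohort)

summary_rows <- list()
for (cond in c("cad", "t2d", "htn")) {
  st <- read.delim(file.path(stratadir, paste0(cond, "_strata.tsv")))
  df <- cdf[match(st$id, cdf$id), ]
  ev <- df[[paste0("event_", cond)]]
  tm <- df[[paste0("time_", cond)]]

  adv_rules <- st$advised
  adv_frs <- st$clinical_category == "high"
  ss_rules <- sens_spec(confusion_at_high(adv_rules, ev))
  auc_rules <- auroc(as.integer(factor(st$stratum,
                                       levels = c("NOT_ELEVATED", "ELEVATED",
                                                  "HIGH", "CLINICAL"))),
                     ev, B = B, seed = seed + 1)
  auc_frs <- auroc(st$frs_probability, ev, B = B, seed = seed + 2)
  dl <- delong_compare(as.integer(factor(st$stratum)), st$frs_probability, ev)
  reclass <- build_reclassification(adv_frs, adv_rules, ev)
  nri_est <- nri(reclass)

  cox <- fit_cox_strata(tm, ev, st$stratum, reference = "NOT_ELEVATED",
                        horizon = 8.8)
  write.table(cox$table, file.path(outdir, paste0(cond, "_stratum_hr.tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)
  hrs <- do.call(rbind, lapply(
    c("top_vs_rest", "top_vs_1to7", "8and9_vs_1to7"),
    function(ct) prs_decile_hrs(tm, ev, st$prs_decile, contrast = ct)))
  write.table(hrs, file.path(outdir, paste0(cond, "_prs_decile_hr.tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)
  write.table(decile_incidence(st$prs_decile, ev, times = tm),
              file.path(outdir, paste0(cond, "_decile_incidence.tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)
  km <- cumulative_incidence(tm, ev, st$prs_group)
  write.table(km, file.path(outdir, paste0(cond, "_cuminc_prs_group.tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)

  sens <- ss_rules$point[ss_rules$metric == "sensitivity"]
  spec <- ss_rules$point[ss_rules$metric == "specificity"]
  cat(sprintf(
    "%s: AUROC rules %.3f (%.3f-%.3f) vs FRS %.3f; DeLong p %.3g; NRI %.1f%% (p %.3g)\n",
    cond, auc_rules$point, auc_rules$ci_low, auc_rules$ci_high,
    auc_frs$point, dl$p_value, nri_est$point, nri_est$p_value))
  cat(sprintf("    sensitivity %.1f%%, specificity %.1f%%, person-years %.0f\n",
              100 * sens, 100 * spec, cox$person_years))
  summary_rows[[cond]] <- data.frame(
    condition = cond, n = nrow(st), events = sum(ev),
    auroc_rules = auc_rules$point, auroc_frs = auc_frs$point,
    delong_p = dl$p_value, nri = nri_est$point, nri_p = nri_est$p_value,
    sensitivity = sens, specificity = spec,
    hr_high = cox$table$hr[cox$table$stratum == "HIGH"],
    hr_prs_top_vs_rest = hrs$estimate[hrs$contrast == "top_vs_rest"])
}

write.table(do.call(rbind, summary_rows),
            file.path(outdir, "summary.tsv"), sep = "\t", row.names = FALSE,
            quote = FALSE)
cat("wrote evaluation tables to", outdir, "\n")
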