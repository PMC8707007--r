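#!/usr/bin/env Rscript
# Stage 2: eligibility, scoring and decision-rules stratification.
#
# Reads the stage-1 files back through the package's ingestion layer (so the
# analysis exercises the same path real data would take), applies the
# baseline exclusions, filters variants at imputation quality 0.4, computes
# the additive PRS and its deciles per analysis cohort, the Framingham
# probabilities and categories, and the four-level decision-rules stratum.
# Writes per-condition stratification tables under results/strata/.

library(riskrules)

datadir <- "results/data"
outdir <- "results/strata"
dir.create(outdir, showWarnings = FALSE, recursive = TRUE)

cohort <- read_cohort(file.path(datadir, "cohort.tsv"))
dosages_df <- read.delim(file.path(datadir, "dosages.tsv"),
                         check.names = FALSE)
dosages <- as.matrix(dosages_df[, -1])
rownames(dosages) <- dosages_df$id
weights <- filter_variants(read.delim(file.path(datadir, "weights.tsv")),
                           min_info = 0.4)

ex <- apply_baseline_exclusions(cohort)
write_exclusion_report(ex, file.path(outdir, "exclusions.tsv"),
                       file.path(outdir, "exclusions.json"))
cat("analysis cohorts after baseline exclusions:",
    sprintf("%s %d", names(ex$cohorts), vapply(ex$cohorts, nrow, 1L)), "\n")

frs_fun <- list(cad = frs_cad, t2d = frs_t2d, htn = frs_htn)
strat_fun <- list(cad = stratify_cad, t2d = stratify_t2d, htn = stratify_htn)

for (cond in c("cad", "t2d", "htn")) {
  df <- as.data.frame(ex$cohorts[[cond]])
  D <- dosages[match(df$id, rownames(dosages)), , drop = FALSE]
  raw <- compute_prs(D, weights)
  dec <- bin_deciles(raw)
  prob <- frs_fun[[cond]](df)
  clinical <- categorize_clinical(prob, cond, sex = df$sex)
  st <- strat_fun[[cond]](df, clinical, dec$group)
  out <- data.frame(id = df$id, condition = cond, prs_raw = raw,
                    prs_decile = dec$decile, prs_group = dec$group,
                    frs_probability = prob, clinical_category = clinical,
                    stratum = st$stratum, fired_rules = st$fired_rules,
                    advised = advised_intervention(st$stratum))
  write.table(out, file.path(outdir, paste0(cond, "_strata.tsv")),
              sep = "\t", row.names = FALSE, quote = FALSE)
  cat(sprintf("%s: %s | advised %.1f%%\n", cond,
              paste(names(table(st$stratum)), table(st$stratum),
                    collapse = ", "),
              100 * mean(out$advised)))
}
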