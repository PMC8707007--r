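# End-to-end orchestration: simulate or ingest -> exclude -> score ->
# stratify -> evaluate, producing a nested report plus optional JSON/TSV
# artifacts. Identical configuration and seed give a byte-identical report.

#' Pipeline run configuration
#'
#' Either simulate a cohort (`sim`, default) or read one from `paths` (a list
#' with `cohort`, `dosages`, `weights` file paths; dosages as a TSV matrix
#' with a leading id column, weights as the standard weight-table TSV). The
#' seed governs every stochastic stage (simulation and bootstrap resampling).
#'
#' @param seed integer seed (mandatory).
#' @param conditions subset of `c("cad","t2d","htn")`.
#' @param bootstrap_B bootstrap iterations for AUROC CIs (default 2000).
#' @param min_info imputation-quality threshold for variant filtering.
#' @param sim a [sim_config()]; defaults to `sim_config(seed = seed)`.
#' @param paths optional list of input file paths (overrides `sim`).
#' @param thresholds baseline [exclusion_thresholds()].
#' @param rules a [rule_config()].
#' @param horizon_years horizon for absolute risk.
#' @param outdir optional output directory for report.json and TSV tables.
#' @return a `run_config` list.
#' @export
run_config <- function(seed, conditions = c("cad", "t2d", "htn"),
                       bootstrap_B = 2000, min_info = 0.4, sim = NULL,
                       paths = NULL, thresholds = exclusion_thresholds(),
                       rules = rule_config(), horizon_years = 8.8,
                       outdir = NULL) {
  if (missing(seed)) stop("seed is mandatory")
  conditions <- match.arg(conditions, several.ok = TRUE)
  if (length(conditions) == 0) stop("conditions must be non-empty")
  if (is.null(sim)) sim <- sim_config(seed = seed)
  structure(list(seed = as.integer(seed), conditions = conditions,
                 bootstrap_B = bootstrap_B, min_info = min_info, sim = sim,
                 paths = paths, thresholds = thresholds, rules = rules,
                 horizon_years = horizon_years, outdir = outdir),
            class = "run_config")
}

.read_weights <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

.read_dosages <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  m
}

.acquire_inputs <- function(config) {
  if (!is.null(config$paths)) {
    list(cohort = read_cohort(config$paths$cohort),
         dosages = .read_dosages(config$paths$dosages),
         weights = .read_weights(config$paths$weights),
         truth = NULL)
  } else {
    generate_cohort(config$sim)
  }
}

.stratify_fun <- function(cond) {
  switch(cond, cad = stratify_cad, t2d = stratify_t2d, htn = stratify_htn)
}
.frs_fun <- function(cond) switch(cond, cad = frs_cad, t2d = frs_t2d,
                                  htn = frs_htn)

.sens_spec_df <- function(counts) {
  ss <- sens_spec(counts)
  ss$point <- as.numeric(ss$point)
  ss
}

# evaluate one condition on its post-exclusion cohort
.evaluate_condition <- function(cond, cohort, dosages, weights, config) {
  df <- as.data.frame(cohort)
  n <- nrow(df)
  D <- dosages[match(df$id, rownames(dosages)), , drop = FALSE]

  raw <- compute_prs(D, weights)
  dec <- bin_deciles(raw)
  covs <- df[, c("age", "sex", "array", paste0("pc", 1:4))]
  adj <- adjust_scores(raw, df[[paste0("event_", cond)]], covs)

  prob <- .frs_fun(cond)(df)
  clinical <- categorize_clinical(prob, cond, sex = df$sex)
  st <- .stratify_fun(cond)(df, clinical, dec$group, config$rules)

  ev <- df[[paste0("event_", cond)]]
  tm <- df[[paste0("time_", cond)]]
  adv_rules <- advised_intervention(st$stratum)
  adv_frs <- clinical == "high"

  seed0 <- config$seed + match(cond, .conditions) * 1000L
  B <- config$bootstrap_B
  rules_score <- as.integer(st$stratum)
  metrics <- list(
    counts_rules = confusion_at_high(adv_rules, ev),
    counts_frs = confusion_at_high(adv_frs, ev),
    auroc_rules = auroc(rules_score, ev, B = B, seed = seed0 + 1L),
    auroc_frs = auroc(prob, ev, B = B, seed = seed0 + 2L),
    auroc_prs = auroc(adj$adjusted, ev, B = B, seed = seed0 + 3L),
    delong_rules_vs_frs = delong_compare(rules_score, prob, ev))
  metrics$sens_spec_rules <- .sens_spec_df(metrics$counts_rules)
  metrics$sens_spec_frs <- .sens_spec_df(metrics$counts_frs)

  reclass <- build_reclassification(adv_frs, adv_rules, ev)
  metrics$nri <- nri(reclass)
  if (cond == "cad") {
    metrics$nri_by_sex <- lapply(stats::setNames(.sex_levels, .sex_levels),
      function(sx) {
        i <- df$sex == sx
        nri(build_reclassification(adv_frs[i], adv_rules[i], ev[i]))
      })
  }

  cox_rules <- tryCatch(
    fit_cox_strata(tm, ev, st$stratum, reference = "NOT_ELEVATED",
                   horizon = config$horizon_years),
    error = function(e) list(table = NULL, note = conditionMessage(e)))
  cox_frs <- tryCatch(
    fit_cox_strata(tm, ev, clinical, reference = "low",
                   horizon = config$horizon_years),
    error = function(e) list(table = NULL, note = conditionMessage(e)))
  prs_hrs <- do.call(rbind, lapply(
    c("top_vs_rest", "top_vs_1to7", "8and9_vs_1to7"),
    function(ct) prs_decile_hrs(tm, ev, dec$decile, contrast = ct)))

  list(
    n = n, events = sum(ev),
    person_years = sum(tm),
    strata_counts = as.list(table(st$stratum)),
    advised_fraction = mean(adv_rules),
    advised_fraction_frs = mean(adv_frs),
    metrics = metrics,
    reclassification = list(events = as.list(reclass$events),
                            nonevents = as.list(reclass$nonevents)),
    cox_rules = cox_rules["table"],
    cox_frs = cox_frs["table"],
    person_years_check = NULL,
    prs_decile_hrs = prs_hrs,
    decile_incidence = decile_incidence(dec$decile, ev, times = tm,
                                        horizon = config$horizon_years),
    strata = st, deciles = dec, clinical = as.character(clinical),
    frs_probability = prob)
}

#' Run the full risk-stratification analysis
#'
#' Executes simulate/ingest -> baseline exclusions -> variant filtering and
#' polygenic scoring -> Framingham scoring and categorisation -> decision
#' rules -> evaluation (confusion counts, sensitivity/specificity, bootstrap
#' AUROC, DeLong comparison, reclassification and NRI, Cox stratum HRs, PRS
#' decile HRs, decile incidence) for each requested condition. With
#' `config$outdir` set, writes `report.json` and per-condition TSV tables.
#'
#' @param config a [run_config()].
#' @return the report: a nested list with one block per condition plus a
#'   manifest. The per-participant intermediates (strata, deciles, clinical
#'   categories) ride along in each block under `strata`, `deciles`,
#'   `clinical`, `frs_probability` and are excluded from report.json.
#' @export
run_analysis <- function(config) {
  stopifnot(inherits(config, "run_config"))
  inputs <- .acquire_inputs(config)
  excl <- apply_baseline_exclusions(inputs$cohort, config$thresholds)
  weights <- filter_variants(inputs$weights, config$min_info)

  report <- list(manifest = list(
    seed = config$seed, conditions = config$conditions,
    bootstrap_B = config$bootstrap_B, min_info = config$min_info,
    n_input = nrow(inputs$cohort),
    n_variants_scored = nrow(weights),
    horizon_years = config$horizon_years,
    package_version = as.character(utils::packageVersion("riskrules"))))
  report$exclusion_summary <- excl$summary[config$conditions]

  for (cond in config$conditions) {
    report[[cond]] <- .evaluate_condition(cond, excl$cohorts[[cond]],
                                          inputs$dosages, weights, config)
  }

  if (!is.null(config$outdir)) .write_report(report, config)
  invisible(report)
}

# strip per-participant vectors before serialising
.report_for_json <- function(report) {
  for (cond in intersect(.conditions, names(report))) {
    report[[cond]][c("strata", "deciles", "clinical", "frs_probability",
                     "person_years_check")] <- NULL
    report[[cond]]$metrics$counts_rules <-
      unclass(report[[cond]]$metrics$counts_rules)
    report[[cond]]$metrics$counts_frs <-
      unclass(report[[cond]]$metrics$counts_frs)
  }
  report
}

.write_report <- function(report, config) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(.report_for_json(report),
                       file.path(config$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       na = "null")
  for (cond in intersect(.conditions, names(report))) {
    blk <- report[[cond]]
    utils::write.table(blk$decile_incidence,
                       file.path(config$outdir,
                                 paste0(cond, "_decile_incidence.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    if (!is.null(blk$cox_rules$table))
      utils::write.table(blk$cox_rules$table,
                         file.path(config$outdir,
                                   paste0(cond, "_stratum_hr.tsv")),
                         sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(blk$prs_decile_hrs,
                       file.path(config$outdir,
                                 paste0(cond, "_prs_decile_hr.tsv")),
                       sep = "\t", row.names = FALSE, quote = FALSE)
  }
  invisible(NULL)
}
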