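# Worked-example count tables from a large prospective UK Biobank
# risk-stratification analysis of the three decision-rules models against
# the Framingham scores (~60,000 participants, ~8.8 years of follow-up).
# They let the evaluation layer be exercised on published-scale numbers
# without access to the underlying individual-level data.

#' Worked-example classification counts
#'
#' Per condition and model (Framingham, PRS deciles, decision rules): the
#' analysis-cohort size and case count, the number classified low risk (and
#' how many of those developed disease), and the number advised lifestyle
#' intervention (and how many of those developed disease). Coronary artery
#' disease Framingham rows are sex-specific; its rules and PRS rows pool both
#' sexes.
#'
#' @return data frame, one row per condition-model.
#' @export
example_classification_counts <- function() {
  utils::read.table(system.file("extdata", "example_classification_counts.tsv",
                                package = "riskrules", mustWork = TRUE),
                    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Worked-example reclassification counts
#'
#' Movement counts between the Framingham classification (old) and the
#' decision-rules classification (new) at the advised-intervention dichotomy,
#' split by event status: `ev_up` events moved from not-advised to advised,
#' `ev_down` the reverse, `ev_same_high`/`ev_same_low` unchanged, and the
#' same four cells for non-events (`ne_*`).
#'
#' @return data frame, one row per condition (CAD split by sex).
#' @seealso [reclassification_table()], [nri()]
#' @export
example_reclassification_counts <- function() {
  utils::read.table(system.file("extdata",
                                "example_reclassification_counts.tsv",
                                package = "riskrules", mustWork = TRUE),
                    sep = "\t", header = TRUE, stringsAsFactors = FALSE)
}

#' Reclassification table for a worked-example condition
#'
#' @param condition one of `"cad_women"`, `"cad_men"`, `"t2d"`, `"htn"`.
#' @return a [reclassification_table()] built from the worked-example counts.
#' @export
example_reclassification_table <- function(condition) {
  tab <- example_reclassification_counts()
  row <- tab[tab$condition == condition, ]
  if (nrow(row) != 1) stop("unknown condition: ", condition)
  reclassification_table(
    up_e = row$ev_up, down_e = row$ev_down, same_high_e = row$ev_same_high,
    same_low_e = row$ev_same_low, up_ne = row$ne_up, down_ne = row$ne_down,
    same_high_ne = row$ne_same_high, same_low_ne = row$ne_same_low)
}

#' Confusion counts for a worked-example condition and model
#'
#' Builds the 2x2 advised-intervention confusion counts from the
#' classification count table: positives are those advised intervention,
#' negatives everyone else in the analysis cohort (the low and elevated
#' groups together).
#'
#' @param condition,model row selector for
#'   [example_classification_counts()].
#' @return a [confusion_counts()] object.
#' @export
example_confusion_counts <- function(condition, model) {
  tab <- example_classification_counts()
  row <- tab[tab$condition == condition & tab$model == model, ]
  if (nrow(row) != 1) stop("unknown condition/model: ", condition, "/", model)
  tp <- row$advised_cases
  fn <- row$cases - row$advised_cases
  fp <- row$advised_n - row$advised_cases
  tn <- (row$cohort_n - row$advised_n) - fn
  confusion_counts(tp = tp, fn = fn, fp = fp, tn = tn)
}
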