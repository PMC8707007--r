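# Discrimination and reclassification statistics at the advised-intervention
# dichotomy: confusion counts, sensitivity/specificity/PPV/NPV, midrank
# AUROC with stratified bootstrap CIs, DeLong comparison of paired ROC
# curves, reclassification tables and the Net Reclassification Index.

#' Confusion counts
#'
#' Constructor for the 2x2 counts at the advised-intervention dichotomy
#' (positive = advised).
#'
#' @param tp,fn,fp,tn non-negative integer counts.
#' @return a `confusion_counts` object.
#' @export
confusion_counts <- function(tp, fn, fp, tn) {
  stopifnot(tp >= 0, fn >= 0, fp >= 0, tn >= 0)
  structure(list(tp = tp, fn = fn, fp = fp, tn = tn, n = tp + fn + fp + tn),
            class = "confusion_counts")
}

#' Confusion counts at the advised-intervention dichotomy
#'
#' @param strata per-participant strata (factor/character; `HIGH` counts as
#'   advised) or a logical advised vector.
#' @param events logical incident-event flags, aligned.
#' @return a [confusion_counts()] object.
#' @export
confusion_at_high <- function(strata, events) {
  if (length(strata) != length(events)) stop("length mismatch")
  advised <- if (is.logical(strata)) strata else advised_intervention(strata)
  events <- as.logical(events)
  confusion_counts(tp = sum(advised & events), fn = sum(!advised & events),
                   fp = sum(advised & !events), tn = sum(!advised & !events))
}

#' @export
print.confusion_counts <- function(x, ...) {
  cat(sprintf("confusion counts (n = %d): tp %d, fn %d, fp %d, tn %d\n",
              x$n, x$tp, x$fn, x$fp, x$tn))
  invisible(x)
}

#' Sensitivity, specificity, PPV and NPV with exact binomial CIs
#'
#' sensitivity = tp/(tp+fn), specificity = tn/(tn+fp), ppv = tp/(tp+fp),
#' npv = tn/(tn+fn). A metric with a zero denominator is returned as `NA`
#' with `defined = FALSE` rather than silently propagated.
#'
#' @param counts a [confusion_counts()] object.
#' @param conf_level confidence level for the Clopper-Pearson intervals.
#' @param floor_zero_cells replace zero cells by 1 before computing ratio
#'   statistics (the convention some reports use so that ratio statistics
#'   stay finite when a classification cell holds no events); default off.
#' @return data frame: `metric`, `point`, `ci_low`, `ci_high`, `numerator`,
#'   `denominator`, `defined`. Values are fractions in \[0, 1\].
#' @export
sens_spec <- function(counts, conf_level = 0.95, floor_zero_cells = FALSE) {
  stopifnot(inherits(counts, "confusion_counts"))
  if (floor_zero_cells) {
    for (cell in c("tp", "fn", "fp", "tn"))
      if (counts[[cell]] == 0) counts[[cell]] <- 1
    counts$n <- counts$tp + counts$fn + counts$fp + counts$tn
  }
  cells <- list(sensitivity = c(counts$tp, counts$tp + counts$fn),
                specificity = c(counts$tn, counts$tn + counts$fp),
                ppv = c(counts$tp, counts$tp + counts$fp),
                npv = c(counts$tn, counts$tn + counts$fn))
  rows <- lapply(names(cells), function(m) {
    x <- cells[[m]][1]; d <- cells[[m]][2]
    if (d == 0)
      return(data.frame(metric = m, point = NA_real_, ci_low = NA_real_,
                        ci_high = NA_real_, numerator = x, denominator = d,
                        defined = FALSE))
    ci <- stats::binom.test(x, d, conf.level = conf_level)$conf.int
    data.frame(metric = m, point = x / d, ci_low = ci[1], ci_high = ci[2],
               numerator = x, denominator = d, defined = TRUE)
  })
  do.call(rbind, rows)
}

# midrank (Mann-Whitney) AUROC point estimate
.auc_point <- function(scores, events) {
  r <- rank(scores, ties.method = "average")
  n1 <- sum(events)
  n0 <- sum(!events)
  (sum(r[events]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' AUROC by the midrank Mann-Whitney statistic with bootstrap CI
#'
#' The rank construction handles heavily tied predictors (e.g. a 3-level
#' ordinal stratum) correctly: ties contribute 1/2 per pair. The CI comes
#' from `B` bootstrap resamples stratified by event status (so no resample is
#' single-class), percentile method; deterministic given `seed`.
#'
#' @param scores numeric or ordinal predictor.
#' @param events logical event flags.
#' @param B bootstrap iterations (default 2000).
#' @param seed integer seed for the resampling.
#' @param ci compute the bootstrap CI (skip for speed with `FALSE`).
#' @param conf_level confidence level.
#' @return list: `point`, `ci_low`, `ci_high`, `se`, `B`, `method`.
#' @export
auroc <- function(scores, events, B = 2000, seed = NULL, ci = TRUE,
                  conf_level = 0.95) {
  events <- as.logical(events)
  if (length(scores) != length(events)) stop("length mismatch")
  if (all(events) || !any(events))
    stop("AUROC needs at least one event and one non-event")
  scores <- as.numeric(scores)
  point <- .auc_point(scores, events)
  out <- list(point = point, ci_low = NA_real_, ci_high = NA_real_,
              se = NA_real_, B = 0L,
              method = "midrank Mann-Whitney; stratified percentile bootstrap")
  if (ci) {
    if (!is.null(seed)) set.seed(as.integer(seed))
    i1 <- which(events)
    i0 <- which(!events)
    boots <- vapply(seq_len(B), function(b) {
      j <- c(sample(i1, replace = TRUE), sample(i0, replace = TRUE))
      .auc_point(scores[j], events[j])
    }, numeric(1))
    alpha <- (1 - conf_level) / 2
    qs <- stats::quantile(boots, c(alpha, 1 - alpha), names = FALSE)
    out$ci_low <- qs[1]; out$ci_high <- qs[2]
    out$se <- stats::sd(boots); out$B <- as.integer(B)
  }
  out
}

# DeLong placement values (Sun-Xu fast computation): V10 for cases, V01 for
# controls.
.delong_placements <- function(scores, events) {
  i1 <- which(events); i0 <- which(!events)
  m <- length(i1); n0 <- length(i0)
  R <- rank(scores, ties.method = "average")
  r1 <- rank(scores[i1], ties.method = "average")
  r0 <- rank(scores[i0], ties.method = "average")
  v10 <- (R[i1] - r1) / n0
  v01 <- 1 - (R[i0] - r0) / m
  list(v10 = v10, v01 = v01, auc = (sum(R[i1]) - m * (m + 1) / 2) / (m * n0))
}

#' DeLong's test for two correlated AUROCs
#'
#' Nonparametric comparison of two predictors measured on the same
#' participants, using the paired DeLong variance of the AUROC difference and
#' a two-sided z test. Identical predictors give difference 0 and p = 1.
#'
#' @param scores_a,scores_b the two predictors, aligned with `events`.
#' @param events logical event flags.
#' @return list: `auc_a`, `auc_b`, `difference`, `se`, `z`, `p_value`.
#' @export
delong_compare <- function(scores_a, scores_b, events) {
  events <- as.logical(events)
  stopifnot(length(scores_a) == length(events),
            length(scores_b) == length(events))
  if (all(events) || !any(events))
    stop("DeLong comparison needs both classes")
  pa <- .delong_placements(as.numeric(scores_a), events)
  pb <- .delong_placements(as.numeric(scores_b), events)
  m <- sum(events); n0 <- sum(!events)
  s10 <- stats::var(pa$v10 - pb$v10)
  s01 <- stats::var(pa$v01 - pb$v01)
  v <- s10 / m + s01 / n0
  diff <- pa$auc - pb$auc
  if (v <= 0) {
    z <- if (diff == 0) 0 else sign(diff) * Inf
  } else {
    z <- diff / sqrt(v)
  }
  list(auc_a = pa$auc, auc_b = pb$auc, difference = diff,
       se = sqrt(max(v, 0)), z = z, p_value = 2 * stats::pnorm(-abs(z)))
}

#' Reclassification table constructor
#'
#' Movement counts between an old and a new classifier at the
#' advised-intervention dichotomy, split by event status. `up` = moved from
#' not-advised to advised under the new model, `down` = the reverse.
#'
#' @param up_e,down_e,same_high_e,same_low_e event-arm cells.
#' @param up_ne,down_ne,same_high_ne,same_low_ne non-event-arm cells.
#' @return a `reclassification_table` object.
#' @export
reclassification_table <- function(up_e, down_e, same_high_e, same_low_e,
                                   up_ne, down_ne, same_high_ne, same_low_ne) {
  structure(list(
    events = c(up = up_e, down = down_e, same_high = same_high_e,
               same_low = same_low_e),
    nonevents = c(up = up_ne, down = down_ne, same_high = same_high_ne,
                  same_low = same_low_ne),
    n_events = up_e + down_e + same_high_e + same_low_e,
    n_nonevents = up_ne + down_ne + same_high_ne + same_low_ne),
    class = "reclassification_table")
}

#' Build a reclassification table from per-participant classifications
#'
#' @param old_advised,new_advised logical advised-intervention flags under
#'   the old (e.g. Framingham) and new (e.g. decision rules) classifier.
#' @param events logical event flags.
#' @return a [reclassification_table()].
#' @export
build_reclassification <- function(old_advised, new_advised, events) {
  if (length(old_advised) != length(events) ||
      length(new_advised) != length(events)) stop("length mismatch")
  events <- as.logical(events)
  cell <- function(ev, old, new) {
    sum(events == ev & old_advised == old & new_advised == new)
  }
  reclassification_table(
    up_e = cell(TRUE, FALSE, TRUE), down_e = cell(TRUE, TRUE, FALSE),
    same_high_e = cell(TRUE, TRUE, TRUE), same_low_e = cell(TRUE, FALSE, FALSE),
    up_ne = cell(FALSE, FALSE, TRUE), down_ne = cell(FALSE, TRUE, FALSE),
    same_high_ne = cell(FALSE, TRUE, TRUE),
    same_low_ne = cell(FALSE, FALSE, FALSE))
}

#' @export
print.reclassification_table <- function(x, ...) {
  cat(sprintf("reclassification: %d events, %d non-events\n",
              x$n_events, x$n_nonevents))
  cat("  events:    ", paste(names(x$events), x$events, collapse = ", "), "\n")
  cat("  non-events:", paste(names(x$nonevents), x$nonevents,
                             collapse = ", "), "\n")
  invisible(x)
}

#' Net Reclassification Index (two-category)
#'
#' `NRI% = 100 * [ (up_e - down_e)/n_events - (up_ne - down_ne)/n_nonevents ]`
#' with the standard asymptotic standard error, Wald CI and two-sided z test.
#'
#' @param table a [reclassification_table()].
#' @param conf_level confidence level.
#' @return list: `point` (percent), `se`, `ci_low`, `ci_high`, `z`,
#'   `p_value`, `method`.
#' @export
nri <- function(table, conf_level = 0.95) {
  stopifnot(inherits(table, "reclassification_table"))
  ne <- table$n_events; nn <- table$n_nonevents
  if (ne == 0 || nn == 0) stop("NRI needs events and non-events")
  ue <- table$events[["up"]]; de <- table$events[["down"]]
  un <- table$nonevents[["up"]]; dn <- table$nonevents[["down"]]
  point <- (ue - de) / ne - (un - dn) / nn
  v <- (ue + de) / ne^2 - (ue - de)^2 / ne^3 +
    (un + dn) / nn^2 - (un - dn)^2 / nn^3
  se <- sqrt(v)
  zq <- stats::qnorm(1 - (1 - conf_level) / 2)
  z <- if (se == 0) 0 else point / se
  list(point = 100 * point, se = 100 * se,
       ci_low = 100 * (point - zq * se), ci_high = 100 * (point + zq * se),
       z = z, p_value = 2 * stats::pnorm(-abs(z)),
       method = "two-category NRI, asymptotic SE")
}
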