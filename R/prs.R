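# Additive polygenic scoring: imputation-quality filtering, dosage-weight
# scoring with allele-frequency imputation of missing dosages, logistic
# covariate adjustment, decile binning, and decile-wise incidence.

#' Filter variants on imputation quality
#'
#' Removes weight-table rows whose imputation-quality (INFO/R^2) score is
#' strictly below `min_info`; the conventional cutpoint 0.4 is the default,
#' so a variant with info exactly 0.4 is kept.
#'
#' @param weights weight table (`variant_id`, `effect_allele`, `weight`,
#'   `allele_freq`, `info`).
#' @param min_info threshold in \[0, 1\].
#' @return the filtered weight table.
#' @export
filter_variants <- function(weights, min_info = 0.4) {
  if (min_info < 0 || min_info > 1) stop("min_info must be in [0, 1]")
  keep <- weights$info >= min_info
  message(sum(!keep), " variant(s) removed at info < ", min_info)
  out <- weights[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Additive polygenic score
#'
#' `score_i = sum_j dosage_ij * weight_j` over the weight-table variants.
#' Missing dosage entries are imputed as `2 * allele_freq` (the expected
#' dosage under Hardy-Weinberg equilibrium). Variants absent from the dosage
#' matrix entirely are imputed the same way when `allele_freq` is available,
#' otherwise scoring fails listing them. Dosage columns are keyed by variant
#' id with the stated effect allele; no allele flipping is attempted.
#'
#' @param dosages participants x variants numeric matrix with variant-id
#'   column names; entries in \[0, 2\].
#' @param weights weight table.
#' @return numeric vector of raw scores, one per matrix row.
#' @export
compute_prs <- function(dosages, weights) {
  if (any(dosages < 0 | dosages > 2, na.rm = TRUE))
    stop("dosages must lie in [0, 2]")
  absent <- setdiff(weights$variant_id, colnames(dosages))
  if (length(absent) > 0) {
    af <- weights$allele_freq[match(absent, weights$variant_id)]
    if (anyNA(af))
      stop("variants absent from dosage matrix with no allele_freq: ",
           paste(absent[is.na(af)], collapse = ", "))
  }
  present <- intersect(weights$variant_id, colnames(dosages))
  D <- dosages[, present, drop = FALSE]
  w <- weights$weight[match(present, weights$variant_id)]
  af <- weights$allele_freq[match(present, weights$variant_id)]
  if (anyNA(D)) {
    for (j in which(colSums(is.na(D)) > 0))
      D[is.na(D[, j]), j] <- 2 * af[j]
  }
  score <- as.vector(D %*% w)
  if (length(absent) > 0) {
    af_abs <- weights$allele_freq[match(absent, weights$variant_id)]
    w_abs <- weights$weight[match(absent, weights$variant_id)]
    score <- score + sum(2 * af_abs * w_abs)
  }
  score
}

#' Covariate adjustment of polygenic scores
#'
#' Fits a logistic regression of the binary outcome on the raw score plus
#' covariates (genotyping array, principal components, age, sex, ...) and
#' returns the fitted per-participant linear predictor as the adjusted score.
#' With `include_prs = FALSE` it fits the covariate-only model (e.g. the
#' age-and-sex-alone comparator). `mode = "residual"` instead returns the
#' residual of the raw score regressed on the covariates.
#'
#' @param raw numeric raw scores.
#' @param outcome logical/0-1 event flags.
#' @param covariates data frame of covariates (complete cases required).
#' @param mode `"logistic"` (linear predictor of the outcome model, default)
#'   or `"residual"`.
#' @param include_prs include the raw score in the logistic model.
#' @return list with `adjusted` (numeric scores) and `model` (the fit).
#' @export
adjust_scores <- function(raw, outcome, covariates,
                          mode = c("logistic", "residual"),
                          include_prs = TRUE) {
  mode <- match.arg(mode)
  if (anyNA(covariates)) stop("covariate matrix must be complete")
  if (mode == "residual") {
    fit <- stats::lm(raw ~ ., data = as.data.frame(covariates))
    return(list(adjusted = as.vector(stats::residuals(fit)), model = fit))
  }
  dat <- data.frame(.y = as.numeric(outcome), covariates)
  if (include_prs) dat$.prs <- raw
  fit <- stats::glm(.y ~ ., data = dat, family = stats::binomial())
  if (!fit$converged)
    stop("logistic adjustment model did not converge")
  if (any(abs(stats::coef(fit)) > 30, na.rm = TRUE))
    stop("logistic adjustment model shows signs of separation")
  list(adjusted = as.vector(stats::predict(fit, type = "link")), model = fit)
}

#' Bin scores into deciles and genetic risk groups
#'
#' Decile 10 holds the highest scores. Ranks use midranks (average rank);
#' a tied block is assigned to the decile of its average rank, so bin sizes
#' differ by at most one plus tie spill. If all scores are equal the ranking
#' is uninformative: everyone is assigned decile 1 with a warning. Groups:
#' `high` = decile 10, `elevated` = deciles 8--9, `reference` = 1--7.
#'
#' @param scores numeric vector, length >= 10.
#' @return data frame with integer `decile` (1--10) and factor `group`.
#' @export
bin_deciles <- function(scores) {
  n <- length(scores)
  if (n < 10) stop("need at least 10 scores to form deciles")
  if (length(unique(scores)) == 1) {
    warning("all scores equal; assigning decile 1 to every participant")
    decile <- rep(1L, n)
  } else {
    decile <- .ntile(scores, 10L)
  }
  group <- ifelse(decile == 10L, "high",
                  ifelse(decile >= 8L, "elevated", "reference"))
  data.frame(decile = decile,
             group = factor(group,
                            levels = c("reference", "elevated", "high")))
}

#' Per-decile incidence
#'
#' Event fraction within each PRS decile. An empty decile is reported as
#' `NA` (undefined), never as zero. With follow-up times supplied, also the
#' Kaplan-Meier cumulative incidence at `horizon` per decile.
#'
#' @param deciles integer decile vector (1--10).
#' @param events logical event flags, aligned with `deciles`.
#' @param times optional follow-up times for the Kaplan-Meier column.
#' @param horizon horizon (years) for the Kaplan-Meier cumulative incidence.
#' @return data frame: `decile`, `n`, `events`, `incidence` (and `km_cuminc`
#'   when `times` is given).
#' @export
decile_incidence <- function(deciles, events, times = NULL, horizon = 8.8) {
  if (length(deciles) != length(events)) stop("length mismatch")
  out <- data.frame(decile = 1:10)
  out$n <- vapply(out$decile, function(d) sum(deciles == d), integer(1))
  out$events <- vapply(out$decile, function(d) sum(events[deciles == d]),
                       integer(1))
  out$incidence <- ifelse(out$n == 0, NA_real_, out$events / out$n)
  if (!is.null(times)) {
    out$km_cuminc <- vapply(out$decile, function(d) {
      i <- deciles == d
      if (!any(i)) return(NA_real_)
      sf <- survival::survfit(survival::Surv(times[i], events[i]) ~ 1)
      s <- summary(sf, times = horizon, extend = TRUE)
      1 - s$surv
    }, numeric(1))
  }
  out
}
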