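# Framingham absolute-risk equations and mapping of their probabilities to
# the three clinical-risk categories used by the decision rules.
#
# Coefficients are vendored as delimited data files under extdata/ so they
# can be audited and swapped without code changes:
#  * frs_cad_wilson1998.tsv -- the sex-specific 10-year coronary heart
#    disease equation with categorical cholesterol, HDL and blood-pressure
#    terms (Wilson et al., Circulation 1998;97:1837-47), risk computed as
#    1 - S0^exp(L - Lmean).
#  * frs_t2d_synthetic.tsv, frs_htn_synthetic.tsv -- logistic incident-risk
#    models over the input sets of the published Framingham Offspring 8-year
#    "simple clinical" diabetes model (Wilson et al., Arch Intern Med 2007)
#    and the Framingham incident-hypertension model (Parikh et al., Ann
#    Intern Med 2008). These two files are SYNTHETIC stand-ins: the published
#    coefficient tables were not available for transcription, so the shipped
#    coefficients were constructed once to give epidemiologically plausible
#    risk levels and gradients over the same inputs. Replace the file to use
#    the published values.

.MGDL_PER_MMOL_CHOL <- 38.67

#' Load a vendored Framingham coefficient table
#'
#' @param condition one of `"cad"`, `"t2d"`, `"htn"`.
#' @param path optional path to an alternative coefficient file with the same
#'   layout, substituted for the vendored one.
#' @return data frame of model terms.
#' @export
frs_coefficients <- function(condition = c("cad", "t2d", "htn"), path = NULL) {
  condition <- match.arg(condition)
  if (is.null(path)) {
    file <- c(cad = "frs_cad_wilson1998.tsv", t2d = "frs_t2d_synthetic.tsv",
              htn = "frs_htn_synthetic.tsv")[[condition]]
    path <- system.file("extdata", file, package = "riskrules",
                        mustWork = TRUE)
  }
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE)
}

.smoker <- function(smoking) smoking %in% c("current", "quit_lt1y")

# JNC-V style blood pressure category; the higher of the SBP/DBP categories
# governs.
.bp_category <- function(sbp, dbp) {
  cat_s <- findInterval(sbp, c(120, 130, 140, 160)) + 1L
  cat_d <- findInterval(dbp, c(80, 85, 90, 100)) + 1L
  c("optimal", "normal", "high_normal", "stage1",
    "stage2plus")[pmax(cat_s, cat_d)]
}

.coef_lookup <- function(coefs, sex, term, level) {
  sel <- coefs$sex == sex & coefs$term == term
  val <- coefs$value[sel][match(level, coefs$level[sel])]
  if (anyNA(val)) stop("no coefficient for ", term, " level(s): ",
                       paste(unique(level[is.na(val)]), collapse = ", "))
  val
}

#' Framingham 10-year coronary heart disease risk
#'
#' Sex-specific categorical equation. Inputs: age (years), sex, total
#' cholesterol and HDL (mmol/L, internally converted to mg/dL for the
#' published category boundaries), SBP/DBP (mmHg), smoking status and
#' baseline diabetes diagnosis (`dx_t2d`; taken as `FALSE` when absent, as it
#' is in cohorts from which diagnosed diabetes was excluded). Treated blood
#' pressure is scored by its measured category; the equation has no separate
#' treatment term. Ages outside the published 30--74 validity range are
#' clamped with a warning.
#'
#' @param profile data frame of participant records (canonical columns).
#' @param coefs coefficient table, see [frs_coefficients()].
#' @return vector of 10-year CHD probabilities in \[0, 1\].
#' @export
frs_cad <- function(profile, coefs = frs_coefficients("cad")) {
  age <- profile$age
  if (any(age < 30 | age > 74, na.rm = TRUE)) {
    warning("age outside 30-74 clamped for the CHD equation")
    age <- pmin(pmax(age, 30), 74)
  }
  tc_mgdl <- profile$total_chol * .MGDL_PER_MMOL_CHOL
  hdl_mgdl <- profile$hdl * .MGDL_PER_MMOL_CHOL
  tc_cat <- c("lt160", "160_199", "200_239", "240_279",
              "ge280")[findInterval(tc_mgdl, c(160, 200, 240, 280)) + 1L]
  hdl_cat <- c("lt35", "35_44", "45_49", "50_59",
               "ge60")[findInterval(hdl_mgdl, c(35, 45, 50, 60)) + 1L]
  bp_cat <- .bp_category(profile$sbp, profile$dbp)
  diabetes <- if ("dx_t2d" %in% names(profile)) profile$dx_t2d %in% TRUE
              else rep(FALSE, nrow(profile))
  smoker <- .smoker(profile$smoking)

  p <- numeric(nrow(profile))
  for (sx in .sex_levels) {
    i <- which(profile$sex == sx)
    if (length(i) == 0) next
    L <- .coef_lookup(coefs, sx, "age", "linear") * age[i] +
      .coef_lookup(coefs, sx, "tc", tc_cat[i]) +
      .coef_lookup(coefs, sx, "hdl", hdl_cat[i]) +
      .coef_lookup(coefs, sx, "bp", bp_cat[i]) +
      .coef_lookup(coefs, sx, "diabetes", "yes") * diabetes[i] +
      .coef_lookup(coefs, sx, "smoker", "yes") * smoker[i]
    if (any(coefs$sex == sx & coefs$term == "age_sq"))
      L <- L + .coef_lookup(coefs, sx, "age_sq", "linear") * age[i]^2
    lmean <- .coef_lookup(coefs, sx, "meta", "lmean")
    s0 <- .coef_lookup(coefs, sx, "meta", "s0_10y")
    p[i] <- 1 - s0^exp(L - lmean)
  }
  pmin(pmax(p, 0), 1)
}

.frs_logistic <- function(profile, coefs, fh_col) {
  cf <- stats::setNames(coefs$value, coefs$term)
  term <- function(name, x) if (name %in% names(cf)) cf[[name]] * x else 0
  lp <- cf[["intercept"]] +
    term("age", profile$age) +
    term("male", as.numeric(profile$sex == "male")) +
    term("parental_history", as.numeric(profile[[fh_col]] >= 1)) +
    term("bmi", profile$bmi) +
    term("fasting_glucose", profile$fasting_glucose) +
    term("sbp", profile$sbp) +
    term("dbp", profile$dbp) +
    term("hdl", profile$hdl) +
    term("triglycerides", profile$triglycerides) +
    term("smoker", as.numeric(.smoker(profile$smoking)))
  stats::plogis(lp)
}

#' Framingham 8-year incident diabetes risk
#'
#' Logistic model over the simple-clinical-model input set: age, sex,
#' parental diabetes history, BMI, blood pressure, HDL, triglycerides and
#' fasting glucose. See the note at the top of this file: the vendored
#' coefficient file is a synthetic stand-in for the published table.
#'
#' @inheritParams frs_cad
#' @return vector of 8-year diabetes probabilities in \[0, 1\].
#' @export
frs_t2d <- function(profile, coefs = frs_coefficients("t2d")) {
  .frs_logistic(profile, coefs, "fh_t2d")
}

#' Framingham incident hypertension risk
#'
#' Logistic model over the published input set: age, sex, SBP, DBP, BMI,
#' smoking and parental hypertension. The vendored coefficient file is a
#' synthetic stand-in for the published table (see file header note).
#'
#' @inheritParams frs_cad
#' @return vector of incident-hypertension probabilities in \[0, 1\].
#' @export
frs_htn <- function(profile, coefs = frs_coefficients("htn")) {
  .frs_logistic(profile, coefs, "fh_htn")
}

.risk_levels <- c("low", "intermediate", "high")

# k-tile by midrank: tied blocks go to the tile of their average rank;
# a block whose average rank sits exactly on a boundary goes to the lower
# tile (ceiling of rank*k/n).
.ntile <- function(x, k) {
  n <- length(x)
  pmin.int(k, pmax.int(1L, as.integer(ceiling(rank(x, ties.method = "average") * k / n))))
}

#' Map Framingham probabilities to clinical-risk categories
#'
#' Diabetes: low < 3%, intermediate 3--8% (boundaries inclusive), high > 8%
#' eight-year risk. Hypertension: low < 5%, intermediate 5--10%, high > 10%.
#' Coronary artery disease: bottom/middle/top tertiles of the analysis
#' cohort, computed within sex (the score is reported sex-specifically);
#' tertile ties are assigned by midrank, boundary ties to the lower tertile.
#'
#' @param probability per-participant risk probabilities on the analysis
#'   cohort.
#' @param condition `"cad"`, `"t2d"` or `"htn"`.
#' @param sex participant sex vector; required for CAD tertiles.
#' @return factor with levels `low < intermediate < high`.
#' @export
categorize_clinical <- function(probability, condition = c("cad", "t2d", "htn"),
                                sex = NULL) {
  condition <- match.arg(condition)
  if (any(probability < 0 | probability > 1, na.rm = TRUE))
    stop("probabilities must be in [0, 1]")
  if (condition == "cad") {
    if (length(probability) == 0) stop("empty cohort: cannot form tertiles")
    if (is.null(sex)) {
      tert <- .ntile(probability, 3L)
    } else {
      tert <- integer(length(probability))
      for (sx in unique(sex)) {
        i <- which(sex == sx)
        tert[i] <- .ntile(probability[i], 3L)
      }
    }
    cat <- .risk_levels[tert]
  } else {
    cuts <- if (condition == "t2d") c(0.03, 0.08) else c(0.05, 0.10)
    cat <- ifelse(probability < cuts[1], "low",
                  ifelse(probability > cuts[2], "high", "intermediate"))
  }
  factor(cat, levels = .risk_levels, ordered = TRUE)
}
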