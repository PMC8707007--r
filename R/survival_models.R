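# Proportional-hazards estimation of stratum effects, PRS decile contrasts,
# and Kaplan-Meier cumulative incidence. Fits delegate to the survival
# package (Efron tie handling); tests guard the delegation with a grid-search
# partial-likelihood oracle.

#' Cox proportional-hazards fit of risk strata
#'
#' Fits `Surv(time, event) ~ stratum` with the chosen reference level as
#' baseline (Efron ties, Wald CIs), and reports per-stratum Kaplan-Meier
#' absolute risk at the horizon and total person-years. A non-reference
#' stratum with zero events is flagged `degenerate` (its HR estimate
#' diverges) rather than silently reported.
#'
#' @param times follow-up times (years).
#' @param events logical event flags.
#' @param strata per-participant stratum labels.
#' @param reference reference stratum label.
#' @param horizon horizon (years) for absolute risk; default the maximum
#'   observed time.
#' @param covariates optional data frame of adjustment covariates.
#' @return list: `table` (stratum, n, events, hr, ci_low, ci_high, p_value,
#'   abs_risk, degenerate), `reference`, `person_years`, `fit`.
#' @export
fit_cox_strata <- function(times, events, strata, reference,
                           horizon = NULL, covariates = NULL) {
  stopifnot(length(times) == length(events),
            length(strata) == length(events))
  strata <- factor(as.character(strata))
  if (!reference %in% levels(strata)) stop("reference stratum not present")
  if (nlevels(droplevels(strata)) < 2) stop("need at least two strata")
  strata <- stats::relevel(strata, ref = reference)
  events <- as.logical(events)
  if (is.null(horizon)) horizon <- max(times)

  dat <- data.frame(.t = times, .e = as.numeric(events), .s = strata)
  form <- survival::Surv(.t, .e) ~ .s
  if (!is.null(covariates)) {
    dat <- cbind(dat, covariates)
    form <- stats::as.formula(paste("survival::Surv(.t, .e) ~ .s +",
                                    paste(names(covariates), collapse = "+")))
  }
  fit <- survival::coxph(form, data = dat, ties = "efron")
  sm <- summary(fit)

  sf <- survival::survfit(survival::Surv(.t, .e) ~ .s, data = dat)
  km <- summary(sf, times = horizon, extend = TRUE)
  km_strata <- sub("^\\.s=", "", as.character(km$strata))
  abs_risk <- stats::setNames(1 - km$surv, km_strata)

  lv <- levels(strata)
  ref_events <- sum(events[strata == reference])
  rows <- lapply(lv, function(s) {
    n_s <- sum(strata == s)
    ev_s <- sum(events[strata == s])
    if (s == reference) {
      hr <- 1; lo <- 1; hi <- 1; p <- NA_real_
    } else {
      nm <- paste0(".s", s)
      hr <- sm$conf.int[nm, "exp(coef)"]
      lo <- sm$conf.int[nm, "lower .95"]
      hi <- sm$conf.int[nm, "upper .95"]
      p <- sm$coefficients[nm, "Pr(>|z|)"]
    }
    data.frame(stratum = s, n = n_s, events = ev_s, hr = hr, ci_low = lo,
               ci_high = hi, p_value = p,
               abs_risk = unname(abs_risk[s]),
               degenerate = s != reference & (ev_s == 0 | ref_events == 0),
               stringsAsFactors = FALSE)
  })
  list(table = do.call(rbind, rows), reference = reference,
       person_years = sum(times), fit = fit)
}

#' Hazard ratios for PRS decile contrasts
#'
#' Contrasts: `top_vs_rest` (decile 10 vs 1--9), `top_vs_1to7` (decile 10 vs
#' the reference group, deciles 8--9 dropped), `8and9_vs_1to7` (elevated
#' group vs reference, decile 10 dropped). Default is a Cox
#' proportional-hazards fit; `mode = "logistic"` returns the odds ratio from
#' a logistic fit instead (some reports quote the decile contrast from a
#' logistic model; the proportional-hazards form is the primary one here).
#'
#' @param times,events follow-up times and event flags.
#' @param deciles integer PRS deciles (1--10).
#' @param contrast one of `"top_vs_rest"`, `"top_vs_1to7"`,
#'   `"8and9_vs_1to7"`.
#' @param covariates optional data frame of adjustment covariates.
#' @param mode `"cox"` (default) or `"logistic"`.
#' @return one-row data frame: `contrast`, `estimate`, `ci_low`, `ci_high`,
#'   `p_value`, `n`, `events`, `mode`.
#' @export
prs_decile_hrs <- function(times, events, deciles,
                           contrast = c("top_vs_rest", "top_vs_1to7",
                                        "8and9_vs_1to7"),
                           covariates = NULL, mode = c("cox", "logistic")) {
  contrast <- match.arg(contrast)
  mode <- match.arg(mode)
  keep <- switch(contrast,
                 top_vs_rest = rep(TRUE, length(deciles)),
                 top_vs_1to7 = deciles == 10 | deciles <= 7,
                 `8and9_vs_1to7` = deciles <= 9)
  g <- switch(contrast,
              top_vs_rest = deciles == 10,
              top_vs_1to7 = deciles == 10,
              `8and9_vs_1to7` = deciles >= 8)
  g <- g[keep]
  if (!any(g) || all(g)) stop("empty contrast group")
  dat <- data.frame(.t = times[keep], .e = as.numeric(events[keep]),
                    .g = as.numeric(g))
  rhs <- ".g"
  if (!is.null(covariates)) {
    dat <- cbind(dat, covariates[keep, , drop = FALSE])
    rhs <- paste(c(".g", names(covariates)), collapse = "+")
  }
  if (mode == "cox") {
    fit <- survival::coxph(
      stats::as.formula(paste("survival::Surv(.t, .e) ~", rhs)),
      data = dat, ties = "efron")
    sm <- summary(fit)
    est <- sm$conf.int[".g", "exp(coef)"]
    lo <- sm$conf.int[".g", "lower .95"]
    hi <- sm$conf.int[".g", "upper .95"]
    p <- sm$coefficients[".g", "Pr(>|z|)"]
  } else {
    fit <- stats::glm(stats::as.formula(paste(".e ~", rhs)), data = dat,
                      family = stats::binomial())
    co <- summary(fit)$coefficients
    est <- exp(co[".g", "Estimate"])
    zq <- stats::qnorm(0.975)
    lo <- exp(co[".g", "Estimate"] - zq * co[".g", "Std. Error"])
    hi <- exp(co[".g", "Estimate"] + zq * co[".g", "Std. Error"])
    p <- co[".g", "Pr(>|z|)"]
  }
  data.frame(contrast = contrast, estimate = est, ci_low = lo, ci_high = hi,
             p_value = p, n = nrow(dat), events = sum(dat$.e), mode = mode,
             stringsAsFactors = FALSE)
}

#' Kaplan-Meier cumulative incidence per group
#'
#' `1 - S(t)` per group with pointwise CIs, in long format ready for export
#' or plotting.
#'
#' @param times,events follow-up times and event flags.
#' @param groups per-participant group labels (all groups non-empty).
#' @param conf_level confidence level.
#' @return data frame: `group`, `time`, `cuminc`, `ci_low`, `ci_high`,
#'   `n_risk`.
#' @export
cumulative_incidence <- function(times, events, groups, conf_level = 0.95) {
  stopifnot(length(times) == length(events), length(groups) == length(events))
  groups <- factor(as.character(groups))
  dat <- data.frame(.t = times, .e = as.numeric(as.logical(events)),
                    .g = groups)
  out <- lapply(levels(groups), function(g) {
    sub <- dat[dat$.g == g, ]
    sf <- survival::survfit(survival::Surv(.t, .e) ~ 1, data = sub,
                            conf.int = conf_level)
    data.frame(group = g, time = c(0, sf$time), cuminc = c(0, 1 - sf$surv),
               ci_low = c(0, 1 - sf$upper), ci_high = c(0, 1 - sf$lower),
               n_risk = c(nrow(sub), sf$n.risk), stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
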