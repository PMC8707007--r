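# Synthetic cohort generator: Table-1-like marginals, a latent metabolic
# factor correlating adiposity/glycaemia/blood pressure, an additive genetic
# liability scored from simulated dosages, and incident events drawn from an
# exponential proportional-hazards model with administrative censoring.

#' Simulation configuration
#'
#' Defaults emulate the baseline marginals of a large UK population cohort of
#' middle-aged adults (mean SBP 138/DBP 82 mmHg, total cholesterol
#' 5.71 mmol/L, BMI 26.8 kg/m2, HbA1c 35.2 mmol/mol, ...) followed for
#' incident coronary artery disease, type 2 diabetes and hypertension over a
#' median 8.8 years. Baseline hazards are per-year rates at the reference
#' (covariate-mean) profile; `log_hr_per_sd_prs` is the log hazard ratio per
#' standard deviation of the polygenic score; `log_hr_coefficients` are
#' per-unit log hazard ratios applied to mean-centered risk factors.
#'
#' @param n_participants cohort size.
#' @param n_variants number of simulated variants.
#' @param seed integer seed; the whole generated object is a deterministic
#'   function of the configuration.
#' @param horizon_years administrative censoring horizon (years).
#' @param allele_freq_range range of simulated effect-allele frequencies.
#' @param baseline_hazard named per-condition baseline event rates
#'   (events/person-year).
#' @param log_hr_per_sd_prs named per-condition log HR per SD of PRS.
#' @param log_hr_coefficients per-condition named lists of per-unit log HRs
#'   for mean-centered risk factors (`male` and `smoking_current` are 0/1).
#' @param biomarkers named list of `c(mean, sd)` marginals.
#' @param dx_prevalence named per-condition baseline-diagnosis prevalence.
#' @param fh_prevalence per-condition probabilities of 0/1/2 affected parents.
#' @return a `sim_config` list.
#' @export
sim_config <- function(n_participants = 40000,
                       n_variants = 1000,
                       seed = 1,
                       horizon_years = 8.8,
                       allele_freq_range = c(0.05, 0.5),
                       baseline_hazard = c(cad = 0.00166, t2d = 0.00289,
                                           htn = 0.00868),
                       log_hr_per_sd_prs = c(cad = 0.78, t2d = 0.55,
                                             htn = 0.33),
                       log_hr_coefficients = list(
                         cad = c(age = 0.055, male = 0.35, total_chol = 0.18,
                                 hdl = -0.5, sbp = 0.012,
                                 smoking_current = 0.55),
                         t2d = c(age = 0.03, bmi = 0.09, fasting_glucose = 0.8,
                                 hba1c_pct = 0.5, fh_t2d = 0.3),
                         htn = c(age = 0.03, sbp = 0.03, dbp = 0.02,
                                 bmi = 0.05)),
                       biomarkers = list(
                         age = c(56.3, 7.59), sbp = c(138, 19), dbp = c(82, 10),
                         total_chol = c(5.71, 1.1), ldl = c(3.58, 0.84),
                         hdl = c(1.47, 0.38), triglycerides = c(1.68, 0.97),
                         hscrp = c(2.17, 3.8), fasting_glucose = c(5.0, 1.0),
                         hba1c_ifcc = c(35.2, 5.3), bmi = c(26.8, 4.35),
                         waist = c(88.7, 12.8), egfr = c(90, 15),
                         acr = c(2.4, 8.3)),
                       dx_prevalence = c(cad = 0.03, t2d = 0.03, htn = 0.12),
                       fh_prevalence = list(
                         cad = c(0.581, 0.418, 0.0007),
                         t2d = c(0.832, 0.168, 0.0001),
                         htn = c(0.573, 0.427, 0.0008))) {
  cfg <- list(n_participants = n_participants, n_variants = n_variants,
              seed = as.integer(seed), horizon_years = horizon_years,
              allele_freq_range = allele_freq_range,
              baseline_hazard = baseline_hazard,
              log_hr_per_sd_prs = log_hr_per_sd_prs,
              log_hr_coefficients = log_hr_coefficients,
              biomarkers = biomarkers, dx_prevalence = dx_prevalence,
              fh_prevalence = fh_prevalence)
  stopifnot(n_participants >= 1, n_variants >= 1, horizon_years > 0,
            all(baseline_hazard > 0),
            all(allele_freq_range > 0), all(allele_freq_range < 1),
            all(names(baseline_hazard) == .conditions))
  class(cfg) <- "sim_config"
  cfg
}

#' Generate a synthetic variant weight table
#'
#' Stands in for a pre-computed (LD-corrected) GWAS weight file: variant ids,
#' effect alleles, mean-zero normal per-allele weights, effect-allele
#' frequencies, and imputation-quality (INFO/R^2) scores in \[0, 1\].
#' Deterministic given the seed.
#'
#' @param n_variants number of variants (>= 1).
#' @param seed integer seed.
#' @param weight_sd standard deviation of per-allele weights.
#' @param allele_freq_range allele-frequency range.
#' @return data frame: `variant_id`, `effect_allele`, `weight`,
#'   `allele_freq`, `info`.
#' @export
generate_weights <- function(n_variants, seed,
                             weight_sd = 0.05,
                             allele_freq_range = c(0.05, 0.5)) {
  if (n_variants < 1) stop("n_variants must be >= 1")
  set.seed(as.integer(seed))
  data.frame(
    variant_id = sprintf("var%06d", seq_len(n_variants)),
    effect_allele = sample(c("A", "C", "G", "T"), n_variants, replace = TRUE),
    weight = stats::rnorm(n_variants, 0, weight_sd),
    allele_freq = stats::runif(n_variants, allele_freq_range[1],
                               allele_freq_range[2]),
    info = stats::rbeta(n_variants, 8, 1.5),
    stringsAsFactors = FALSE
  )
}

# x = mean + sd * (structured part + residual), residual variance chosen so
# the standardized part has unit variance.
.load <- function(n, mean, sd, parts) {
  v <- sum(vapply(parts, function(p) p$loading^2, numeric(1)))
  if (v > 0.95) stop("loadings imply residual variance < 0.05")
  z <- stats::rnorm(n, 0, sqrt(1 - v))
  for (p in parts) z <- z + p$loading * p$z
  list(x = mean + sd * z, z = z)
}

#' Generate a synthetic cohort with genotypes and incident events
#'
#' Dosages are drawn per variant from Binomial(2, allele frequency); the true
#' polygenic score is the dosage-weight dot product. Biomarkers are drawn
#' from the configured marginals with correlation induced by a latent
#' metabolic factor (loading on BMI, triglycerides, glucose, HbA1c and blood
#' pressure) plus age and sex structure; triglycerides, hs-CRP and the
#' albumin-creatinine ratio are log-normal with matching mean and SD. Event
#' times per condition come from an exponential proportional-hazards model
#' with linear predictor `sum(coefficients * centered risk factors) +
#' log_hr_per_sd_prs * standardized PRS`, administratively censored at the
#' horizon. Genotyping array and four genetic principal components are
#' simulated as independent covariates for the adjustment API.
#'
#' @param config a [sim_config()].
#' @return list with elements `cohort` (a validated [as_cohort()] object),
#'   `dosages` (participants x variants matrix), `weights` (see
#'   [generate_weights()]), and `truth` (per-participant true PRS,
#'   standardized PRS and per-condition linear predictors).
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  weights <- generate_weights(config$n_variants, config$seed,
                              allele_freq_range = config$allele_freq_range)
  set.seed(config$seed + 1L)
  n <- config$n_participants
  m <- config$n_variants
  bm <- config$biomarkers

  dosages <- vapply(seq_len(m),
                    function(j) stats::rbinom(n, 2, weights$allele_freq[j]),
                    integer(n))
  if (n == 1) dosages <- matrix(dosages, nrow = 1)
  ids <- sprintf("P%06d", seq_len(n))
  rownames(dosages) <- ids
  colnames(dosages) <- weights$variant_id
  prs_raw <- as.vector(dosages %*% weights$weight)
  prs_sd <- stats::sd(prs_raw)
  prs_z <- if (is.na(prs_sd) || prs_sd == 0) rep(0, n)
           else (prs_raw - mean(prs_raw)) / prs_sd

  female <- stats::rbinom(n, 1, 0.512) == 1
  sex <- ifelse(female, "female", "male")
  sex_z <- (as.numeric(female) - 0.512) / sqrt(0.512 * 0.488)
  M <- stats::rnorm(n)  # latent metabolic factor

  age <- pmin(pmax(stats::rnorm(n, bm$age[1], bm$age[2]), 37), 73)
  age_z <- (age - bm$age[1]) / bm$age[2]

  sbp <- .load(n, bm$sbp[1], bm$sbp[2],
               list(list(loading = 0.25, z = M), list(loading = 0.25, z = age_z)))
  dbp <- .load(n, bm$dbp[1], bm$dbp[2], list(list(loading = 0.55, z = sbp$z)))
  dbp$x <- pmin(dbp$x, sbp$x - 5)  # enforce sbp > dbp
  bmi <- .load(n, bm$bmi[1], bm$bmi[2], list(list(loading = 0.55, z = M)))
  waist <- .load(n, bm$waist[1], bm$waist[2],
                 list(list(loading = 0.7, z = bmi$z)))
  tc <- .load(n, bm$total_chol[1], bm$total_chol[2],
              list(list(loading = 0.15, z = M), list(loading = 0.2, z = age_z)))
  ldl <- .load(n, bm$ldl[1], bm$ldl[2], list(list(loading = 0.85, z = tc$z)))
  hdl <- .load(n, bm$hdl[1], bm$hdl[2],
               list(list(loading = -0.35, z = M), list(loading = 0.2, z = sex_z)))
  glucose <- .load(n, bm$fasting_glucose[1], bm$fasting_glucose[2],
                   list(list(loading = 0.4, z = M), list(loading = 0.15, z = age_z)))
  hba1c_ifcc <- .load(n, bm$hba1c_ifcc[1], bm$hba1c_ifcc[2],
                      list(list(loading = 0.5, z = glucose$z),
                           list(loading = 0.2, z = M)))
  egfr <- .load(n, bm$egfr[1], bm$egfr[2], list(list(loading = -0.3, z = age_z)))

  lnorm_pars <- function(mean, sd) {
    s2 <- log(1 + (sd / mean)^2)
    c(mu = log(mean) - s2 / 2, sigma = sqrt(s2))
  }
  tg_p <- lnorm_pars(bm$triglycerides[1], bm$triglycerides[2])
  tg_z <- 0.45 * M + sqrt(1 - 0.45^2) * stats::rnorm(n)
  triglycerides <- exp(tg_p["mu"] + tg_p["sigma"] * tg_z)
  crp_p <- lnorm_pars(bm$hscrp[1], bm$hscrp[2])
  crp_z <- 0.3 * M + sqrt(1 - 0.09) * stats::rnorm(n)
  hscrp <- exp(crp_p["mu"] + crp_p["sigma"] * crp_z)
  acr_p <- lnorm_pars(bm$acr[1], bm$acr[2])
  acr <- stats::rlnorm(n, acr_p["mu"], acr_p["sigma"])

  smoking <- sample(.smoking_levels, n, replace = TRUE,
                    prob = c(0.941, 0.003, 0.056))
  fh <- lapply(config$fh_prevalence, function(p)
    sample(0:2, n, replace = TRUE, prob = p))
  dx <- lapply(config$dx_prevalence, function(p)
    stats::rbinom(n, 1, p) == 1)

  df <- data.frame(
    id = ids, age = age, sex = sex, sbp = sbp$x, dbp = dbp$x,
    total_chol = pmax(tc$x, 1), ldl = pmax(ldl$x, 0.3), hdl = pmax(hdl$x, 0.3),
    triglycerides = triglycerides, hscrp = hscrp,
    fasting_glucose = pmax(glucose$x, 2.5),
    hba1c_pct = pmin(pmax(hba1c_ngsp_from_ifcc(hba1c_ifcc$x), 3), 20),
    bmi = pmax(bmi$x, 15), waist = pmax(waist$x, 50), smoking = smoking,
    bp_treatment = stats::rbinom(n, 1, 0.02) == 1,
    egfr = pmin(pmax(egfr$x, 15), 150), acr = acr,
    fh_cad = fh$cad, fh_t2d = fh$t2d, fh_htn = fh$htn,
    dx_cad = dx$cad, dx_t2d = dx$t2d, dx_htn = dx$htn,
    array = sample(c("axiom", "bileve"), n, replace = TRUE, prob = c(0.9, 0.1)),
    pc1 = stats::rnorm(n), pc2 = stats::rnorm(n),
    pc3 = stats::rnorm(n), pc4 = stats::rnorm(n),
    stringsAsFactors = FALSE
  )

  center <- function(x) x - mean(x)
  covariate <- function(name) {
    switch(name,
           male = center(as.numeric(df$sex == "male")),
           smoking_current = center(as.numeric(df$smoking == "current")),
           center(df[[name]]))
  }
  truth <- data.frame(id = ids, prs_raw = prs_raw, prs_z = prs_z)
  for (cond in .conditions) {
    coefs <- config$log_hr_coefficients[[cond]]
    lp <- config$log_hr_per_sd_prs[[cond]] * prs_z
    for (v in names(coefs)) lp <- lp + coefs[[v]] * covariate(v)
    rate <- config$baseline_hazard[[cond]] * exp(lp)
    if (any(!is.finite(rate)) || any(rate <= 0))
      stop("configuration implies non-finite or non-positive hazard for ", cond)
    t_event <- stats::rexp(n, rate = rate)
    df[[paste0("event_", cond)]] <- t_event <= config$horizon_years
    df[[paste0("time_", cond)]] <- pmin(t_event, config$horizon_years)
    truth[[paste0("lp_", cond)]] <- lp
  }

  list(cohort = as_cohort(df, source = "synthetic"),
       dosages = dosages, weights = weights, truth = truth)
}
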