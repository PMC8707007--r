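---
title: "Methods: decision-rules risk stratification for CAD, T2D and hypertension"
author: "riskrules"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: decision-rules risk stratification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(riskrules)
```

## The problem and the model

Preventive care needs to separate people who should be referred to medical
care from people who would benefit from lifestyle intervention, and both from
people whose short-term cardiometabolic risk is low. `riskrules` implements
three decision-rules classifiers — for incident coronary artery disease
(CAD), type 2 diabetes (T2D), and hypertension — that map each participant to
one of four ordinal strata:

    NOT_ELEVATED < ELEVATED < HIGH < CLINICAL

`HIGH` is the stratum for which lifestyle intervention is advised; `CLINICAL`
marks participants who have crossed a clinical threshold (e.g. fasting
glucose above 7.0 mmol/L) and are referred to care instead. The classifiers
are deliberately *rules*, not risk regressions: each stratum is the result of
named, auditable clauses over blood biomarkers, physical measurements, a
Framingham risk category, family history, and a polygenic risk score (PRS)
decile group. The model therefore does not output individual probabilities;
its ordinal output is evaluated against conventional scores at the
advised-intervention dichotomy.

The per-condition HIGH clauses (all defaults live in `rule_config()` and are
overridable):

* **CAD** — total cholesterol > 8 mmol/L; SBP > 180 mmHg; LDL > 4.9 mmol/L;
  or (triglycerides > 1.7 mmol/L and/or hs-CRP > 3 mg/L) together with a high
  Framingham category or a high PRS group.
* **T2D** — HbA1c > 6.5% with glucose < 6.1 mmol/L; glucose > 6.1 mmol/L; an
  elevated glycaemic variable (HbA1c 5.5–6.4% or glucose 5.6–6.1 mmol/L)
  with BMI ≥ 25; high clinical risk with unregulated glucose and high genetic
  risk; or intermediate clinical risk with age > 45, HDL < 0.9 mmol/L and
  triglycerides > 2.8 mmol/L.
* **Hypertension** — SBP 130–139 mmHg; DBP 80–89 mmHg; high clinical risk;
  or intermediate clinical risk with a high PRS group.

`NOT_ELEVATED` requires every condition-relevant marker inside its reference
range, a PRS decile below 8, and (for CAD) negative family history or (T2D,
hypertension) low clinical risk. Everything else is `ELEVATED`.

Interval conventions are fixed package-wide: "above x" and "below x" are
strict, bands such as 130–139 are closed, and the reference ranges are
half-open `[lower, upper)`. Because the rule sets are stated verbally in
places, three kinds of thresholds had to be fixed as package defaults and are
explicitly configurable rather than hidden: the triglyceride (1.7 mmol/L) and
hs-CRP (3 mg/L) "out of range" cutpoints, the overweight threshold
(BMI ≥ 25), and the per-condition reference-range tables used by the
not-elevated arm. All are conventional guideline values.

Two genuinely open readings were decided as follows. First, the compound T2D
clause ("clinical risk high, glucose unregulated, genetic susceptibility
high") is read **conjunctively** — one rule with three conditions — because
the disjunctive reading would make every clinically-high participant HIGH and
collapse the clinical-risk gradient; `rule_config(t2d_high_disjunctive =
TRUE)` exposes the alternative. Second, within the CAD engine the clinical
threshold is glucose-only: blood pressure at or past 140/90 mmHg is an
*eligibility* exclusion applied before stratification, and SBP above 180 is
one of the CAD rule set's own HIGH triggers, so re-applying the 140/90
threshold inside the engine would make that trigger unreachable.

## Eligibility

`apply_baseline_exclusions()` forms per-condition analysis cohorts by
removing, in order: incomplete records; participants with a baseline
physician diagnosis of the condition; SBP ≥ 140 or DBP ≥ 90 mmHg; fasting
glucose > 7.0 mmol/L; impaired kidney function. The kidney rule is stated
only by reference to guidelines in the defining analysis, so the default —
eGFR < 60 mL/min/1.73m² or albumin–creatinine ratio > 3 mg/mmol — is a
KDIGO-style substitute and is configurable. Whether the blood-pressure and
glucose thresholds exclude from *all* cohorts or only the matching one is
also not fully determined; the default is global (consistent with framing
the exclusions as "crossed a clinical threshold for any of the conditions"),
switchable via `exclusion_thresholds(clinical_global = FALSE)`.

## Framingham layer

Three absolute-risk equations feed the clinical-risk categories, with
coefficients vendored as delimited files under `extdata/` so they can be
audited or swapped without code changes:

* **CAD**: the sex-specific 10-year coronary heart disease equation with
  categorical cholesterol, HDL and blood-pressure terms (Wilson et al.,
  *Circulation* 1998;97:1837–47), evaluated as `1 − S0^exp(L − Lmean)`.
* **T2D** and **hypertension**: logistic models over the input sets of the
  Framingham Offspring 8-year "simple clinical" diabetes model (Wilson et
  al., *Arch Intern Med* 2007) and the Framingham incident-hypertension model
  (Parikh et al., *Ann Intern Med* 2008). **The shipped coefficient files for
  these two are synthetic stand-ins** (`frs_t2d_synthetic.tsv`,
  `frs_htn_synthetic.tsv`): the published coefficient tables were not
  available for transcription when the package was built, so coefficients
  were constructed once to give epidemiologically plausible risk levels and
  gradients over exactly the published inputs. Anyone with the source papers
  can drop in the published values via `frs_coefficients(path = ...)`.

Categories: T2D low < 3%, intermediate 3–8% (boundaries inclusive, as "<3%,
3 to 8%, >8%" implies), high > 8% eight-year risk; hypertension < 5%, 5–10%,
\> 10%; CAD uses cohort tertiles computed **within sex**, since that score is
built and reported sex-specifically. Tertile and decile ties use midranks: a
tied block goes to the bin of its average rank, boundary ties to the lower
bin — a deterministic rule chosen because ranking ties are the only
non-reproducible degree of freedom in quantile binning.

## Polygenic scores

`compute_prs()` is a plain additive score, `sum(dosage × weight)` over a
weight table that is consumed pre-adjusted for linkage disequilibrium (LD
shrinkage is out of scope). Variants with imputation-quality (INFO/R²) below
0.4 are removed — strictly below, so 0.40 survives. Missing dosages are
imputed as `2 × allele_freq` (Hardy–Weinberg expectation); allele mismatches
are errors, never silent flips. Deciles are computed per analysis cohort,
after exclusions (the alternative — before exclusions — is not what the
decile-specific incidence summaries condition on). Decile 10 is `high` risk,
deciles 8–9 `elevated`, 1–7 the `reference` group; the degenerate all-tied
input collapses to decile 1 with a warning rather than an arbitrary split.

"Adjusted PRS" is operationalised as the linear predictor of a logistic
model of the outcome on the raw score plus covariates (genotyping array,
four principal components, age, sex), because the adjusted score is used for
risk classification downstream; a residual-on-covariates mode
(`adjust_scores(mode = "residual")`) is available for uses where the score
itself must be purged of covariate signal, and the covariate-only
(`include_prs = FALSE`) model provides the age-and-sex comparator.

## Synthetic cohort

`generate_cohort()` exists so every downstream stage is testable without
access-controlled data. It emulates:

* baseline marginals of a middle-aged UK population cohort (age 56.3 ± 7.6,
  51.2% female, SBP 138 ± 19 / DBP 82 ± 10 mmHg, total cholesterol
  5.71 ± 1.1 mmol/L, BMI 26.8 ± 4.35, HbA1c 35.2 ± 5.3 mmol/mol, fasting
  glucose 5.0 ± 1.0 mmol/L, and so on), with triglycerides, hs-CRP and ACR
  log-normal to match their skew;
* a latent "metabolic" factor loading on BMI, triglycerides, glucose, HbA1c
  and blood pressure, plus age and sex structure, so that compound rules
  (e.g. elevated glycaemia *and* overweight) fire on correlated inputs as
  they would in real data;
* family-history prevalences per condition (e.g. 16.8% one-parent diabetes
  history) driving the low-risk arms;
* an additive genetic liability from per-variant Binomial(2, p) dosages
  (1,000 variants by default — scoring is linear, so the published
  hundreds-of-thousands scale adds nothing to correctness);
* incident events from an **exponential** proportional-hazards model,
  administratively censored at 8.8 years. A constant baseline hazard is the
  simplest model consistent with the quantities the analysis reports
  (cumulative incidence at a fixed horizon and hazard ratios); nothing
  downstream assumes a hazard shape.

Default effect sizes were fixed once, before any acceptance measurement, as
follows: baseline hazards are the observed marginal incidence rates of the
motivating cohort (500/300,407, 1,005/347,382 and 2,379/274,009 events per
person-year for CAD, T2D and hypertension); the per-SD PRS log hazard ratios
(0.78, 0.55, 0.33) are backed out of the reported top-decile-versus-rest
hazard ratios (4.6, 2.9, 1.9) through the normal order-statistic gap between
the top decile and the rest (≈1.95 SD); the conventional-risk-factor
coefficients are round, guideline-plausible per-unit values. The generator
does **not** emulate LD between variants, population stratification (the
principal components it emits are independent noise, present only to
exercise the adjustment API), non-proportional hazards, measurement error,
or informative censoring — so green tests demonstrate the *pipeline's*
correctness on data satisfying its assumptions, not robustness to the ways
real cohort data violate them.

## Evaluation layer

* **Confusion counts** are taken at the advised-intervention dichotomy
  (positive = HIGH stratum; CLINICAL is *not* advised, being referred to
  care). Sensitivity/specificity/PPV/NPV carry exact binomial CIs; a zero
  denominator is flagged `defined = FALSE` rather than propagated as NaN,
  and `sens_spec(floor_zero_cells = TRUE)` reproduces the reporting
  convention of flooring empty cells at 1 for ratio statistics.
* **AUROC** uses the midrank Mann–Whitney statistic. This is a deliberate
  choice: the rules model is a 3-level ordinal classifier on the analysis
  cohort, and the rank construction with midranks is the only AUROC
  consistent with such a predictor (ties contribute 1/2). CIs come from
  percentile bootstrap (default B = 2000) stratified by event status so no
  resample is single-class; the seed is mandatory wherever resampling
  happens.
* **DeLong's test** compares two predictors on the same participants via the
  paired placement-value variance; identical predictors return difference 0
  and p = 1 by convention.
* **NRI** is the two-category version at the advice dichotomy,
  `100 × [(up_e − down_e)/n_e − (up_ne − down_ne)/n_ne]`, with the standard
  asymptotic SE and Wald CI. The asymptotic (not bootstrap) interval is the
  default because it exactly reproduces the worked-example intervals the
  package ships (e.g. hypertension 19.9, CI 18.1–21.8).
* **Survival**: Cox proportional-hazards fits with Efron tie handling
  (appropriate for the heavy ties that coarse-resolution data produce) and
  the not-elevated/low stratum as reference; Kaplan–Meier absolute risk at
  the horizon per stratum; person-years as the sum of follow-up. Stratum
  hazard ratios are unadjusted by default (the stratum *is* the exposure of
  interest); a covariate list is accepted. PRS decile contrasts
  (top-vs-rest, top-vs-deciles-1–7, 8&9-vs-1–7) default to proportional
  hazards, with a logistic odds-ratio mode because decile contrasts are
  sometimes quoted from logistic fits; the two do not coincide and the mode
  is always recorded in the output. The Cox fit itself delegates to the
  `survival` package; a grid-search partial-likelihood oracle in the test
  suite guards the delegation.

## Problem sizes, tolerances and seeds

The analysis scripts and the acceptance script run the pipeline at
n = 20,000 participants × 500 variants with B = 200 bootstrap iterations —
sizes chosen so a complete desk run takes well under a minute while keeping
Monte-Carlo error far below every tolerance used. Parameter-recovery checks
use 50 seeded replicates at n = 1,200–6,000 and require ≥ 90% CI coverage of
the simulation truth; the zero-effect closed form `1 − exp(−h·t)` is checked
within 3.5 binomial standard errors at n = 20,000. Dual-implementation
equalities (score equations, ML fits) are asserted at 1e-10 and 1e-6
respectively; the grid-search Cox oracle at 1e-3. Every stochastic stage
takes an explicit integer seed, and identical configuration plus seed
reproduces reports byte-for-byte.

## Known limitations

* The T2D and hypertension Framingham coefficient files are labelled
  synthetic stand-ins (above); absolute risks from those two scores are
  plausible but not the published calibrations, so downstream *categories*
  (which are what the rules consume) are meaningful while the probabilities
  themselves should not be quoted.
* The rules engines require complete inputs by design — eligibility is the
  single place missingness is handled — so they fail loudly on NA rather
  than guessing.
* The generator's independence assumptions (no LD, independent PCs) mean
  covariate-adjustment code paths are exercised but confounding-removal
  performance on structured genotypes is not demonstrated.
* No competing risks, time-varying covariates, or recalibration of the
  Framingham equations to the target population.
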