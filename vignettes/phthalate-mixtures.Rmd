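---
title: "Phthalate mixtures and time to delivery: models, risk scores and the synthetic cohort"
author: "phthalmix"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phthalate mixtures and time to delivery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem

Urinary phthalate metabolites are short-lived biomarkers of exposure to
plasticizers that have repeatedly been associated with earlier delivery.
Treating delivery as a time-to-event outcome, rather than only a preterm
(< 259 days, i.e. < 37 weeks) indicator, uses the whole gestational-age
distribution; treating the nine routinely measured metabolites jointly,
rather than one at a time, addresses the fact that exposure is to a mixture.
`phthalmix` implements this analysis framework end to end: exposure
processing, two summative mixture scores (an environmental risk score, ERS,
and a weighted quantile sum, WQS), a two-stage mixed-model treatment of
repeated exposure measurements, and design-weighted logistic, Cox and
accelerated-failure-time (AFT) outcome models. Because cohorts of this kind
are not publicly deposited, the package ships a synthetic cohort generator
that reproduces the *structure* of such data — it is first-class, tested
code, and every simulation experiment in the package runs on it.

## Exposure processing

Concentrations below the assay limit of detection are flagged at censoring
time and substituted by LOD/√2 at analysis time, the standard convention
when non-detect fractions are low (a few percent here). Urinary dilution is
handled two ways, deliberately kept apart:

* descriptively, concentrations are specific-gravity corrected,
  `P_C = P (M_SG − 1)/(SG − 1)` with `M_SG = 1.015`, and the Pearson
  correlation matrix of mean SG-corrected log concentrations is reported;
* in regression, *raw* concentrations are used and SG enters as a
  covariate, because regressing on dilution-corrected values can bias
  exposure coefficients.

The four DEHP metabolites (MEHP, MEHHP, MEOHP, MECPP) are additionally
summed on the molar scale (µg/L × 1000 / MW, in nmol/L) as an index of
exposure to the parent compound. The package logs the per-visit molar sum
and then averages across visits, mirroring the single-metabolite handling;
whether the sum should be averaged before or after the log is not settled,
so the choice is isolated in one place and documented here.

The average-exposure arm summarises each subject by the mean of the visit
1–3 natural-log concentrations. Visit 4 is excluded from averages because
women who deliver early are less likely to have one — its availability is
informative. All model coefficients are reported per interquartile range
(IQR) of the exposure summary: the IQR is `Q3 − Q1` under the type-7
(linear-interpolation) quantile rule, computed on the analysis sample
without design weights by default (coefficients then read "per sample IQR";
a weighted IQR is available via `analysis_config(weighted_iqr = TRUE)`).

## Outcome models

Three models are fitted per exposure, all inverse-probability weighted by
the case-control design weights:

* logistic regression of the preterm indicator — odds ratio per IQR;
* Cox proportional hazards for time to delivery in days. Every pregnancy
  ends in delivery, so there is no censoring and a hazard ratio above one
  means *shorter* gestation. Ties are handled by the Efron method because
  day-scale delivery times are heavily tied;
* lognormal AFT, which with no censoring reduces to normal regression of
  `log(T)`; the coefficient is reported as `100(exp(γ) − 1)`, the percent
  change in gestational age per IQR, negative meaning shorter gestation.

Robust (sandwich) standard errors are the default for all three — required
for valid inference under design weighting — with model-based standard
errors retained alongside. Confidence limits are computed on the
coefficient scale and transformed (the maps are monotone). Categorical
covariates are reference-coded against their most frequent level. The
standard covariate set follows the analysis plan: average SG, maternal age,
race and education for the average-exposure single-pollutant models, with
insurance added for MBzP/MBP/MiBP/MEP/MCPP and for all risk-score models;
the repeated-measures stage-2 models adjust for maternal age, race,
education (and insurance per the same rule), SG having been absorbed in
stage 1.

## Summative risk scores

Two subset-selection routes defuse the multicollinearity of the nine
metabolites:

* **correlation screen** (`-corr`): exposures are greedily grouped into
  blocks whose pairwise |r| exceeds 0.5 in the descriptive SG-corrected
  correlation matrix; within a block only the member with the strongest
  single-pollutant Cox association (largest |z|) is retained. The molar
  DEHP sum participates in block formation (it is collinear with its
  components) but is never itself retained as a mixture component.
* **stepwise** (`-stepwise`): bidirectional AIC stepwise on the IPW
  logistic model, adjustment covariates forced in, metabolites free.
  Neither the selection criterion nor the search direction is canonical for
  this step; AIC/bidirectional is the package's documented default, chosen
  for determinism and comparability. Exposures showing
  near-separation are dropped with a warning before selection.

**ERS** weights are the coefficients of one *joint* IPW logistic model of
preterm birth on the selected subset plus covariates. A joint fit avoids
double-counting correlated metabolites; using single-pollutant coefficients
instead is a documented alternative. The score `RS_i = Σ w_k x_ik` is then
IQR-standardized like any exposure.

**WQS** quantile-scores each selected exposure into quartiles (scores
0–3, cutpoints at type-7 sample quantiles, ties to the lower category) and
estimates non-negative weights summing to one by bootstrap: on each of
`B = 100` resamples the IPW logistic likelihood of
`β0 + β1 Σ w_k q_ik + Z'φ` is maximized subject to `w ≥ 0`, `Σw = 1` and
`β1 ≥ 0` (the direction of harm: higher odds of preterm birth). Weights are
parameterized by a softmax, so the simplex constraint holds exactly, and the
likelihood is maximized by L-BFGS-B with an analytic gradient; covariates
are standardized internally for conditioning (the index coefficient and
weights are invariant to that). Final weights average the converged
resamples with `β1 > 0` — if none qualify, all converged resamples are
averaged with a warning — and `β1` is re-estimated on the full data with
the weights fixed. There is no training/validation split by default: at a
few hundred subjects a split costs more in weight stability than it buys in
optimism control; a split remains a reasonable variant for larger samples.

Quartile analyses categorize each standardized score at its IPW-weighted
25/50/75th percentiles (computed so that integer design weights reproduce
the quantiles of the weight-expanded sample) and contrast Q2–Q4 against Q1
in all three models.

## Repeated measures: the two-stage path

Stage 1 fits, per exposure, a random-intercept linear mixed model to the
visit 1–4 log concentrations with fixed effects for gestational week at
sampling and visit-specific SG, by REML (unbiased variance components; the
likelihood route falls back to a method-of-moments ANOVA estimator with a
warning if it fails). The BLUP of the subject intercept is a shrinkage
estimate of the subject's average deviation — subjects with fewer visits
are shrunk harder — and all four visits contribute, which is exactly why
this path handles unbalanced visit schedules more gracefully than the plain
average. Stage 2 regresses the outcome on the IQR-standardized BLUPs.
Gestational week enters stage 1 in weeks, uncentered; only the intercept
BLUPs are consumed downstream, so centering would not change them.

Because the BLUP is a noisier summary of exposure than the three-visit
mean (it is built from residual-contaminated data and then shrunk),
stage-2 coefficients are expected to be attenuated and more variable than
their average-exposure counterparts — the package's tests assert both the
variance inflation and the attenuation on shared cohorts.

The per-visit ERS follows the same path: the average-analysis selection and
weights are applied to visit-specific log concentrations (scaled by the
average-analysis IQRs), giving a per-visit score that feeds the same LMM.
Whether the weights should instead be refit per visit is not settled; fixed
weights keep the repeated and average scores on the same scale. WQS is
excluded from this arm by construction — the stage-1 response must be
continuous and the quantile-sum index is inherently discrete — and
requesting it is a configuration error.

## The synthetic cohort generator

The generator is parameterized by `sim_truth()` and emulates, feature by
feature, the data structure the analysis assumes:

* **Exposures.** `log X_ijk = b_ik + d_ij + e_ijk`: subject intercepts
  `b_ik` are multivariate normal with a strongly correlated DEHP block
  (between-subject r = 0.9 inside the block, 0.25 elsewhere); `d_ij =
  log((SG_ij − 1)/0.015)` is a physical dilution term shared by all
  metabolites in a sample; `e_ijk` is visit noise, itself correlated inside
  the DEHP block (r = 0.8) because metabolites of one parent compound rise
  and fall together within a urine void. Without the correlated noise the
  *observed* visit-averaged concentrations could not show the > 0.5 block
  correlations the screen relies on while keeping ICCs in the reported
  0.19–0.61 range. The visit-noise variance is set to
  `σ_b²(1/ICC − 1) − Var(d)` (the dilution variance has a closed form under
  the uniform SG law), so the generated between/(between+within) ratio
  equals the configured ICC exactly.
* **Visits.** Median gestational weeks 9.71 / 17.9 / 26.0 / 35.1 with
  uniform jitter approximating the reported ranges. Attrition removes any
  visit at or after delivery (the structural mechanism that depletes visit
  4 among preterm births) plus independent random missingness (defaults
  0/10/12/8% for visits 1–4); visit 1 is never removed at random because
  enrolment requires it.
* **Detection limits.** Default LODs sit at the quantile of each marginal
  lognormal law matching target non-detect fractions — 4.7% for MEHP, 1%
  for the rest — reflecting the high detection rates of these assays.
  Values exactly at the LOD count as detected (strict inequality censors).
* **Outcome.** Two modes. `aft_lognormal` draws `log T` from the linear
  model in the realized visit 1–3 mean log exposures, so the fitted AFT *is*
  the generative model — the mode used for parameter recovery and coverage
  experiments. `term_preterm_mixture` (default) draws an early-delivery
  indicator from a logistic model in the same exposure summaries, with the
  intercept solved at generation time so the marginal preterm fraction hits
  its target (0.110 = 130/1181 by default; no hand-tuned constant), then
  term deliveries from a normal component (mean 277 d, sd 8 d, truncated to
  [259, 295]) and early deliveries from `259 − (1 + 34·Beta(1.2, 2.2))`
  days, rounded to whole days. The marginal distribution is left-skewed
  with a realistic preterm tail; day-scale ties are what the Efron method
  is for.
* **Design.** All preterm deliveries are cases (weight 1); controls are
  drawn uniformly from non-cases with a visit-1 sample and at least one
  later visit, each carrying weight `n_eligible / n_controls`; with the
  printed counts (130 cases, 1051 eligible non-cases, 352 controls) the
  control weight is 1051/352 ≈ 2.986. Controls are drawn after outcomes are
  known, matching a nested design assembled at the end of follow-up.

What the generator does *not* emulate — and hence what green tests do not
establish about real data: dietary and temporal sources of exposure,
gestational-age measurement error (LMP vs ultrasound), multiple births,
confounding structures beyond the modelled covariates, and the real
cohort's effect sizes, which are not recoverable from the publication. The
generator's covariate effects are small and conventional; they exist so
adjustment does something, not to reproduce any particular cohort.

## Numerical choices and degenerate inputs

* Type-7 quantiles everywhere (IQRs, quantile scoring, quartile
  cutpoints), ties at a cutpoint to the lower category; both configurable.
* IQR standardization divides without centering, so effect estimates are
  per-IQR contrasts; a zero IQR is an error, as is a constant exposure in
  quantile scoring.
* A constant exposure in the Cox model returns a zero log-hazard by
  convention (flat partial likelihood) rather than a singular fit.
* If stepwise selection retains a single metabolite, WQS on that subset
  degenerates to the metabolite's own quantile score with weight one; the
  pipeline does this with a warning rather than failing the run.
* Perfect collinearity in the ERS generating model is reported as a
  rank-deficiency error; near-separation in logistic fits is warned about
  (|coefficient| > 15 on a standardized exposure).
* The WQS optimizer treats `β1 = 0` (within 1e−8) as a non-positive
  resample when aggregating weights.

## Validation problem sizes

The test suite validates the pipeline at sizes chosen to make Monte-Carlo
error small relative to the assertions: cohorts of n = 2000 with 500
replicates for AFT/logistic recovery and coverage (bias within 2 MC SE,
coverage within [93%, 97%]), 200 replicates for the case-control IPW
comparison and the ERS amplification property, 100 replicates for WQS
dominant-weight identification, and 40 shared-cohort replicates for the
average-vs-repeated attenuation check. `scripts/acceptance.R` re-runs a
scaled version of the same experiments from scratch and writes the
resulting quantities as JSON.

## Known limitations

ERS is estimated and applied on the same data, so its association estimates
carry optimism; validating the score in an independent sample is the
correct use. WQS weight identification degrades under strong
within-subset collinearity (the screen exists to prevent exactly that).
The lognormal AFT models a left-skewed outcome through a symmetric error on
the log scale; percent-change estimates are therefore sensitive to the
shortest gestations. LOD/√2 substitution is adequate at the low non-detect
fractions generated here but biases coefficients when non-detects are
common; censored-likelihood or imputation approaches are out of scope.
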