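# phthalmix

Phthalate mixtures and time to delivery: summative risk scores, repeated
exposure measures and survival models for pregnancy cohorts.

## What this package is for

Pregnant women are exposed to mixtures of phthalate plasticizers, measured
as nine urinary metabolites at up to four prenatal visits. Higher exposure
has been associated with earlier delivery. `phthalmix` implements a complete
analysis framework for this question, treating gestational age at delivery
as a time-to-event outcome rather than only a preterm/term dichotomy:

* **Exposure processing** — LOD/√2 substitution for non-detects,
  specific-gravity dilution correction (`P_C = P(M_SG − 1)/(SG − 1)`,
  `M_SG = 1.015`; descriptive use only — regressions use raw levels with SG
  as a covariate), molar summation of the four DEHP metabolites (nmol/L),
  averaging of visit 1–3 log concentrations, IQR standardization.
* **Outcome models** — inverse-probability-weighted logistic regression of
  preterm birth (`logit(π_i) = β0 + β1 X̄_i + Z_i'β2`), Cox proportional
  hazards for time to delivery (`λ(t) = λ0(t) exp(α1 X̄_i + Z_i'α2)`, Efron
  ties, HR > 1 ⇒ shorter gestation), and the lognormal accelerated failure
  time model (`log T_i = γ0 + γ1 X̄_i + Z_i'γ2 + σε_i`), reported as
  `100(exp(γ1) − 1)`, the percent change in gestational age per IQR. Robust
  sandwich variances throughout.
* **Summative risk scores** — the environmental risk score
  (`ERS_i = Σ_k w_k x_ik`, weights from one joint IPW logistic model) and
  the weighted quantile sum (`WQS_i = Σ_k w_k q_ik`, non-negative weights
  summing to one, estimated by bootstrap under a `β1 ≥ 0` constraint), each
  built on two subsets: a correlation screen (one representative per block
  of pairwise |r| > 0.5) and stepwise logistic selection. Continuous and
  quartile-contrast fits.
* **Repeated measures** — a two-stage path: random-intercept linear mixed
  model per exposure (`x_ij = b_0i + φ0 + φ1 T_ij + φ2 SG_ij + ε_ij`),
  then outcome models on the IQR-standardized BLUPs `b̂*_0i`.
* **A synthetic cohort generator** — correlated lognormal exposures with
  configurable ICC, a shared urinary-dilution term, visit attrition,
  left-skewed gestational age with ≈ 11% preterm, and nested case-control
  sampling with design weights. All simulation experiments run on it.

## Worked example

```r
library(phthalmix)

truth <- sim_truth(n_subjects = 1181, seed = 7)   # study-sized cohort
study <- simulate_study(truth)                    # attrition, LOD, sampling
print(study)
#> Synthetic pregnancy cohort: 1181 subjects, 4322 visit records
#>   preterm: 146 (12.4%)   sampled: 498 (cases 146, controls 352)

cfg <- analysis_config(seed = 7, B = 100)
avg <- run_average_analysis(study, cfg)
avg$selection
#> $corr
#> [1] "meohp" "mbzp"  "mbp"   "mibp"  "mep"   "mcpp"
#> $stepwise
#> [1] "meohp" "mbp"   "mibp"

subset(avg$effects, scale == "per_IQR" &
         exposure %in% c("mecpp", "sum_dehp", "ers_corr", "wqs_corr"))[,
       c("exposure", "model", "effect", "ci_low", "ci_high")]
#>  exposure    model effect ci_low ci_high
#>     mecpp logistic  1.671  1.259   2.217
#>     mecpp      cox  1.043  0.924   1.176
#>     mecpp      aft -0.663 -1.134  -0.191
#>  sum_dehp logistic  1.758  1.293   2.390
#>  sum_dehp      cox  1.068  0.939   1.216
#>  sum_dehp      aft -0.773 -1.269  -0.275
#>  ers_corr logistic  2.084  1.551   2.800
#>  ers_corr      cox  1.151  1.010   1.312
#>  ers_corr      aft -1.038 -1.524  -0.549
#>  wqs_corr logistic  2.097  1.490   2.951
#>  wqs_corr      cox  1.152  0.977   1.357
#>  wqs_corr      aft -1.052 -1.616  -0.486
```

Reading the numbers: per IQR of mean log MECPP this cohort shows 1.67-fold
odds of preterm birth and a 0.66% shorter gestation; the mixture scores
amplify the association (ERS: 2.08-fold odds, 1.04% shorter gestation, and
a delivery hazard ratio of 1.15 — above every single-pollutant HR), the
qualitative signature of aggregate exposure summaries. On this seed the
correlation screen kept MEOHP as the DEHP-block representative; which block
member wins varies across simulated cohorts.

The repeated-measures arm is run the same way
(`run_repeated_analysis(study, cfg, average = avg)`); its estimates are
attenuated relative to the average-exposure arm because BLUPs are noisier
exposure summaries.

## The analysis workflow

Numbered drivers under `analysis/` reproduce the whole study on a simulated
cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate.R        # cohort CSVs + generator parameters
Rscript analysis/02_exposures.R       # exposure summaries, IQRs, correlations
Rscript analysis/03_average_analysis.R
Rscript analysis/04_repeated_analysis.R
Rscript analysis/05_report.R          # combined effects.tsv, weights.json, ...
```

## Package layout

```
R/                   exposure processing, outcome models, risk scores,
                     mixed-model stage, cohort generator, pipeline
analysis/            numbered workflow drivers (simulate → report)
scripts/acceptance.R headline-quantity reproduction script
tests/testthat/      unit, property and acceptance tests
vignettes/           methods vignette (models, assumptions, design choices)
```
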