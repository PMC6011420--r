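# Helpers for recovery/structure experiments shared by the acceptance tests.

# Per-subject mean of visit log concentrations, aligned to the subject table.
subject_mean_log <- function(coh, met = "mecpp", visits = 1:3) {
  v <- coh$visits[coh$visits$visit %in% visits, ]
  m <- tapply(log(v[[met]]), v$subject_id, mean)
  as.numeric(m[match(coh$subjects$subject_id, as.integer(names(m)))])
}

subject_covariates <- function(coh) {
  coh$subjects[, c("maternal_age", "race", "education", "insurance")]
}

# Ground truth with a single active exposure (MECPP), used for clean
# single-pollutant parameter recovery.
recovery_truth <- function(mode, effect, n = 2000, seed = 1) {
  g <- setNames(rep(0, 9), phthalate_metabolites())
  p <- g
  if (mode == "aft_lognormal") g["mecpp"] <- effect else p["mecpp"] <- effect
  sim_truth(n_subjects = n, outcome_mode = mode, gamma_true = g,
            preterm_logit_effects = p, seed = seed)
}
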