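#' Ground-truth configuration for the synthetic pregnancy cohort
#'
#' Bundles every parameter of the synthetic cohort generator: the nine urinary
#' phthalate metabolites and their joint lognormal law, the within-subject
#' visit structure, the urinary dilution (specific gravity) model, the
#' gestational-age outcome model, and assay detection limits.
#'
#' The exposure model decomposes each log concentration as
#' `log X_ijk = b_ik + d_ij + e_ijk`, where `b_ik` is a subject-level
#' intercept with between-subject covariance `cov_log`, `d_ij =
#' log((SG_ij - 1)/(sg_center - 1))` is a physical urinary dilution term
#' shared by all metabolites in a sample, and `e_ijk` is independent visit
#' noise. The visit-noise variance for metabolite `k` is chosen so that the
#' between/(between + within) variance ratio of the generated log
#' concentrations equals `icc[k]` exactly: `var(e) =
#' diag(cov_log)[k] * (1/icc[k] - 1) - var(d)`, with `var(d)` evaluated in
#' closed form under the uniform specific-gravity law.
#'
#' Two outcome modes are available. `"aft_lognormal"` draws
#' `log(T_i) = gamma0 + sum_k gamma_true[k] * xbar_ik + Z_i' theta + sigma_log_T * eps`
#' where `xbar_ik` is the realized mean of the visit 1-3 log concentrations,
#' so the lognormal accelerated-failure-time model fitted downstream is the
#' generative model exactly (parameter-recovery ground truth).
#' `"term_preterm_mixture"` (the default) draws an early-delivery indicator
#' from a logistic model in `xbar_ik` (coefficients
#' `preterm_logit_effects`) whose intercept is solved at generation time so
#' the marginal early fraction equals `preterm_target`, then draws term
#' deliveries from a normal component (mean 277 d, sd 8 d, truncated to
#' [259, 295]) and early deliveries from `259 - (1 + 34 * Beta(1.2, 2.2))`
#' days, reproducing the left-skewed gestational-age distribution with a
#' realistic preterm fraction.
#'
#' Default detection limits are defined through target non-detect fractions
#' on the marginal lognormal scale (4.7% for MEHP, 1% for the others), so the
#' generated non-detect rates match what sensitive assays achieve.
#'
#' @param n_subjects number of women followed to delivery.
#' @param mu_log per-metabolite log-scale means of concentration (log µg/L).
#' @param cor_between between-subject correlation matrix of log
#'   concentrations (the four DEHP metabolites form a strongly correlated
#'   block by default).
#' @param cor_within correlation matrix of the within-visit noise. Metabolites
#'   of a common parent compound rise and fall together within a urine
#'   sample, so the DEHP block is strongly correlated here too (0.8 by
#'   default); without this the observed visit-averaged concentrations would
#'   not reproduce the strong pairwise correlations such cohorts show.
#' @param sd_log_total per-metabolite total (between + within) log-scale SD.
#' @param icc per-metabolite intraclass correlation in (0, 1).
#' @param visit_weeks median gestational week of each of the four visits.
#' @param visit_jitter half-width (weeks) of the uniform jitter around each
#'   visit median.
#' @param sg_center median specific gravity (also the reference `M_SG` used
#'   by [sg_correct()]).
#' @param sg_spread half-width of the uniform specific-gravity law.
#' @param outcome_mode `"term_preterm_mixture"` or `"aft_lognormal"`.
#' @param gamma_true per-metabolite log-time coefficients (per unit log
#'   exposure), used by the `aft_lognormal` mode.
#' @param preterm_logit_effects per-metabolite log-odds coefficients for the
#'   early-delivery component of the mixture mode.
#' @param preterm_target marginal early-delivery fraction the mixture mode
#'   calibrates to (default 0.110, i.e. 130/1181).
#' @param gamma0 intercept of the log gestational-age model (log days).
#' @param sigma_log_T residual SD of log gestational age (aft mode).
#' @param covariate_effects list with numeric vectors `log_time` and
#'   `preterm_logit`, named by covariate design columns (see Details).
#' @param lod per-metabolite detection limit in µg/L; `NULL` derives limits
#'   from `nondetect_target`.
#' @param nondetect_target per-metabolite target non-detect fraction used
#'   when `lod` is `NULL`.
#' @param seed integer seed; the generator is fully reproducible given the
#'   truth object.
#' @return an object of class `sim_truth`.
#' @export
sim_truth <- function(n_subjects = 1181,
                      mu_log = NULL,
                      cor_between = NULL,
                      cor_within = NULL,
                      sd_log_total = NULL,
                      icc = NULL,
                      visit_weeks = c(9.71, 17.9, 26.0, 35.1),
                      visit_jitter = c(2.5, 1.5, 1.6, 1.3),
                      sg_center = 1.015,
                      sg_spread = 0.008,
                      outcome_mode = c("term_preterm_mixture", "aft_lognormal"),
                      gamma_true = NULL,
                      preterm_logit_effects = NULL,
                      preterm_target = 130 / 1181,
                      gamma0 = log(277),
                      sigma_log_T = 0.03,
                      covariate_effects = NULL,
                      lod = NULL,
                      nondetect_target = NULL,
                      seed = 1L) {
  mets <- phthalate_metabolites()
  K <- length(mets)
  outcome_mode <- match.arg(outcome_mode)

  if (is.null(mu_log)) {
    gm <- c(mehp = 5, mehhp = 20, meohp = 14, mecpp = 30, mbzp = 7,
            mbp = 15, mibp = 7, mep = 100, mcpp = 2)
    mu_log <- log(gm)
  }
  mu_log <- stats::setNames(rep_len(mu_log, K), mets)

  if (is.null(icc)) {
    icc <- c(mehp = 0.25, mehhp = 0.21, meohp = 0.23, mecpp = 0.30,
             mbzp = 0.45, mbp = 0.40, mibp = 0.50, mep = 0.61, mcpp = 0.35)
  }
  icc <- stats::setNames(rep_len(icc, K), mets)

  if (is.null(sd_log_total)) sd_log_total <- rep(1, K)
  sd_log_total <- stats::setNames(rep_len(sd_log_total, K), mets)

  if (is.null(cor_between)) {
    cor_between <- matrix(0.25, K, K, dimnames = list(mets, mets))
    dehp <- dehp_metabolites()
    cor_between[dehp, dehp] <- 0.9
    diag(cor_between) <- 1
  }
  if (is.null(cor_within)) {
    cor_within <- matrix(0.1, K, K, dimnames = list(mets, mets))
    dehp <- dehp_metabolites()
    cor_within[dehp, dehp] <- 0.8
    diag(cor_within) <- 1
  }

  if (is.null(gamma_true)) {
    gamma_true <- c(mehp = -0.004, mehhp = -0.002, meohp = -0.003,
                    mecpp = -0.010, mbzp = -0.004, mbp = -0.004,
                    mibp = 0, mep = -0.001, mcpp = -0.003)
  }
  gamma_true <- stats::setNames(rep_len(gamma_true, K), mets)

  if (is.null(preterm_logit_effects)) {
    preterm_logit_effects <- c(mehp = 0.10, mehhp = 0.05, meohp = 0.08,
                               mecpp = 0.30, mbzp = 0.12, mbp = 0.12,
                               mibp = 0, mep = 0.03, mcpp = 0.08)
  }
  preterm_logit_effects <- stats::setNames(rep_len(preterm_logit_effects, K), mets)

  if (is.null(covariate_effects)) {
    covariate_effects <- list(
      log_time = c(maternal_age_c = -0.0002, insurance_public = -0.004,
                   race_black = -0.003, race_asian = 0, race_other = -0.001,
                   edu_highschool = -0.003, edu_graduate = 0.001, edu_technical = -0.001),
      preterm_logit = c(maternal_age_c = 0.010, insurance_public = 0.25,
                        race_black = 0.15, race_asian = 0, race_other = 0.05,
                        edu_highschool = 0.15, edu_graduate = -0.05, edu_technical = 0.05)
    )
  }

  if (is.null(nondetect_target)) {
    nondetect_target <- stats::setNames(rep(0.01, K), mets)
    nondetect_target["mehp"] <- 0.047
  }
  nondetect_target <- stats::setNames(rep_len(nondetect_target, K), mets)

  sd_b <- sqrt(icc) * sd_log_total
  cov_log <- cor_between * outer(sd_b, sd_b)

  truth <- structure(list(
    n_subjects = as.integer(n_subjects),
    metabolite_names = mets,
    mu_log = mu_log,
    cov_log = cov_log,
    cor_within = cor_within,
    icc = icc,
    sd_log_total = sd_log_total,
    visit_weeks = visit_weeks,
    visit_jitter = visit_jitter,
    sg_center = sg_center,
    sg_spread = sg_spread,
    outcome_mode = outcome_mode,
    gamma_true = gamma_true,
    preterm_logit_effects = preterm_logit_effects,
    preterm_target = preterm_target,
    gamma0 = gamma0,
    sigma_log_T = sigma_log_T,
    covariate_effects = covariate_effects,
    lod = lod,
    nondetect_target = nondetect_target,
    seed = as.integer(seed)
  ), class = "sim_truth")
  validate_sim_truth(truth)
  truth
}

#' The nine urinary phthalate metabolites modelled by the package
#' @return character vector of metabolite labels.
#' @export
phthalate_metabolites <- function() {
  c("mehp", "mehhp", "meohp", "mecpp", "mbzp", "mbp", "mibp", "mep", "mcpp")
}

#' The four DEHP metabolites entering the molar sum
#' @return character vector (subset of [phthalate_metabolites()]).
#' @export
dehp_metabolites <- function() c("mehp", "mehhp", "meohp", "mecpp")

validate_sim_truth <- function(truth) {
  stopifnot(truth$n_subjects >= 2L)
  if (any(truth$icc <= 0 | truth$icc >= 1)) {
    stop("icc must lie strictly in (0, 1)")
  }
  if (!isTRUE(all.equal(truth$cov_log, t(truth$cov_log), tolerance = 1e-8))) {
    stop("cov_log must be symmetric")
  }
  ev <- eigen(truth$cov_log, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8 * max(abs(ev))) {
    stop("cov_log must be positive semi-definite")
  }
  if (any(diff(truth$visit_weeks) <= 0)) stop("visit_weeks must be strictly increasing")
  if (truth$sg_center <= 1) stop("sg_center must exceed 1")
  if (truth$sg_center - truth$sg_spread <= 1) stop("sg law must stay above 1")
  # visit-noise variance must remain positive once dilution variance is removed
  wvar <- diag(truth$cov_log) * (1 / truth$icc - 1)
  if (any(wvar <= dilution_log_variance(truth) + 1e-10)) {
    stop("within-subject variance implied by icc is smaller than the dilution variance")
  }
  se <- visit_noise_cov(truth)
  ev_e <- eigen(se, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev_e) < -1e-8 * max(abs(ev_e))) {
    stop("cor_within and icc imply a non-PSD visit-noise covariance")
  }
  invisible(truth)
}

# Covariance of the visit-noise component (dilution excluded).
visit_noise_cov <- function(truth) {
  evar <- diag(truth$cov_log) * (1 / truth$icc - 1) - dilution_log_variance(truth)
  truth$cor_within * outer(sqrt(evar), sqrt(evar))
}

# Mean and variance of log((SG - 1)/(sg_center - 1)) for SG uniform on
# [sg_center - sg_spread, sg_center + sg_spread]; closed form from the
# antiderivatives of log(u) and log(u)^2.
dilution_log_moments <- function(truth) {
  a <- truth$sg_center - truth$sg_spread - 1
  b <- truth$sg_center + truth$sg_spread - 1
  m1 <- (b * log(b) - b - (a * log(a) - a)) / (b - a)
  f2 <- function(u) u * (log(u)^2 - 2 * log(u) + 2)
  m2 <- (f2(b) - f2(a)) / (b - a)
  ref <- log(truth$sg_center - 1)
  c(mean = m1 - ref, var = m2 - m1^2)
}

dilution_log_variance <- function(truth) unname(dilution_log_moments(truth)["var"])

#' @export
print.sim_truth <- function(x, ...) {
  cat("Synthetic pregnancy-cohort truth\n")
  cat(sprintf("  subjects: %d   outcome mode: %s   seed: %d\n",
              x$n_subjects, x$outcome_mode, x$seed))
  cat(sprintf("  metabolites: %s\n", paste(x$metabolite_names, collapse = ", ")))
  cat(sprintf("  icc range: %.2f-%.2f   visit weeks: %s\n",
              min(x$icc), max(x$icc), paste(x$visit_weeks, collapse = ", ")))
  invisible(x)
}
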