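#' Generate a full pregnancy cohort from a ground-truth configuration
#'
#' Draws subject-level covariates, subject-level exposure intercepts, four
#' visits of log-concentration measurements with urinary-dilution coupling to
#' specific gravity, and gestational age at delivery under the configured
#' outcome mode. The output is the *full* cohort before visit attrition,
#' detection-limit censoring and nested case-control sampling, which are
#' applied by [apply_visit_attrition()], [censor_at_lod()] and
#' [sample_nested_case_control()].
#'
#' @param truth a [sim_truth()] object.
#' @return a list of class `phthal_cohort` with elements
#'   `subjects` (one row per subject: `subject_id`, `T_days`, `preterm`,
#'   covariates, `sampled`, `w`), `visits` (one row per subject-visit:
#'   `subject_id`, `visit`, `gest_week`, `sg`, one concentration column per
#'   metabolite in µg/L and one `det_*` detection flag per metabolite), and
#'   `truth`.
#' @export
generate_full_cohort <- function(truth) {
  validate_sim_truth(truth)
  set.seed(truth$seed)
  n <- truth$n_subjects
  mets <- truth$metabolite_names
  K <- length(mets)

  subjects <- data.frame(
    subject_id = seq_len(n),
    race = sample(c("white", "black", "asian", "other"), n, replace = TRUE,
                  prob = c(0.60, 0.16, 0.10, 0.14)),
    education = sample(c("college", "graduate", "highschool", "technical"), n,
                       replace = TRUE, prob = c(0.40, 0.30, 0.16, 0.14)),
    maternal_age = pmin(pmax(stats::rnorm(n, 32.5, 5), 18), 45),
    insurance = sample(c("private", "public"), n, replace = TRUE,
                       prob = c(0.80, 0.20)),
    stringsAsFactors = FALSE
  )

  b <- MASS::mvrnorm(n, mu = truth$mu_log, Sigma = truth$cov_log)
  colnames(b) <- mets

  sigma_e <- visit_noise_cov(truth)
  n_visits <- length(truth$visit_weeks)
  visit_list <- vector("list", n_visits)
  logx_by_visit <- vector("list", n_visits)
  for (j in seq_len(n_visits)) {
    week <- truth$visit_weeks[j] +
      stats::runif(n, -truth$visit_jitter[j], truth$visit_jitter[j])
    sg <- stats::runif(n, truth$sg_center - truth$sg_spread,
                       truth$sg_center + truth$sg_spread)
    d <- log((sg - 1) / (truth$sg_center - 1))
    e <- MASS::mvrnorm(n, mu = rep(0, K), Sigma = sigma_e)
    logx <- b + d + e
    colnames(logx) <- mets
    logx_by_visit[[j]] <- logx
    v <- data.frame(subject_id = subjects$subject_id, visit = j,
                    gest_week = week, sg = sg)
    v[mets] <- as.data.frame(exp(logx))
    for (m in mets) v[[paste0("det_", m)]] <- TRUE
    visit_list[[j]] <- v
  }
  visits <- do.call(rbind, visit_list)
  rownames(visits) <- NULL

  # mean of visit 1-3 log concentrations: the exposure summary the
  # average-exposure analysis fits, and the quantity driving the outcome
  xbar <- (logx_by_visit[[1]] + logx_by_visit[[2]] + logx_by_visit[[3]]) / 3

  zmat <- generation_design(subjects)
  eff <- truth$covariate_effects
  if (truth$outcome_mode == "aft_lognormal") {
    lp <- drop(xbar %*% truth$gamma_true) +
      drop(zmat %*% eff$log_time[colnames(zmat)])
    log_t <- truth$gamma0 + lp + truth$sigma_log_T * stats::rnorm(n)
    t_days <- exp(log_t)
  } else {
    xc <- scale(xbar, center = TRUE, scale = FALSE)
    lp <- drop(xc %*% truth$preterm_logit_effects) +
      drop(zmat %*% eff$preterm_logit[colnames(zmat)])
    eta0 <- stats::uniroot(
      function(e) mean(stats::plogis(e + lp)) - truth$preterm_target,
      interval = c(-25, 10), tol = 1e-10
    )$root
    early <- stats::runif(n) < stats::plogis(eta0 + lp)
    p_lo <- stats::pnorm(259, 277, 8)
    p_hi <- stats::pnorm(295, 277, 8)
    t_term <- stats::qnorm(p_lo + stats::runif(n) * (p_hi - p_lo), 277, 8)
    t_early <- 259 - (1 + 34 * stats::rbeta(n, 1.2, 2.2))
    t_days <- round(ifelse(early, t_early, t_term))
  }
  subjects$T_days <- as.numeric(t_days)
  subjects$preterm <- as.integer(subjects$T_days < 259)
  subjects$sampled <- NA
  subjects$w <- NA_real_

  structure(list(subjects = subjects, visits = visits, truth = truth),
            class = "phthal_cohort")
}

# Numeric design columns the generator's covariate effects are expressed in.
generation_design <- function(subjects) {
  cbind(
    maternal_age_c = subjects$maternal_age - 32.5,
    insurance_public = as.numeric(subjects$insurance == "public"),
    race_black = as.numeric(subjects$race == "black"),
    race_asian = as.numeric(subjects$race == "asian"),
    race_other = as.numeric(subjects$race == "other"),
    edu_highschool = as.numeric(subjects$education == "highschool"),
    edu_graduate = as.numeric(subjects$education == "graduate"),
    edu_technical = as.numeric(subjects$education == "technical")
  )
}

#' Remove visit records lost to delivery or missed at random
#'
#' Every visit whose sampling time (gestational weeks times 7) falls at or
#' after the subject's delivery day is removed — a woman cannot provide a
#' pregnancy urine sample after delivering. Visits 2 onward are additionally
#' removed independently at the configured per-visit rates; visit 1 is never
#' removed by the random mechanism (enrolment requires it).
#'
#' @param visits visit table from [generate_full_cohort()].
#' @param outcomes subject table carrying `subject_id` and `T_days`.
#' @param missing_rate_by_visit per-visit random missingness probabilities;
#'   the first entry must be 0.
#' @return the filtered visit table.
#' @export
apply_visit_attrition <- function(visits, outcomes,
                                  missing_rate_by_visit = c(0, 0.10, 0.12, 0.08)) {
  stopifnot(all(missing_rate_by_visit >= 0), all(missing_rate_by_visit <= 1))
  if (missing_rate_by_visit[1] != 0) {
    stop("visit 1 cannot be removed by the random missingness mechanism")
  }
  t_days <- outcomes$T_days[match(visits$subject_id, outcomes$subject_id)]
  keep <- visits$gest_week * 7 < t_days
  rate <- missing_rate_by_visit[visits$visit]
  rate[is.na(rate)] <- 0
  miss <- stats::runif(nrow(visits)) < rate
  out <- visits[keep & !miss, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Censor concentrations at the assay limit of detection
#'
#' Values strictly below the limit of detection are flagged as non-detects
#' and stored at the LOD itself; substitution by LOD/sqrt(2) is deferred to
#' [substitute_nondetects()] so the censoring state survives in the data.
#' Values exactly at the LOD count as detected.
#'
#' @param visits visit table with one concentration and one `det_*` column
#'   per metabolite.
#' @param lod named per-metabolite detection limits (µg/L), e.g. from
#'   [default_lod()].
#' @return the visit table with censored concentrations and updated flags.
#' @export
censor_at_lod <- function(visits, lod) {
  stopifnot(all(lod > 0), !is.null(names(lod)))
  for (m in names(lod)) {
    if (!m %in% names(visits)) stop("unknown metabolite in lod: ", m)
    det <- visits[[m]] >= lod[[m]]
    visits[[m]][!det] <- lod[[m]]
    visits[[paste0("det_", m)]] <- det
  }
  visits
}

#' Default detection limits implied by target non-detect fractions
#'
#' Places each metabolite's LOD at the `nondetect_target` quantile of its
#' marginal lognormal law (including the dilution shift), so the generated
#' non-detect fraction matches the target in expectation.
#'
#' @param truth a [sim_truth()] object.
#' @return named numeric vector of detection limits (µg/L).
#' @export
default_lod <- function(truth) {
  dm <- dilution_log_moments(truth)
  sd_tot <- sqrt(diag(truth$cov_log) / truth$icc)
  exp(truth$mu_log + dm["mean"] + stats::qnorm(truth$nondetect_target) * sd_tot)
}

#' Draw the nested case-control sample and assign design weights
#'
#' All preterm deliveries are selected as cases with weight 1. Controls are
#' drawn uniformly without replacement from non-cases that have a visit-1
#' sample and at least one later visit; each sampled control represents
#' `n_eligible / n_controls` cohort members (inverse probability of
#' selection).
#'
#' @param outcomes subject table with `preterm`.
#' @param visits visit table after attrition (defines control eligibility).
#' @param n_controls number of controls to draw.
#' @param seed optional integer seed for the control draw.
#' @return the subject table with `sampled` and `w` filled in (`w = 0` for
#'   unsampled subjects).
#' @export
sample_nested_case_control <- function(outcomes, visits, n_controls, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  has_v1 <- unique(visits$subject_id[visits$visit == 1])
  has_later <- unique(visits$subject_id[visits$visit > 1])
  eligible <- intersect(has_v1, has_later)
  is_case <- outcomes$preterm == 1
  pool <- outcomes$subject_id[!is_case & outcomes$subject_id %in% eligible]
  if (n_controls > length(pool)) {
    stop(sprintf("n_controls (%d) exceeds the eligible non-case pool (%d)",
                 n_controls, length(pool)))
  }
  controls <- sample(pool, n_controls)
  outcomes$sampled <- is_case | outcomes$subject_id %in% controls
  outcomes$w <- 0
  outcomes$w[is_case] <- 1
  outcomes$w[outcomes$subject_id %in% controls] <- length(pool) / n_controls
  outcomes
}

#' Run the whole study design in one call
#'
#' Convenience wrapper: generates the full cohort, applies visit attrition,
#' censors at the (default or supplied) detection limits, and draws the
#' nested case-control sample.
#'
#' @param truth a [sim_truth()] object.
#' @param missing_rate_by_visit passed to [apply_visit_attrition()].
#' @param n_controls number of controls (default 352, capped at the eligible
#'   pool).
#' @param lod detection limits; default from [default_lod()].
#' @return a `phthal_cohort` list with sampling applied.
#' @export
simulate_study <- function(truth,
                           missing_rate_by_visit = c(0, 0.10, 0.12, 0.08),
                           n_controls = 352,
                           lod = NULL) {
  cohort <- generate_full_cohort(truth)
  cohort$visits <- apply_visit_attrition(cohort$visits, cohort$subjects,
                                         missing_rate_by_visit)
  if (is.null(lod)) lod <- default_lod(truth)
  cohort$visits <- censor_at_lod(cohort$visits, lod)
  cohort$lod <- lod
  has_v1 <- unique(cohort$visits$subject_id[cohort$visits$visit == 1])
  has_later <- unique(cohort$visits$subject_id[cohort$visits$visit > 1])
  pool_n <- sum(cohort$subjects$preterm == 0 &
                  cohort$subjects$subject_id %in% intersect(has_v1, has_later))
  cohort$subjects <- sample_nested_case_control(
    cohort$subjects, cohort$visits, min(n_controls, pool_n)
  )
  cohort
}

#' Write a cohort to plain-text files
#'
#' Writes `cohort_subjects.csv`, `cohort_visits.csv` and `simtruth.json`
#' (all generator parameters and the seed) into `dir`.
#'
#' @param cohort a `phthal_cohort`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(cohort$subjects, file.path(dir, "cohort_subjects.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$visits, file.path(dir, "cohort_visits.csv"),
                   row.names = FALSE)
  tr <- unclass(cohort$truth)
  tr$cov_log <- as.data.frame(tr$cov_log)
  tr$cor_within <- as.data.frame(tr$cor_within)
  if (!is.null(cohort$lod)) tr$lod_applied <- as.list(cohort$lod)
  jsonlite::write_json(tr, file.path(dir, "simtruth.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}

#' Read a cohort written by [write_cohort()]
#' @param dir directory containing the cohort files.
#' @return a `phthal_cohort` list (truth echoed as a plain list).
#' @export
read_cohort <- function(dir) {
  subjects <- utils::read.csv(file.path(dir, "cohort_subjects.csv"))
  visits <- utils::read.csv(file.path(dir, "cohort_visits.csv"))
  truth_path <- file.path(dir, "simtruth.json")
  truth <- if (file.exists(truth_path)) jsonlite::read_json(truth_path, simplifyVector = TRUE)
  lod <- if (!is.null(truth$lod_applied)) unlist(truth$lod_applied)
  structure(list(subjects = subjects, visits = visits, truth = truth,
                 lod = lod),
            class = "phthal_cohort")
}

#' @export
print.phthal_cohort <- function(x, ...) {
  cat(sprintf("Synthetic pregnancy cohort: %d subjects, %d visit records\n",
              nrow(x$subjects), nrow(x$visits)))
  cat(sprintf("  preterm: %d (%.1f%%)", sum(x$subjects$preterm),
              100 * mean(x$subjects$preterm)))
  if (any(!is.na(x$subjects$sampled))) {
    cat(sprintf("   sampled: %d (cases %d, controls %d)",
                sum(x$subjects$sampled, na.rm = TRUE),
                sum(x$subjects$sampled & x$subjects$preterm == 1, na.rm = TRUE),
                sum(x$subjects$sampled & x$subjects$preterm == 0, na.rm = TRUE)))
  }
  cat("\n")
  invisible(x)
}
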