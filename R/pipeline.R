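# Orchestration of the two analysis arms over a (simulated or loaded)
# nested case-control cohort:
#   * average-exposure arm: per-subject mean of visit 1-3 log concentrations
#     -> single-pollutant models (logistic / Cox / AFT) for the nine
#     metabolites and the molar DEHP sum -> four summative risk scores
#     (ERS/WQS x correlation-screen/stepwise) fitted continuously and by
#     quartile;
#   * repeated-measures arm: stage-1 random-intercept LMM per exposure (all
#     four visits) -> IQR-standardized BLUPs -> the same outcome models;
#     per-visit ERS -> LMM -> BLUP for the two ERS scores (WQS is excluded:
#     the stage-1 response must be continuous).
# Exposure summaries are always frozen before any outcome model is fitted.

#' Analysis configuration
#'
#' @param seed seed used for the WQS bootstrap.
#' @param q number of quantile groups for WQS scoring.
#' @param B WQS bootstrap resamples.
#' @param corr_threshold block-forming correlation threshold for the
#'   correlation screen.
#' @param quantile_type quantile rule for IQRs and quantile scoring.
#' @param visit_set visits entering the average-exposure summaries.
#' @param insurance_exposures single-pollutant models for these exposures
#'   additionally adjust for insurance (risk-score models always do).
#' @param scores risk scores to build in the average arm.
#' @param weighted_iqr logical: use IPW design weights when computing IQRs
#'   (default FALSE: coefficients are reported per analysis-sample IQR).
#' @return a list of class `analysis_config`.
#' @export
analysis_config <- function(seed = 1L, q = 4, B = 100, corr_threshold = 0.5,
                            quantile_type = 7, visit_set = 1:3,
                            insurance_exposures = c("mbzp", "mbp", "mibp",
                                                    "mep", "mcpp"),
                            scores = c("ers_corr", "ers_stepwise",
                                       "wqs_corr", "wqs_stepwise"),
                            weighted_iqr = FALSE) {
  structure(list(seed = as.integer(seed), q = q, B = B,
                 corr_threshold = corr_threshold,
                 quantile_type = quantile_type, visit_set = visit_set,
                 insurance_exposures = insurance_exposures, scores = scores,
                 weighted_iqr = weighted_iqr),
            class = "analysis_config")
}

# Analysis subset: sampled subjects with their design weights and visits.
.analysis_set <- function(cohort) {
  subj <- cohort$subjects
  if (all(is.na(subj$sampled))) {
    # full-cohort analysis: everyone in, weight 1
    subj$sampled <- TRUE
    subj$w <- 1
  }
  subj <- subj[subj$sampled %in% TRUE, , drop = FALSE]
  visits <- cohort$visits[cohort$visits$subject_id %in% subj$subject_id, , drop = FALSE]
  list(subjects = subj, visits = visits)
}

.cohort_lod <- function(cohort) {
  if (!is.null(cohort$lod)) return(cohort$lod)
  mets <- intersect(phthalate_metabolites(), names(cohort$visits))
  vapply(mets, function(m) {
    det <- cohort$visits[[paste0("det_", m)]]
    if (!is.null(det) && any(!det)) min(cohort$visits[[m]][!det]) else 1
  }, numeric(1))
}

#' Run the average-exposure analysis arm
#'
#' @param cohort a `phthal_cohort` (sampled via
#'   [sample_nested_case_control()], or a full cohort analysed with unit
#'   weights).
#' @param config an [analysis_config()].
#' @return list with `effects` (one row per model/contrast), `iqr` (per
#'   exposure), `selection` (both subsets), `ers`, `wqs` (fit objects),
#'   `scores` (per-subject score data frame), `corr` (descriptive
#'   correlation matrix of SG-corrected mean exposures) and `descriptives`.
#' @export
run_average_analysis <- function(cohort, config = analysis_config()) {
  set.seed(config$seed)
  an <- .analysis_set(cohort)
  subj <- an$subjects
  lod <- .cohort_lod(cohort)
  expo <- build_average_exposures(an$visits, lod, config$visit_set)
  dat <- merge(subj, expo, by = "subject_id")
  w <- dat$w
  mets <- phthalate_metabolites()
  exposures <- c(mets, "sum_dehp")

  covs_base <- dat[, c("maternal_age", "race", "education")]
  covs_base$avg_sg <- dat$avg_sg
  covs_ins <- cbind(covs_base, insurance = dat$insurance)

  iqr_w <- if (config$weighted_iqr) w else NULL
  std <- list(); iqrs <- numeric(0)
  for (x in exposures) {
    s <- iqr_standardize(dat[[x]], type = config$quantile_type, weights = iqr_w)
    std[[x]] <- s$values_std
    iqrs[x] <- s$iqr
  }

  effects <- list()
  cox_z <- numeric(0)
  for (x in exposures) {
    covs <- if (x %in% config$insurance_exposures) covs_ins else covs_base
    rows <- rbind(
      fit_logistic(std[[x]], dat$preterm, covs, w, label = x),
      fit_cox(std[[x]], dat$T_days, covs, w, label = x),
      fit_aft_lognormal(std[[x]], dat$T_days, covs, w, label = x)
    )
    effects[[x]] <- rows
    cx <- rows[rows$model == "cox", ]
    cox_z[x] <- cx$coefficient / cx$se
  }

  corr <- sg_corrected_correlation(an$visits, lod, config$visit_set,
                                   m_sg = 1.015)
  subset_corr <- select_by_correlation(corr, abs(cox_z),
                                       threshold = config$corr_threshold,
                                       candidates = mets)
  subset_step <- select_stepwise(as.data.frame(std[mets]), dat$preterm,
                                 covs_ins, w)
  if (!length(subset_step)) subset_step <- names(which.max(abs(cox_z[mets])))
  selection <- list(corr = subset_corr, stepwise = subset_step)

  score_tab <- data.frame(subject_id = dat$subject_id)
  ers_fits <- list(); wqs_fits <- list()
  for (sc in config$scores) {
    kind <- sub("_.*$", "", sc)
    sel <- if (grepl("_corr$", sc)) subset_corr else subset_step
    if (kind == "ers") {
      ww <- fit_ers_weights(as.data.frame(std[sel]), dat$preterm, covs_ins, w)
      ers <- compute_ers(as.data.frame(std[sel]), ww, type = config$quantile_type)
      ers_fits[[sc]] <- list(subset = sel, weights = ww, iqr = ers$iqr)
      score_std <- ers$score_std
    } else {
      qs <- vapply(sel, function(m) quantile_score(dat[[m]], q = config$q,
                                                   type = config$quantile_type),
                   numeric(nrow(dat)))
      if (length(sel) >= 2L) {
        wf <- fit_wqs(qs, dat$preterm, covs_ins, w, B = config$B)
      } else {
        # degenerate mixture: the index is the lone quantile score, weight 1
        warning("subset for ", sc, " has a single exposure; ",
                "WQS reduces to its quantile score")
        idx <- qs[, 1]
        std <- iqr_standardize(idx, type = config$quantile_type)
        refit <- fit_logistic(std$values_std, dat$preterm, covs_ins, w,
                              label = sc)
        wf <- structure(list(weights = stats::setNames(1, sel),
                             index = idx, index_std = std$values_std,
                             iqr = std$iqr, beta1 = refit$coefficient,
                             se = refit$se, boot = NULL, n_used = 0L,
                             B = config$B),
                        class = "wqs_fit")
      }
      wqs_fits[[sc]] <- wf
      score_std <- wf$index_std
    }
    score_tab[[sc]] <- score_std
    rows <- rbind(
      fit_logistic(score_std, dat$preterm, covs_ins, w, label = sc),
      fit_cox(score_std, dat$T_days, covs_ins, w, label = sc),
      fit_aft_lognormal(score_std, dat$T_days, covs_ins, w, label = sc)
    )
    quart <- quartile_categorize(score_std, w)
    score_tab[[paste0(sc, "_quartile")]] <- as.character(quart)
    qrows <- fit_quartile_models(quart, dat$T_days, dat$preterm, covs_ins, w,
                                 label = sc)
    effects[[sc]] <- rbind(rows, qrows)
  }

  effects <- do.call(rbind, effects)
  effects <- cbind(analysis = "average", effects)
  rownames(effects) <- NULL
  list(effects = effects, iqr = iqrs, selection = selection,
       ers = ers_fits, wqs = wqs_fits, scores = score_tab, corr = corr,
       descriptives = cohort_descriptives(cohort, an),
       data = dat, std = std, config = config)
}

# Pearson correlation matrix of SG-corrected, log-transformed mean exposures
# (descriptive only; regression models use raw exposures with SG as a
# covariate).
sg_corrected_correlation <- function(visits, lod, visit_set = 1:3, m_sg = 1.015) {
  visits <- substitute_nondetects_visits(visits, lod)
  mets <- names(lod)
  for (m in mets) visits[[m]] <- sg_correct(visits[[m]], visits$sg, m_sg)
  visits <- add_sum_dehp(visits)
  cols <- c(mets, "sum_dehp")
  means <- NULL
  for (m in cols) {
    a <- suppressWarnings(average_log_exposure(visits, m, visit_set))
    names(a)[names(a) == "value"] <- m
    a$n_visits <- NULL
    means <- if (is.null(means)) a else merge(means, a, by = "subject_id")
  }
  stats::cor(as.matrix(means[cols]))
}

# Descriptive summaries for reporting: non-detect fractions, gestational-age
# histogram counts, visit availability by case status.
cohort_descriptives <- function(cohort, an = .analysis_set(cohort)) {
  visits <- an$visits
  mets <- intersect(phthalate_metabolites(), names(visits))
  nondetect <- vapply(mets, function(m) {
    det <- visits[[paste0("det_", m)]]
    if (is.null(det)) 0 else mean(!det)
  }, numeric(1))
  breaks <- seq(154, 322, by = 7)
  t_days <- pmin(pmax(an$subjects$T_days, 154.5), 321.5)
  counts <- as.integer(table(cut(t_days, breaks = breaks)))
  avail <- stats::aggregate(
    list(has_v4 = visits$visit),
    by = list(subject_id = visits$subject_id),
    FUN = function(v) as.integer(4 %in% v)
  )
  avail <- merge(avail, an$subjects[, c("subject_id", "preterm")])
  list(nondetect_fraction = nondetect,
       ga_hist = list(breaks = breaks, counts = counts),
       visit4_by_status = tapply(avail$has_v4, avail$preterm, mean))
}

#' Run the repeated-measures analysis arm
#'
#' Stage 1 fits a random-intercept LMM (fixed effects: gestational week at
#' sampling and specific gravity) to each exposure's visit 1-4 log
#' concentrations; stage 2 regresses the outcome on the IQR-standardized
#' BLUPs, adjusting for maternal age, race and education (plus insurance per
#' the configured rule). Per-visit ERS (average-analysis selection and
#' weights applied to visit-specific IQR-scaled log concentrations) follows
#' the same two-stage path. WQS is not available in this arm because the
#' stage-1 response must be continuous.
#'
#' @inheritParams run_average_analysis
#' @param average optional result of [run_average_analysis()] providing the
#'   ERS selections and weights; computed internally when missing.
#' @param scores repeated-measures risk scores (ERS only).
#' @return list with `effects`, `blup_iqr`, and the ERS construction used.
#' @export
run_repeated_analysis <- function(cohort, config = analysis_config(),
                                  average = NULL,
                                  scores = c("ers_corr", "ers_stepwise")) {
  if (any(grepl("^wqs", scores))) {
    stop("WQS cannot be used in the repeated-measures arm: the stage-1 ",
         "linear mixed model needs a continuous response and the weighted ",
         "quantile sum is inherently discrete")
  }
  an <- .analysis_set(cohort)
  subj <- an$subjects
  lod <- .cohort_lod(cohort)
  visits <- substitute_nondetects_visits(an$visits, lod)
  visits <- add_sum_dehp(visits)
  mets <- phthalate_metabolites()
  exposures <- c(mets, "sum_dehp")

  covs_base <- subj[, c("maternal_age", "race", "education")]
  covs_ins <- cbind(covs_base, insurance = subj$insurance)

  fit_stage2 <- function(blup_df, covs, label) {
    m <- merge(subj, blup_df, by.x = "subject_id", by.y = "subject")
    m <- m[order(m$subject_id), ]
    ix <- match(m$subject_id, subj$subject_id)
    rbind(
      fit_logistic(m$blup_std, m$preterm, covs[ix, , drop = FALSE], m$w, label),
      fit_cox(m$blup_std, m$T_days, covs[ix, , drop = FALSE], m$w, label),
      fit_aft_lognormal(m$blup_std, m$T_days, covs[ix, , drop = FALSE], m$w, label)
    )
  }

  effects <- list(); blup_iqr <- numeric(0)
  for (x in exposures) {
    long <- data.frame(subject_id = visits$subject_id,
                       value = log(visits[[x]]),
                       gest_week = visits$gest_week, sg = visits$sg)
    fit <- fit_random_intercept_lmm(long)
    bl <- extract_blups(fit, type = config$quantile_type)
    blup_iqr[x] <- attr(bl, "iqr")
    covs <- if (x %in% config$insurance_exposures) covs_ins else covs_base
    effects[[x]] <- fit_stage2(bl, covs, x)
  }

  if (length(scores)) {
    if (is.null(average)) average <- run_average_analysis(cohort, config)
    for (sc in scores) {
      ers <- average$ers[[sc]]
      if (is.null(ers)) stop("average-analysis ERS '", sc, "' not available")
      # per-visit score: average-analysis weights on visit-specific log
      # concentrations, scaled by the average-analysis exposure IQRs
      ers_ij <- rowSums(vapply(
        ers$subset,
        function(m) ers$weights[[m]] * log(visits[[m]]) / average$iqr[[m]],
        numeric(nrow(visits))
      ))
      long <- data.frame(subject_id = visits$subject_id, value = ers_ij,
                         gest_week = visits$gest_week, sg = visits$sg)
      fit <- fit_random_intercept_lmm(long)
      bl <- extract_blups(fit, type = config$quantile_type)
      blup_iqr[sc] <- attr(bl, "iqr")
      effects[[sc]] <- fit_stage2(bl, covs_ins, sc)
    }
  }

  effects <- do.call(rbind, effects)
  effects <- cbind(analysis = "repeated", effects)
  rownames(effects) <- NULL
  list(effects = effects, blup_iqr = blup_iqr, scores = scores,
       config = config)
}

#' Write analysis outputs to files
#'
#' Writes `effects.tsv` (all effect estimates), `weights.json` (subset
#' selections, ERS/WQS weights, IQRs, seed), `descriptives.json`
#' (correlation matrix, non-detect fractions, gestational-age histogram)
#' and `manifest.json` (configuration and session provenance).
#'
#' @param average result of [run_average_analysis()].
#' @param repeated optional result of [run_repeated_analysis()].
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
make_report <- function(average, repeated = NULL, dir = "results") {
  if (is.null(average$effects) || !nrow(average$effects)) stop("no effects to report")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  effects <- average$effects
  if (!is.null(repeated)) effects <- rbind(effects, repeated$effects)
  utils::write.table(effects, file.path(dir, "effects.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  weights <- list(
    selection = average$selection,
    ers = lapply(average$ers, function(e)
      list(subset = e$subset, weights = as.list(e$weights), iqr = e$iqr)),
    wqs = lapply(average$wqs, function(wf)
      list(subset = names(wf$weights), weights = as.list(wf$weights),
           beta1 = wf$beta1, B = wf$B, n_used = wf$n_used)),
    exposure_iqr = as.list(average$iqr),
    blup_iqr = if (!is.null(repeated)) as.list(repeated$blup_iqr),
    seed = average$config$seed, B = average$config$B
  )
  jsonlite::write_json(weights, file.path(dir, "weights.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  desc <- average$descriptives
  desc$correlation <- as.data.frame(average$corr)
  jsonlite::write_json(desc, file.path(dir, "descriptives.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  manifest <- list(
    config = unclass(average$config),
    package_version = as.character(utils::packageVersion("phthalmix")),
    r_version = R.version.string,
    created = format(Sys.time(), tz = "UTC")
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
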