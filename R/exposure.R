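# Exposure processing: non-detect substitution, specific-gravity dilution
# correction, molar DEHP summation, visit averaging, IQR standardization.
#
# Regression contract: models are fitted on raw (uncorrected) concentrations
# with specific gravity entering as a covariate; SG-corrected values are used
# only for descriptive correlation tables, because regressing on
# dilution-corrected concentrations can bias exposure coefficients.

#' Substitute non-detects by LOD/sqrt(2)
#'
#' @param conc concentration vector (µg/L), with non-detects stored at the
#'   LOD as produced by [censor_at_lod()].
#' @param detected logical vector, same length.
#' @param lod detection limit(s), scalar or vector.
#' @return concentrations with non-detects replaced by `lod / sqrt(2)`.
#' @export
substitute_nondetects <- function(conc, detected, lod) {
  stopifnot(all(lod > 0))
  lod <- rep_len(lod, length(conc))
  ifelse(detected, conc, lod / sqrt(2))
}

# Apply LOD/sqrt(2) substitution to every metabolite column of a visit table.
#' Substitute non-detects across a visit table
#' @param visits visit table with `det_*` flags.
#' @param lod named per-metabolite detection limits.
#' @return visit table with substituted concentrations (flags retained).
#' @export
substitute_nondetects_visits <- function(visits, lod) {
  for (m in names(lod)) {
    visits[[m]] <- substitute_nondetects(visits[[m]],
                                         visits[[paste0("det_", m)]],
                                         lod[[m]])
  }
  visits
}

#' Specific-gravity dilution correction
#'
#' Corrects a urinary concentration for dilution:
#' `P_C = P * (M_SG - 1) / (SG - 1)`, where `M_SG` is the population median
#' specific gravity. Used for descriptive summaries only (see the regression
#' contract above).
#'
#' @param p measured concentration (µg/L).
#' @param sg specific gravity of the sample (> 1).
#' @param m_sg median specific gravity (default 1.015).
#' @return corrected concentration (µg/L).
#' @export
sg_correct <- function(p, sg, m_sg = 1.015) {
  if (any(sg <= 1)) stop("specific gravity must exceed 1 (dilution correction singular)")
  p * (m_sg - 1) / (sg - 1)
}

# Molecular weights (g/mol) of the DEHP metabolites.
DEHP_MW <- c(mehp = 278.34, mehhp = 294.34, meohp = 292.33, mecpp = 308.33)

#' Molar sum of DEHP metabolites
#'
#' Converts the four DEHP metabolite concentrations from µg/L to nmol/L
#' (`conc * 1000 / MW`) and sums them, giving an index of exposure to the
#' parent compound.
#'
#' @param mehp,mehhp,meohp,mecpp concentrations in µg/L (post-substitution).
#' @return total DEHP metabolite concentration in nmol/L.
#' @export
molar_sum_dehp <- function(mehp, mehhp, meohp, mecpp) {
  if (any(c(mehp, mehhp, meohp, mecpp) < 0)) stop("concentrations must be non-negative")
  mehp * 1000 / DEHP_MW[["mehp"]] +
    mehhp * 1000 / DEHP_MW[["mehhp"]] +
    meohp * 1000 / DEHP_MW[["meohp"]] +
    mecpp * 1000 / DEHP_MW[["mecpp"]]
}

# Add a per-visit molar DEHP sum column (nmol/L) to a visit table.
add_sum_dehp <- function(visits) {
  visits$sum_dehp <- molar_sum_dehp(visits$mehp, visits$mehhp,
                                    visits$meohp, visits$mecpp)
  visits
}

#' Per-subject mean of log-transformed concentrations
#'
#' Natural-log transforms each available concentration and averages over the
#' subject's visits in `visit_set` (default visits 1-3; the fourth visit is
#' excluded because women delivering early are less likely to have one,
#' which would make its availability informative).
#'
#' @param visits visit table (post-substitution).
#' @param metabolite concentration column to summarise.
#' @param visit_set visits entering the average.
#' @return data frame with `subject_id`, `value` (mean log concentration)
#'   and `n_visits`; subjects with no qualifying visit are dropped with a
#'   warning.
#' @export
average_log_exposure <- function(visits, metabolite, visit_set = 1:3) {
  stopifnot(metabolite %in% names(visits))
  v <- visits[visits$visit %in% visit_set, c("subject_id", metabolite)]
  if (any(v[[metabolite]] <= 0)) stop("non-positive concentration after substitution")
  all_subj <- unique(visits$subject_id)
  agg <- stats::aggregate(
    list(value = log(v[[metabolite]])),
    by = list(subject_id = v$subject_id), FUN = mean
  )
  nv <- stats::aggregate(
    list(n_visits = v[[metabolite]]),
    by = list(subject_id = v$subject_id), FUN = length
  )
  out <- merge(agg, nv, by = "subject_id")
  dropped <- setdiff(all_subj, out$subject_id)
  if (length(dropped)) {
    warning(sprintf("%d subject(s) have no visit in {%s} for %s and were dropped",
                    length(dropped), paste(visit_set, collapse = ","), metabolite))
  }
  out[order(out$subject_id), , drop = FALSE]
}

#' Standardize values by their interquartile range
#'
#' Divides by `IQR = Q3 - Q1` without centering, so model coefficients read
#' as "per IQR increase". The quantile rule defaults to linear interpolation
#' of the empirical CDF (R type 7); optionally weights the quantiles by IPW
#' design weights.
#'
#' @param values numeric vector (at least 4 finite values).
#' @param type quantile algorithm passed to [stats::quantile()].
#' @param weights optional design weights for a weighted IQR.
#' @return list with `values_std` and `iqr`.
#' @export
iqr_standardize <- function(values, type = 7, weights = NULL) {
  v <- values[is.finite(values)]
  if (length(v) < 4) stop("need at least 4 finite values to estimate an IQR")
  qs <- if (is.null(weights)) {
    stats::quantile(v, c(0.25, 0.75), type = type, names = FALSE)
  } else {
    weighted_quantile(values, weights, c(0.25, 0.75))
  }
  iqr <- qs[2] - qs[1]
  if (iqr <= 0) stop("degenerate exposure: IQR is zero")
  list(values_std = values / iqr, iqr = iqr)
}

#' Build the per-subject average-exposure matrix
#'
#' Substitutes non-detects, forms the per-visit molar DEHP sum, and returns
#' per-subject mean log values for the nine metabolites and `sum_dehp`
#' (log nmol/L, averaged across per-visit log molar sums), together with the
#' subjects' mean specific gravity over the same visits.
#'
#' @param visits visit table (censored, pre-substitution).
#' @param lod named detection limits used for substitution.
#' @param visit_set visits entering the averages (default 1-3).
#' @return data frame keyed by `subject_id` with one column per exposure and
#'   `avg_sg`.
#' @export
build_average_exposures <- function(visits, lod, visit_set = 1:3) {
  visits <- substitute_nondetects_visits(visits, lod)
  visits <- add_sum_dehp(visits)
  exposures <- c(names(lod), "sum_dehp")
  out <- NULL
  for (m in exposures) {
    a <- suppressWarnings(average_log_exposure(visits, m, visit_set))
    names(a)[names(a) == "value"] <- m
    a$n_visits <- NULL
    out <- if (is.null(out)) a else merge(out, a, by = "subject_id")
  }
  sgv <- visits[visits$visit %in% visit_set, c("subject_id", "sg")]
  sga <- stats::aggregate(list(avg_sg = sgv$sg),
                          by = list(subject_id = sgv$subject_id), FUN = mean)
  merge(out, sga, by = "subject_id")
}
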