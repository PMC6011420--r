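# Outcome models: inverse-probability-weighted logistic regression for the
# preterm indicator, Cox proportional hazards for time to delivery (everyone
# delivers, so no censoring; Efron handling for day-scale ties), and the
# lognormal accelerated failure time model, which with no censoring is a
# weighted normal regression of log gestational age.
#
# All fitters report robust (sandwich) standard errors by default — required
# for valid inference under design weighting — and retain the model-based
# standard error alongside.

# Shared assembly/fitting core. `X` is a matrix of focal predictor columns
# (one column for a continuous exposure, three indicator columns for
# quartile contrasts); covariates enter reference-coded with the most
# frequent level as reference.
.fit_core <- function(model, X, time = NULL, event = NULL,
                      covariates = NULL, weights = NULL) {
  n <- nrow(X)
  if (is.null(weights)) weights <- rep(1, n)
  stopifnot(all(weights >= 0), length(weights) == n)
  Z <- covariate_matrix(covariates)
  d <- as.data.frame(cbind(X, if (ncol(Z)) Z))
  names(d) <- make.names(names(d))
  preds <- names(d)
  d$.w <- weights
  if (model == "logistic") {
    stopifnot(length(unique(event)) == 2L)
    d$.y <- event
    f <- stats::as.formula(paste(".y ~", paste(preds, collapse = " + ")))
    fit <- stats::glm(f, data = d, weights = .w, family = stats::quasibinomial())
    if (!fit$converged) stop("logistic fit did not converge")
    focal <- make.names(colnames(X))
    if (max(abs(stats::coef(fit)[focal]), na.rm = TRUE) > 15) {
      warning("very large logistic coefficient: possible separation")
    }
    if (any(is.na(stats::coef(fit)))) stop("rank-deficient logistic design")
    vr <- sandwich::vcovHC(fit, type = "HC0")
    vm <- stats::vcov(fit)
  } else if (model == "cox") {
    stopifnot(all(time > 0))
    if (length(unique(time)) < 2L) stop("all event times identical")
    d$.time <- time
    d$.status <- 1
    f <- stats::as.formula(paste("survival::Surv(.time, .status) ~",
                                 paste(preds, collapse = " + ")))
    fit <- survival::coxph(f, data = d, weights = .w, robust = TRUE,
                           ties = "efron")
    vr <- fit$var
    vm <- if (!is.null(fit$naive.var)) fit$naive.var else fit$var
    dimnames(vr) <- dimnames(vm) <- list(names(stats::coef(fit)), names(stats::coef(fit)))
  } else if (model == "aft") {
    stopifnot(all(time > 0))
    d$.time <- time
    f <- stats::as.formula(paste("survival::Surv(.time) ~",
                                 paste(preds, collapse = " + ")))
    fit <- survival::survreg(f, data = d, weights = .w, dist = "lognormal",
                             robust = TRUE)
    cn <- names(stats::coef(fit))
    ix <- seq_along(cn)  # coefficient block precedes Log(scale) in $var
    vr <- fit$var[ix, ix, drop = FALSE]
    vm <- if (!is.null(fit$naive.var)) fit$naive.var[ix, ix, drop = FALSE] else vr
    dimnames(vr) <- dimnames(vm) <- list(cn, cn)
  } else stop("unknown model: ", model)
  list(fit = fit, coef = stats::coef(fit), vr = vr, vm = vm, n = n,
       focal = make.names(colnames(X)))
}

.effect_rows <- function(core, model, label, scales = NULL, level = 0.95) {
  transform <- switch(model,
                      logistic = exp, cox = exp,
                      aft = percent_change)
  rows <- lapply(seq_along(core$focal), function(i) {
    term <- core$focal[i]
    b <- core$coef[[term]]
    se <- sqrt(core$vr[term, term])
    ci <- wald_ci(b, se, level)
    data.frame(
      model = model, exposure = label,
      scale = if (is.null(scales)) "per_IQR" else scales[i],
      n = core$n, coefficient = b, se = se,
      se_model = sqrt(core$vm[term, term]),
      effect = transform(b), ci_low = transform(ci[1]), ci_high = transform(ci[2]),
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' IPW logistic regression of preterm birth on one exposure
#'
#' @param exposure IQR-standardized exposure summary (one value per subject).
#' @param preterm 0/1 preterm indicator.
#' @param covariates data frame of adjustment covariates (factors are
#'   reference-coded against their most frequent level).
#' @param weights IPW design weights (default 1).
#' @param label exposure label recorded in the output.
#' @return one-row data frame: coefficient, robust and model-based SE, odds
#'   ratio and 95% Wald CI on the odds-ratio scale.
#' @export
fit_logistic <- function(exposure, preterm, covariates = NULL, weights = NULL,
                         label = "exposure") {
  X <- matrix(exposure, ncol = 1, dimnames = list(NULL, ".x"))
  core <- .fit_core("logistic", X, event = preterm, covariates = covariates,
                    weights = weights)
  .effect_rows(core, "logistic", label)
}

#' IPW Cox proportional hazards model for time to delivery
#'
#' Every pregnancy ends in delivery, so all times are events. A hazard ratio
#' above one means delivery occurs sooner (shorter gestation).
#'
#' @inheritParams fit_logistic
#' @param time gestational age at delivery in days.
#' @return one-row data frame with the hazard ratio per IQR and 95% CI.
#' @export
fit_cox <- function(exposure, time, covariates = NULL, weights = NULL,
                    label = "exposure") {
  if (stats::var(exposure) == 0) {
    # flat partial likelihood: report a null log hazard by convention
    return(data.frame(model = "cox", exposure = label, scale = "per_IQR",
                      n = length(exposure), coefficient = 0, se = NA_real_,
                      se_model = NA_real_, effect = 1, ci_low = NA_real_,
                      ci_high = NA_real_, stringsAsFactors = FALSE))
  }
  X <- matrix(exposure, ncol = 1, dimnames = list(NULL, ".x"))
  core <- .fit_core("cox", X, time = time, covariates = covariates,
                    weights = weights)
  .effect_rows(core, "cox", label)
}

#' IPW lognormal accelerated failure time model for gestational age
#'
#' With no censoring this is a weighted normal regression of `log(T)`;
#' the coefficient is reported as `100 * (exp(gamma) - 1)`, the percent
#' change in gestational age per IQR of exposure (negative = shorter
#' gestation).
#'
#' @inheritParams fit_cox
#' @return one-row data frame with the percent change per IQR and 95% CI.
#' @export
fit_aft_lognormal <- function(exposure, time, covariates = NULL,
                              weights = NULL, label = "exposure") {
  X <- matrix(exposure, ncol = 1, dimnames = list(NULL, ".x"))
  core <- .fit_core("aft", X, time = time, covariates = covariates,
                    weights = weights)
  .effect_rows(core, "aft", label)
}

#' Percent change in gestational age implied by an AFT coefficient
#' @param gamma log-time coefficient.
#' @return `100 * (exp(gamma) - 1)`.
#' @export
percent_change <- function(gamma) 100 * (exp(gamma) - 1)

#' Quartile-contrast versions of all three outcome models
#'
#' Replaces the continuous exposure with indicator contrasts Q2, Q3, Q4
#' against the lowest quartile Q1 and fits the logistic, Cox and AFT models.
#'
#' @param quartile factor with levels `Q1`-`Q4` (e.g. from
#'   [quartile_categorize()]).
#' @param time gestational age at delivery (days).
#' @param preterm 0/1 preterm indicator.
#' @inheritParams fit_logistic
#' @return data frame with nine rows (three contrasts by three models).
#' @export
fit_quartile_models <- function(quartile, time, preterm, covariates = NULL,
                                weights = NULL, label = "exposure") {
  quartile <- factor(quartile, levels = paste0("Q", 1:4))
  if (any(table(quartile) == 0)) stop("every quartile must contain at least one subject")
  X <- stats::model.matrix(~quartile)[, -1L, drop = FALSE]
  colnames(X) <- paste0("Q", 2:4)
  scales <- colnames(X)
  rows <- list(
    .effect_rows(.fit_core("logistic", X, event = preterm,
                           covariates = covariates, weights = weights),
                 "logistic", label, scales),
    .effect_rows(.fit_core("cox", X, time = time, covariates = covariates,
                           weights = weights), "cox", label, scales),
    .effect_rows(.fit_core("aft", X, time = time, covariates = covariates,
                           weights = weights), "aft", label, scales)
  )
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
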