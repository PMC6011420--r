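# Stage 1 of the two-stage repeated-measures analysis: a random-intercept
# linear mixed model per exposure (or per-visit risk score), with BLUP
# extraction and IQR standardization for use as stage-2 predictors.
#
# REML is the default (unbiased variance components). If the likelihood fit
# fails, a method-of-moments one-way ANOVA estimator (after residualizing on
# the fixed covariates) is used instead, with a warning.

#' Fit a random-intercept linear mixed model to repeated exposure measures
#'
#' Fits `response ~ covariates + (1 | subject)` by REML and extracts the
#' best linear unbiased predictors (BLUPs) of the subject intercepts. The
#' BLUP is a shrinkage estimate of the subject's average deviation: for a
#' pure random-intercept model,
#' `blup_i = (sigma_b^2 / (sigma_b^2 + sigma^2 / n_i)) * (mean residual)`,
#' so subjects with fewer visits are shrunk more towards zero.
#'
#' @param data long-format data frame.
#' @param response name of the response column (e.g. a log concentration or
#'   a per-visit risk score).
#' @param subject name of the subject identifier column.
#' @param covariates names of fixed-effect covariate columns (default:
#'   gestational week at sampling and specific gravity; use `character(0)`
#'   for an intercept-only model).
#' @return object of class `lmm_fit`: fixed effects `phi`, variance
#'   components `sigma_b2` and `sigma2`, a `blups` data frame (`subject`,
#'   `blup`, `n_obs`), the fitting `method` (`"reml"` or `"moments"`), and
#'   `converged`.
#' @export
fit_random_intercept_lmm <- function(data, response = "value",
                                     subject = "subject_id",
                                     covariates = c("gest_week", "sg")) {
  stopifnot(response %in% names(data), subject %in% names(data))
  if (length(unique(data[[subject]])) < 2L) stop("need at least 2 subjects")
  y <- data[[response]]
  if (any(!is.finite(y))) stop("response must be finite")

  rhs <- paste(c(if (length(covariates)) covariates else "1",
                 sprintf("(1 | %s)", subject)), collapse = " + ")
  f <- stats::as.formula(paste(response, "~", rhs))
  # covariates keep their natural units (weeks; specific gravity near 1), so
  # silence lme4's predictor-scale advisory
  ctrl <- lme4::lmerControl(check.scaleX = "ignore")
  fit <- tryCatch(
    suppressMessages(lme4::lmer(f, data = data, REML = TRUE, control = ctrl)),
    error = function(e) NULL
  )
  if (!is.null(fit)) {
    vc <- as.data.frame(lme4::VarCorr(fit))
    sigma_b2 <- vc$vcov[vc$grp == subject]
    sigma2 <- vc$vcov[vc$grp == "Residual"]
    re <- lme4::ranef(fit)[[subject]]
    blups <- data.frame(subject = rownames(re), blup = re[["(Intercept)"]],
                        stringsAsFactors = FALSE)
    nobs <- table(as.character(data[[subject]]))
    blups$n_obs <- as.integer(nobs[blups$subject])
    phi <- lme4::fixef(fit)
    method <- "reml"
  } else {
    warning("mixed-model fit failed; falling back to the moment (ANOVA) estimator")
    mom <- moment_random_intercept(data, response, subject, covariates)
    sigma_b2 <- mom$sigma_b2; sigma2 <- mom$sigma2
    blups <- mom$blups; phi <- mom$phi
    method <- "moments"
  }
  structure(list(phi = phi, sigma_b2 = sigma_b2, sigma2 = sigma2,
                 blups = blups, method = method,
                 converged = !is.null(fit) || method == "moments"),
            class = "lmm_fit")
}

# Method-of-moments estimator for the unbalanced one-way random-effects
# layout, applied to residuals from an ordinary regression on the fixed
# covariates. Standard ANOVA decomposition with n0 = (N - sum(n_i^2)/N)/(a-1).
moment_random_intercept <- function(data, response, subject, covariates) {
  if (length(covariates)) {
    f <- stats::as.formula(paste(response, "~", paste(covariates, collapse = " + ")))
    lmfit <- stats::lm(f, data = data)
    r <- stats::resid(lmfit)
    phi <- stats::coef(lmfit)
  } else {
    mu <- mean(data[[response]])
    r <- data[[response]] - mu
    phi <- c(`(Intercept)` = mu)
  }
  g <- as.character(data[[subject]])
  ni <- table(g)
  a <- length(ni); N <- sum(ni)
  gm <- tapply(r, g, mean)
  ssb <- sum(ni * (gm - mean(r))^2)
  ssw <- sum((r - gm[g])^2)
  msw <- ssw / (N - a)
  msb <- ssb / (a - 1)
  n0 <- (N - sum(ni^2) / N) / (a - 1)
  sigma2 <- msw
  sigma_b2 <- max((msb - msw) / n0, 0)
  lambda <- sigma_b2 / (sigma_b2 + sigma2 / as.numeric(ni))
  blups <- data.frame(subject = names(gm),
                      blup = as.numeric(lambda * (gm - mean(r))),
                      n_obs = as.integer(ni), stringsAsFactors = FALSE)
  list(sigma_b2 = sigma_b2, sigma2 = sigma2, blups = blups, phi = phi)
}

#' Extract IQR-standardized BLUPs from a stage-1 fit
#'
#' @param fit an `lmm_fit`.
#' @param type quantile rule for the IQR (see [iqr_standardize()]).
#' @return the `blups` data frame with an added `blup_std = blup / IQR(blup)`
#'   column; the IQR is stored in `attr(, "iqr")`.
#' @export
extract_blups <- function(fit, type = 7) {
  stopifnot(inherits(fit, "lmm_fit"))
  if (!isTRUE(fit$converged)) stop("stage-1 fit did not converge")
  std <- iqr_standardize(fit$blups$blup, type = type)
  out <- fit$blups
  out$blup_std <- std$values_std
  attr(out, "iqr") <- std$iqr
  out
}

#' One-way ANOVA estimate of the intraclass correlation
#'
#' Moment estimator of `sigma_b^2 / (sigma_b^2 + sigma^2)` from repeated
#' measures, used to check that generated cohorts reproduce their configured
#' ICC.
#'
#' @param values numeric vector of repeated measurements.
#' @param subject subject identifier, same length.
#' @return ICC estimate in `[0, 1]`.
#' @export
icc_anova <- function(values, subject) {
  d <- data.frame(value = values, subject_id = as.character(subject))
  mom <- moment_random_intercept(d, "value", "subject_id", character(0))
  mom$sigma_b2 / (mom$sigma_b2 + mom$sigma2)
}

#' @export
print.lmm_fit <- function(x, ...) {
  cat(sprintf("Random-intercept LMM (%s): sigma_b2 = %.4f, sigma2 = %.4f, %d subjects\n",
              x$method, x$sigma_b2, x$sigma2, nrow(x$blups)))
  invisible(x)
}
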