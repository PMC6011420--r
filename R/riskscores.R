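# Summative phthalate risk scores.
#
# Two subset-selection routes feed two score constructions:
#   * correlation screen ("-Corr"): within each block of mutually highly
#     correlated exposures keep only the member most strongly associated
#     with the outcome, to defuse multicollinearity;
#   * stepwise logistic selection ("-Stepwise"): bidirectional AIC stepwise
#     on the IPW logistic model with covariates forced in.
# ERS weights are unconstrained coefficients from one joint IPW logistic
# model of the selected exposures; WQS weights are non-negative, sum to one,
# and are estimated by bootstrap on quartile-scored exposures with the index
# coefficient constrained to the direction of harm (higher odds of preterm).

#' Correlation-screen subset selection
#'
#' Greedily groups exposures into blocks whose pairwise absolute correlation
#' exceeds `threshold` and retains, within each block, the eligible member
#' with the strongest outcome association. Exposures in no block are all
#' retained (if eligible).
#'
#' @param corr_matrix symmetric correlation matrix with unit diagonal; may
#'   include non-candidate columns (e.g. the molar DEHP sum) that can anchor
#'   blocks but are never retained.
#' @param assoc named association strengths (e.g. absolute z statistics from
#'   single-pollutant Cox fits) for every candidate.
#' @param threshold block-forming correlation threshold (default 0.5).
#' @param candidates names eligible for retention (default: all rows of
#'   `corr_matrix`).
#' @return character vector of retained exposure names, in matrix order.
#' @export
select_by_correlation <- function(corr_matrix, assoc, threshold = 0.5,
                                  candidates = rownames(corr_matrix)) {
  nm <- rownames(corr_matrix)
  stopifnot(!is.null(nm), isTRUE(all.equal(unname(diag(corr_matrix)), rep(1, length(nm)),
                                           tolerance = 1e-6)))
  a <- abs(corr_matrix); diag(a) <- 0
  unassigned <- nm
  blocks <- list()
  repeat {
    sub <- a[unassigned, unassigned, drop = FALSE]
    if (max(sub) <= threshold) break
    ij <- which(sub == max(sub), arr.ind = TRUE)[1, ]
    block <- unassigned[ij]
    repeat {
      rest <- setdiff(unassigned, block)
      if (!length(rest)) break
      # candidates whose correlation with *every* block member exceeds the
      # threshold; add the one with the strongest minimum link
      minlink <- vapply(rest, function(k) min(a[k, block]), numeric(1))
      if (max(minlink) <= threshold) break
      block <- c(block, rest[which.max(minlink)])
    }
    blocks <- c(blocks, list(block))
    unassigned <- setdiff(unassigned, block)
  }
  kept <- intersect(unassigned, candidates)
  for (block in blocks) {
    el <- intersect(block, candidates)
    if (!length(el)) next
    if (any(!el %in% names(assoc))) {
      stop("association strength missing for: ",
           paste(setdiff(el, names(assoc)), collapse = ", "))
    }
    kept <- c(kept, el[which.max(abs(assoc[el]))])
  }
  intersect(nm, kept)
}

#' Stepwise logistic subset selection
#'
#' Bidirectional AIC-based stepwise selection on the IPW logistic model of
#' preterm birth, with the adjustment covariates forced into every model and
#' the candidate exposures free to enter or leave. Deterministic given the
#' input. Exposures producing near-separation (absolute coefficient > 15 in
#' the full model) are dropped with a warning before selection.
#'
#' @param exposures data frame of candidate exposure summaries (columns =
#'   exposures, rows = subjects).
#' @param preterm 0/1 outcome.
#' @param covariates forced-in covariate data frame.
#' @param weights IPW design weights.
#' @return character vector of retained exposure names.
#' @export
select_stepwise <- function(exposures, preterm, covariates = NULL, weights = NULL) {
  stopifnot(length(unique(preterm)) == 2L)
  if (is.null(weights)) weights <- rep(1, length(preterm))
  Z <- covariate_matrix(covariates)
  mets <- make.names(names(exposures))
  d <- as.data.frame(cbind(as.matrix(exposures), if (ncol(Z)) Z))
  names(d) <- make.names(names(d))
  d$.y <- preterm
  d$.w <- weights
  zterms <- setdiff(names(d), c(mets, ".y", ".w"))
  base_rhs <- if (length(zterms)) paste(zterms, collapse = " + ") else "1"
  full <- stats::as.formula(paste(".y ~", paste(c(zterms, mets), collapse = " + ")))
  fit_full <- suppressWarnings(
    stats::glm(full, data = d, weights = .w, family = stats::binomial())
  )
  bad <- mets[abs(stats::coef(fit_full)[mets]) > 15 | is.na(stats::coef(fit_full)[mets])]
  if (length(bad)) {
    warning("dropping exposure(s) with unstable coefficients (possible separation): ",
            paste(bad, collapse = ", "))
    mets <- setdiff(mets, bad)
    full <- stats::as.formula(paste(".y ~", paste(c(zterms, mets), collapse = " + ")))
    fit_full <- suppressWarnings(
      stats::glm(full, data = d, weights = .w, family = stats::binomial())
    )
  }
  lower <- stats::as.formula(paste(".y ~", base_rhs))
  sel <- suppressWarnings(
    stats::step(fit_full, scope = list(lower = lower, upper = full),
                direction = "both", trace = 0)
  )
  kept <- intersect(mets, attr(stats::terms(sel), "term.labels"))
  names(exposures)[make.names(names(exposures)) %in% kept]
}

#' Environmental risk score weights from one joint IPW logistic model
#'
#' Fits a single logistic model of preterm birth on all selected exposures
#' plus covariates and returns the exposure coefficients: the ERS weights.
#'
#' @param exposures data frame of IQR-standardized exposure summaries for the
#'   selected subset.
#' @inheritParams select_stepwise
#' @return named numeric vector of weights (log odds ratios).
#' @export
fit_ers_weights <- function(exposures, preterm, covariates = NULL, weights = NULL) {
  stopifnot(ncol(exposures) >= 1L)
  X <- as.matrix(exposures)
  colnames(X) <- make.names(names(exposures))
  core <- .fit_core("logistic", X, event = preterm, covariates = covariates,
                    weights = weights)
  w <- core$coef[colnames(X)]
  names(w) <- names(exposures)
  w
}

#' Compute an environmental risk score
#'
#' `RS_i = sum_k w_k x_ik`, then IQR-standardized.
#'
#' @param exposures data frame or matrix of exposure summaries.
#' @param weights named weight vector aligned to the exposure columns.
#' @param type quantile rule for the IQR.
#' @return list with `score`, `score_std` and `iqr`.
#' @export
compute_ers <- function(exposures, weights, type = 7) {
  X <- as.matrix(exposures)
  stopifnot(all(names(weights) %in% colnames(X)))
  score <- drop(X[, names(weights), drop = FALSE] %*% weights)
  std <- tryCatch(iqr_standardize(score, type = type), error = function(e) NULL)
  if (is.null(std)) {
    # degenerate (constant or tiny) score: leave unstandardized
    return(list(score = score, score_std = rep(NA_real_, length(score)),
                iqr = NA_real_))
  }
  list(score = score, score_std = std$values_std, iqr = std$iqr)
}

#' Quantile-score an exposure
#'
#' Assigns integer scores `0 .. q-1` using cutpoints at the sample quantiles
#' `i/q`; values tied with a cutpoint go to the lower category, the minimum
#' maps to 0 and the maximum to `q - 1`. Monotone transforms of the input
#' leave scores unchanged.
#'
#' @param values numeric vector with at least `q` distinct values.
#' @param q number of quantile groups (default 4, i.e. quartiles).
#' @param type quantile rule.
#' @return integer vector of scores in `0 .. q-1`.
#' @export
quantile_score <- function(values, q = 4, type = 7) {
  if (length(unique(values)) < q) stop("need at least q distinct values")
  cuts <- stats::quantile(values, probs = seq_len(q - 1) / q, type = type,
                          names = FALSE)
  vapply(values, function(v) sum(v > cuts), numeric(1))
}

#' Weighted quantile sum regression with bootstrap-estimated weights
#'
#' Estimates non-negative exposure weights summing to one for the index
#' `WQS_i = sum_k w_k q_ik` of quantile-scored exposures, by maximizing the
#' IPW logistic likelihood of `preterm ~ beta0 + beta1 * WQS + covariates`
#' on each of `B` bootstrap resamples, with `beta1` constrained to be
#' non-negative (direction of harm = higher odds of preterm birth). Final
#' weights are the mean over converged bootstraps with `beta1 > 0`; if none
#' qualify, all converged bootstraps are averaged with a warning. The index
#' coefficient is then re-estimated on the full data with the weights held
#' fixed.
#'
#' Weights are parameterized on the softmax scale (so the simplex constraint
#' holds exactly) and the likelihood is maximized by L-BFGS-B with an
#' analytic gradient.
#'
#' @param qscores matrix or data frame of quantile scores (columns =
#'   exposures in the selected subset, m >= 2).
#' @param preterm 0/1 outcome.
#' @param covariates adjustment covariate data frame.
#' @param weights IPW design weights.
#' @param B number of bootstrap resamples (default 100).
#' @param seed optional seed for the bootstrap.
#' @return object of class `wqs_fit`: `weights` (the averaged simplex
#'   weights), `index` and `index_std` (IQR-standardized), `iqr`, `beta1`
#'   and its robust `se` from the full-data refit, a `boot` data frame
#'   (per-resample beta1, convergence, inclusion), and `n_used`.
#' @export
fit_wqs <- function(qscores, preterm, covariates = NULL, weights = NULL,
                    B = 100, seed = NULL) {
  Q <- as.matrix(qscores)
  m <- ncol(Q)
  stopifnot(m >= 2L, B >= 2L)
  n <- nrow(Q)
  if (is.null(weights)) weights <- rep(1, n)
  Z <- covariate_matrix(covariates)
  if (ncol(Z)) {
    # standardize for optimizer conditioning; beta1 and the simplex weights
    # are invariant to affine reparametrization of the covariate block
    Z <- scale(Z)
    Z[, attr(Z, "scaled:scale") == 0] <- 0
  }
  if (!is.null(seed)) set.seed(seed)

  boot_beta1 <- numeric(B)
  boot_conv <- logical(B)
  boot_w <- matrix(NA_real_, B, m, dimnames = list(NULL, colnames(Q)))
  for (b in seq_len(B)) {
    idx <- sample.int(n, n, replace = TRUE)
    est <- .wqs_mle(Q[idx, , drop = FALSE], preterm[idx],
                    if (ncol(Z)) Z[idx, , drop = FALSE] else Z, weights[idx])
    boot_beta1[b] <- est$beta1
    boot_conv[b] <- est$converged
    boot_w[b, ] <- est$w
    stopifnot(all(est$w >= -1e-9), abs(sum(est$w) - 1) < 1e-6)
  }
  use <- boot_conv & boot_beta1 > 1e-8
  if (!any(use)) {
    warning("no bootstrap had a positive index coefficient; averaging all converged resamples")
    use <- boot_conv
    if (!any(use)) stop("WQS optimizer failed on every bootstrap resample")
  }
  if (sum(!boot_conv) > B / 2) {
    stop("WQS optimizer failed on more than half of the bootstrap resamples")
  }
  w_bar <- colMeans(boot_w[use, , drop = FALSE])
  w_bar <- w_bar / sum(w_bar)
  index <- drop(Q %*% w_bar)
  std <- iqr_standardize(index)
  refit <- fit_logistic(std$values_std, preterm, covariates, weights,
                        label = "wqs_index")
  structure(list(weights = w_bar, index = index, index_std = std$values_std,
                 iqr = std$iqr, beta1 = refit$coefficient, se = refit$se,
                 boot = data.frame(beta1 = boot_beta1, converged = boot_conv,
                                   used = use),
                 n_used = sum(use), B = B),
            class = "wqs_fit")
}

# Constrained MLE for one (bootstrap) dataset. Parameters: beta0, beta1
# (box-constrained >= 0), covariate slopes, and m softmax scores theta
# (first fixed at 0 for identifiability).
.wqs_mle <- function(Q, y, Z, a) {
  m <- ncol(Q); pz <- if (is.null(dim(Z))) 0L else ncol(Z)
  softw <- function(theta) {
    e <- exp(c(0, theta) - max(c(0, theta)))
    e / sum(e)
  }
  unpack <- function(p) {
    list(b0 = p[1], b1 = p[2],
         phi = if (pz) p[2 + seq_len(pz)] else numeric(0),
         w = softw(p[-seq_len(2 + pz)]))
  }
  eta_of <- function(pr) {
    s <- drop(Q %*% pr$w)
    pr$b0 + pr$b1 * s + if (pz) drop(Z %*% pr$phi) else 0
  }
  log1pexp <- function(x) ifelse(x > 0, x + log1p(exp(-x)), log1p(exp(x)))
  nll <- function(p) {
    pr <- unpack(p)
    eta <- eta_of(pr)
    -sum(a * (y * eta - log1pexp(eta)))
  }
  grad <- function(p) {
    pr <- unpack(p)
    s <- drop(Q %*% pr$w)
    eta <- pr$b0 + pr$b1 * s + if (pz) drop(Z %*% pr$phi) else 0
    r <- a * (y - stats::plogis(eta))
    g_b0 <- sum(r)
    g_b1 <- sum(r * s)
    g_phi <- if (pz) drop(crossprod(Z, r)) else numeric(0)
    gk <- drop(crossprod(Q, r))           # d ll / d s through each column
    gw <- pr$b1 * pr$w * (gk - sum(pr$w * gk))
    -c(g_b0, g_b1, g_phi, gw[-1])
  }
  p0 <- c(stats::qlogis(min(max(stats::weighted.mean(y, a), 1e-3), 1 - 1e-3)),
          0.1, rep(0, pz), rep(0, m - 1))
  lower <- c(-Inf, 0, rep(-Inf, pz + m - 1))
  opt <- tryCatch(
    stats::optim(p0, nll, grad, method = "L-BFGS-B", lower = lower,
                 control = list(maxit = 1000)),
    error = function(e) NULL
  )
  if (is.null(opt)) {
    return(list(beta1 = NA_real_, w = rep(1 / m, m), converged = FALSE))
  }
  pr <- unpack(opt$par)
  list(beta1 = pr$b1, w = pr$w, converged = opt$convergence == 0)
}

#' Categorize a risk score into IPW-weighted quartiles
#'
#' Cutpoints are the weighted 25/50/75th percentiles of the score (see
#' [weighted_quantile()]; with uniform weights they reduce to the ordinary
#' sample quartiles). Ties at a cutpoint fall in the lower category; Q1 is
#' the reference.
#'
#' @param score numeric risk-score vector (>= 4 distinct values).
#' @param weights IPW design weights (default uniform).
#' @return factor with levels `Q1`-`Q4`; cutpoints in `attr(, "cuts")`.
#' @export
quartile_categorize <- function(score, weights = NULL) {
  if (length(unique(score)) < 4L) stop("need at least 4 distinct score values")
  cuts <- weighted_quantile(score, weights, c(0.25, 0.5, 0.75))
  if (any(diff(cuts) <= 0)) stop("degenerate quartile cutpoints")
  cat <- factor(paste0("Q", 1 + vapply(score, function(v) sum(v > cuts), numeric(1))),
                levels = paste0("Q", 1:4))
  attr(cat, "cuts") <- cuts
  cat
}

#' @export
print.wqs_fit <- function(x, ...) {
  cat(sprintf("WQS fit: %d exposures, beta1 = %.3f (se %.3f), %d/%d bootstraps used\n",
              length(x$weights), x$beta1, x$se, x$n_used, x$B))
  print(round(x$weights, 3))
  invisible(x)
}
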