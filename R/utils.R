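# Small shared numerical helpers.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Weighted sample quantiles consistent with integer-weight replication
#'
#' Computes quantiles of `x` with non-negative weights `w` such that, for
#' integer weights, the result equals `stats::quantile(rep(x, w), type = 7)`.
#' The sorted values are laid out on an expanded axis of length `sum(w)` and
#' the type-7 plotting position `h = (sum(w) - 1) * p + 1` is interpolated
#' linearly between the values covering adjacent integer positions.
#'
#' @param x numeric vector.
#' @param w non-negative weights, recycled to `length(x)`; `NULL` means
#'   uniform weights, in which case the result equals `quantile(x, type = 7)`.
#' @param probs probabilities in `[0, 1]`.
#' @return numeric vector of quantiles, one per element of `probs`.
#' @export
weighted_quantile <- function(x, w = NULL, probs) {
  stopifnot(is.numeric(x), length(x) > 0L, all(is.finite(x)))
  if (is.null(w)) w <- rep(1, length(x))
  w <- rep_len(as.numeric(w), length(x))
  if (any(w < 0) || all(w == 0)) stop("weights must be non-negative with positive sum")
  keep <- w > 0
  x <- x[keep]; w <- w[keep]
  ord <- order(x)
  x <- x[ord]; w <- w[ord]
  cw <- cumsum(w)
  N <- cw[length(cw)]
  # value occupying (possibly fractional) position m on the expanded axis
  val_at <- function(m) {
    m <- min(max(m, 1), N)
    x[which(cw >= m - 1e-12)[1L]]
  }
  vapply(probs, function(p) {
    h <- (N - 1) * p + 1
    lo <- floor(h); hi <- ceiling(h)
    vlo <- val_at(lo); vhi <- val_at(hi)
    vlo + (h - lo) * (vhi - vlo)
  }, numeric(1))
}

# Wald CI limits on the coefficient scale.
wald_ci <- function(est, se, level = 0.95) {
  z <- stats::qnorm(1 - (1 - level) / 2)
  c(est - z * se, est + z * se)
}

# Reference-coded model matrix for the standard covariate set; reference level
# of each factor is its most frequent level in the supplied data.
covariate_matrix <- function(covariates) {
  if (is.null(covariates) || ncol(covariates) == 0L) {
    return(matrix(numeric(0), nrow = if (is.null(covariates)) 0L else nrow(covariates), ncol = 0L))
  }
  cols <- lapply(names(covariates), function(nm) {
    v <- covariates[[nm]]
    if (is.numeric(v)) {
      m <- matrix(v, ncol = 1, dimnames = list(NULL, nm))
      return(m)
    }
    f <- as.factor(v)
    ref <- names(sort(table(f), decreasing = TRUE))[1L]
    f <- stats::relevel(f, ref = ref)
    mm <- stats::model.matrix(~f)[, -1L, drop = FALSE]
    colnames(mm) <- paste0(nm, sub("^f", "_", colnames(mm)))
    mm
  })
  do.call(cbind, cols)
}
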