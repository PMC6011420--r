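# Independent oracles and small fixture builders shared across tests.

# Exact Cox partial log-likelihood for untied event times (every subject an
# event), maximized on a fine grid: the brute-force oracle for fit_cox.
cox_partial_loglik <- function(alpha, x, time) {
  ord <- order(time)
  x <- x[ord]
  n <- length(x)
  ll <- 0
  for (i in seq_len(n)) {
    risk <- i:n  # still pregnant at the i-th delivery
    ll <- ll + alpha * x[i] - log(sum(exp(alpha * x[risk])))
  }
  ll
}

cox_grid_mle <- function(x, time, grid = seq(-5, 5, by = 5e-4)) {
  ll <- vapply(grid, cox_partial_loglik, numeric(1), x = x, time = time)
  grid[which.max(ll)]
}

# Closed-form balanced one-way random-effects ANOVA estimators.
anova_oneway <- function(y, g) {
  ni <- table(g)
  stopifnot(length(unique(ni)) == 1L)
  k <- as.numeric(ni[1])
  a <- length(ni)
  gm <- tapply(y, g, mean)
  msb <- k * sum((gm - mean(y))^2) / (a - 1)
  msw <- sum((y - gm[as.character(g)])^2) / (a * (k - 1))
  list(sigma2 = msw, sigma_b2 = (msb - msw) / k, means = gm)
}

# Balanced random-intercept data with known variance components.
make_balanced_lmm <- function(n_subj, n_visit, sigma_b = 1, sigma = 1, seed = 1) {
  set.seed(seed)
  b <- rnorm(n_subj, 0, sigma_b)
  data.frame(
    subject_id = rep(seq_len(n_subj), each = n_visit),
    value = rep(b, each = n_visit) + rnorm(n_subj * n_visit, 0, sigma)
  )
}

# Small case-control-style dataset with a known logistic structure.
make_logistic_data <- function(n = 500, beta = 0.5, seed = 1) {
  set.seed(seed)
  x <- rnorm(n)
  z <- data.frame(age = rnorm(n, 30, 5), grp = sample(c("a", "b"), n, TRUE))
  eta <- -2 + beta * x + 0.02 * (z$age - 30) + 0.3 * (z$grp == "b")
  y <- rbinom(n, 1, plogis(eta))
  list(x = x, y = y, z = z)
}

# A fast ground truth for pipeline-level tests.
small_truth <- function(n = 600, seed = 11, ...) {
  sim_truth(n_subjects = n, seed = seed, ...)
}
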