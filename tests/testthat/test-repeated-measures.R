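test_that("REML recovers variance components on balanced data", {
  d <- make_balanced_lmm(500, 3, sigma_b = 1, sigma = 1, seed = 7)
  fit <- fit_random_intercept_lmm(d, covariates = character(0))
  ratio <- fit$sigma_b2 / (fit$sigma_b2 + fit$sigma2)
  expect_lt(abs(ratio - 0.5), 0.06)
})

test_that("balanced-data REML matches the closed-form ANOVA estimators", {
  d <- make_balanced_lmm(60, 4, sigma_b = 1.3, sigma = 0.8, seed = 3)
  fit <- fit_random_intercept_lmm(d, covariates = character(0))
  oracle <- anova_oneway(d$value, d$subject_id)
  expect_equal(fit$sigma2, oracle$sigma2, tolerance = 1e-6)
  expect_equal(fit$sigma_b2, oracle$sigma_b2, tolerance = 1e-6)
  # BLUPs equal the shrinkage formula applied to subject mean deviations
  lambda <- oracle$sigma_b2 / (oracle$sigma_b2 + oracle$sigma2 / 4)
  dev <- oracle$means - mean(d$value)
  expect_equal(fit$blups$blup[match(names(dev), fit$blups$subject)],
               as.numeric(lambda * dev), tolerance = 1e-6)
})

test_that("no between-subject signal gives near-zero variance and BLUPs", {
  set.seed(5)
  visit_effect <- c(0, 1, 2)
  d <- data.frame(subject_id = rep(1:80, each = 3),
                  gest_week = rep(c(10, 18, 26), 80),
                  sg = 1.015,
                  value = rep(visit_effect, 80) + rnorm(240, 0, 0.3))
  fit <- fit_random_intercept_lmm(d, covariates = "gest_week")
  expect_lt(fit$sigma_b2, 0.02)
  expect_lt(max(abs(fit$blups$blup)), 0.15)
})

test_that("BLUP shrinkage is stronger for subjects with fewer visits", {
  set.seed(9)
  # background subjects plus two probes with identical raw deviation +2
  d <- make_balanced_lmm(100, 3, sigma_b = 1, sigma = 1, seed = 9)
  probe1 <- data.frame(subject_id = 9001, value = mean(d$value) + 2)
  probe3 <- data.frame(subject_id = 9003,
                       value = rep(mean(d$value) + 2, 3))
  dd <- rbind(d, probe1, probe3)
  fit <- fit_random_intercept_lmm(dd, covariates = character(0))
  b1 <- fit$blups$blup[fit$blups$subject == "9001"]
  b3 <- fit$blups$blup[fit$blups$subject == "9003"]
  expect_lt(abs(b1), abs(b3))
  expect_gt(b1, 0)
})

test_that("BLUP spread grows with between-subject variance per the shrinkage formula", {
  f1 <- fit_random_intercept_lmm(
    make_balanced_lmm(800, 3, sigma_b = 1, sigma = 1, seed = 31),
    covariates = character(0))
  f2 <- fit_random_intercept_lmm(
    make_balanced_lmm(800, 3, sigma_b = sqrt(2), sigma = 1, seed = 32),
    covariates = character(0))
  # var(blup) = lambda^2 (sigma_b^2 + sigma^2/k): ratio 2.28 at these values
  ratio <- var(f2$blups$blup) / var(f1$blups$blup)
  expect_gt(ratio, 1.9)
  expect_lt(ratio, 2.7)
})

test_that("extract_blups standardizes by the BLUP IQR", {
  d <- make_balanced_lmm(50, 3, seed = 13)
  fit <- fit_random_intercept_lmm(d, covariates = character(0))
  bl <- extract_blups(fit)
  expect_equal(bl$blup_std * attr(bl, "iqr"), bl$blup, tolerance = 1e-10)
  # degenerate case: all BLUPs identical
  fit$blups$blup <- rep(0, nrow(fit$blups))
  expect_error(extract_blups(fit), "IQR")
})

test_that("moment fallback agrees with REML on clean balanced data", {
  d <- make_balanced_lmm(80, 3, sigma_b = 1.1, sigma = 0.9, seed = 17)
  reml <- fit_random_intercept_lmm(d, covariates = character(0))
  mom <- phthalmix:::moment_random_intercept(d, "value", "subject_id", character(0))
  expect_equal(reml$sigma_b2, mom$sigma_b2, tolerance = 1e-6)
  expect_equal(reml$sigma2, mom$sigma2, tolerance = 1e-6)
})

test_that("stage-2 coefficients from BLUPs are noisier than from raw means", {
  # same cohorts, two exposure summaries; BLUP route must inflate sampling
  # variance of the outcome coefficient (the attenuation mechanism)
  set.seed(71)
  n <- 150; k <- 3
  coef_mean <- coef_blup <- numeric(120)
  for (r in 1:120) {
    b <- rnorm(n)
    x <- matrix(b, n, k) + matrix(rnorm(n * k), n, k)
    logt <- 5.62 - 0.03 * b + 0.02 * rnorm(n)
    d <- data.frame(subject_id = rep(1:n, each = k), value = as.vector(t(x)))
    fit <- fit_random_intercept_lmm(d, covariates = character(0))
    bl <- fit$blups$blup[match(as.character(1:n), fit$blups$subject)]
    t_days <- exp(logt)
    coef_mean[r] <- fit_aft_lognormal(rowMeans(x), t_days)$coefficient
    coef_blup[r] <- fit_aft_lognormal(bl, t_days)$coefficient
  }
  expect_gt(var(coef_blup), var(coef_mean))
})
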