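test_that("non-detect substitution follows the LOD/sqrt(2) rule and is idempotent", {
  expect_equal(substitute_nondetects(1.0, FALSE, 1.0), 1 / sqrt(2), tolerance = 1e-10)
  expect_identical(substitute_nondetects(5.0, TRUE, 1.0), 5.0)
  expect_equal(substitute_nondetects(sqrt(2), FALSE, sqrt(2)), 1.0, tolerance = 1e-12)
  # substituting twice equals substituting once (flags unchanged)
  conc <- c(0.5, 3, 0.2); det <- c(FALSE, TRUE, FALSE)
  once <- substitute_nondetects(conc, det, 0.5)
  expect_identical(substitute_nondetects(once, det, 0.5), once)
})

test_that("specific-gravity correction matches the dilution formula", {
  expect_equal(sg_correct(10, 1.015), 10)          # at the median SG: identity
  expect_equal(sg_correct(10, 1.030), 5.0)         # 10 * 0.015 / 0.030
  expect_equal(sg_correct(0, 1.020), 0)
  expect_error(sg_correct(10, 1.0), "singular")
  expect_error(sg_correct(10, 0.99), "singular")
  # homogeneous of degree 1 in the concentration
  p <- runif(20, 0.1, 50); sg <- runif(20, 1.005, 1.03)
  expect_equal(sg_correct(3.7 * p, sg), 3.7 * sg_correct(p, sg), tolerance = 1e-12)
})

test_that("molar DEHP sum converts by molecular weight", {
  expect_equal(molar_sum_dehp(2.7834, 0, 0, 0), 10.0, tolerance = 1e-10)
  expect_identical(molar_sum_dehp(0, 0, 0, 0), 0)
  # at equal mass concentration the heaviest metabolite contributes least
  contrib <- c(molar_sum_dehp(1, 0, 0, 0), molar_sum_dehp(0, 1, 0, 0),
               molar_sum_dehp(0, 0, 1, 0), molar_sum_dehp(0, 0, 0, 1))
  expect_identical(which.min(contrib), 4L)  # MECPP, MW 308.33
  expect_error(molar_sum_dehp(-1, 0, 0, 0), "non-negative")
})

test_that("visit averaging uses natural logs over the configured visits", {
  visits <- data.frame(
    subject_id = c(1, 1, 1, 1, 2, 2),
    visit = c(1, 2, 3, 4, 1, 2),
    mecpp = c(exp(1), exp(1), exp(1), exp(9), 1, exp(2))
  )
  out <- average_log_exposure(visits, "mecpp")
  expect_equal(out$value[out$subject_id == 1], 1.0)  # visit 4 ignored
  expect_equal(out$value[out$subject_id == 2], 1.0)  # mean of (0, 2)
  expect_identical(out$n_visits, c(3L, 2L))
  # a subject with no qualifying visit is dropped with a warning
  visits2 <- rbind(visits, data.frame(subject_id = 3, visit = 4, mecpp = 5))
  expect_warning(out2 <- average_log_exposure(visits2, "mecpp"), "dropped")
  expect_false(3 %in% out2$subject_id)
  visits$mecpp[1] <- 0
  expect_error(average_log_exposure(visits, "mecpp"), "non-positive")
})

test_that("scaling all concentrations shifts the mean log by log(c)", {
  visits <- data.frame(subject_id = rep(1:5, each = 3), visit = rep(1:3, 5),
                       mecpp = exp(rnorm(15)))
  base <- average_log_exposure(visits, "mecpp")
  visits$mecpp <- visits$mecpp * 7
  shifted <- average_log_exposure(visits, "mecpp")
  expect_equal(shifted$value, base$value + log(7), tolerance = 1e-12)
})

test_that("IQR standardization divides by the type-7 interquartile range", {
  s <- iqr_standardize(1:8)
  # type-7 positions for n = 8: Q1 at 2.75, Q3 at 6.25 (linear interpolation)
  expect_equal(s$iqr, 3.5)
  expect_equal(s$values_std[8], 8 / 3.5)
  # scale equivariance: values_std invariant under multiplication
  v <- rexp(40)
  s1 <- iqr_standardize(v); s2 <- iqr_standardize(10 * v)
  expect_equal(s2$iqr, 10 * s1$iqr, tolerance = 1e-12)
  expect_equal(s2$values_std, s1$values_std, tolerance = 1e-12)
  expect_error(iqr_standardize(rep(2, 10)), "IQR")
  expect_error(iqr_standardize(c(1, 2, 3)), "at least 4")
})

test_that("weighted quantiles agree with integer-weight replication", {
  set.seed(2)
  for (rep in 1:5) {
    x <- rnorm(30)
    w <- sample(1:4, 30, replace = TRUE)
    probs <- c(0.1, 0.25, 0.5, 0.75, 0.9)
    expect_equal(weighted_quantile(x, w, probs),
                 unname(quantile(rep(x, w), probs, type = 7)),
                 tolerance = 1e-10)
    # unit weights reduce to the ordinary type-7 quantile
    expect_equal(weighted_quantile(x, NULL, probs),
                 unname(quantile(x, probs, type = 7)), tolerance = 1e-12)
  }
})
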