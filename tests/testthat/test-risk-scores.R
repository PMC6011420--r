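test_that("correlation screen keeps one member per block plus all singletons", {
  mets <- phthalate_metabolites()
  labs <- c(mets, "sum_dehp")
  corr <- matrix(0.2, 10, 10, dimnames = list(labs, labs))
  block <- c(dehp_metabolites(), "sum_dehp")   # five mutually correlated columns
  corr[block, block] <- 0.8
  diag(corr) <- 1
  assoc <- setNames(c(1.2, 0.8, 0.9, 2.5, 1.1, 1.0, 0.3, 0.4, 0.9), mets)
  kept <- select_by_correlation(corr, assoc, threshold = 0.5, candidates = mets)
  expect_identical(kept, c("mecpp", "mbzp", "mbp", "mibp", "mep", "mcpp"))
  expect_length(kept, 6L)
  # never two members of one block
  expect_identical(intersect(kept, dehp_metabolites()), "mecpp")

  ident <- diag(9); dimnames(ident) <- list(mets, mets)
  expect_identical(select_by_correlation(ident, assoc), mets)
  expect_identical(select_by_correlation(corr, assoc, threshold = 0.9,
                                         candidates = mets), mets)
  expect_error(select_by_correlation(corr, assoc[-4], candidates = mets),
               "missing")
})

test_that("stepwise selection retains a strong predictor and is deterministic", {
  set.seed(19)
  n <- 800
  x <- as.data.frame(matrix(rnorm(n * 6), n, 6))
  names(x) <- paste0("met", 1:6)
  y <- rbinom(n, 1, plogis(-2 + 0.8 * x$met4))
  z <- data.frame(age = rnorm(n, 30, 5))
  s1 <- select_stepwise(x, y, z)
  s2 <- select_stepwise(x, y, z)
  expect_identical(s1, s2)
  expect_true("met4" %in% s1)
})

test_that("ERS weights equal the joint logistic coefficients and score is a dot product", {
  d <- make_logistic_data(n = 400, beta = 0.6, seed = 23)
  ex <- data.frame(a = d$x, b = rnorm(400))
  w <- fit_ers_weights(ex, d$y, d$z)
  ref <- glm(d$y ~ ex$a + ex$b + d$z$age + I(d$z$grp == "b"),
             family = binomial())
  expect_equal(unname(w), unname(coef(ref)[2:3]), tolerance = 1e-6)

  # dot-product definition (tiny input: score exact, no IQR available)
  ers <- compute_ers(data.frame(a = c(2, 1), b = c(4, 0)),
                     c(a = 0.5, b = 0.25))
  expect_equal(ers$score, c(2.0, 0.5))
  expect_true(is.na(ers$iqr))
  # zero weights give the zero score (degenerate, no IQR)
  ers0 <- compute_ers(data.frame(a = c(2, 1), b = c(4, 0)), c(a = 0, b = 0))
  expect_identical(ers0$score, c(0, 0))
  # a single-exposure score is proportional to that exposure
  ers1 <- compute_ers(data.frame(a = rnorm(10)), c(a = 1))
  expect_equal(cor(ers1$score_std, ers1$score), 1, tolerance = 1e-12)
  # perfect collinearity is a rank-deficiency error
  ex$c <- ex$a
  expect_error(fit_ers_weights(ex, d$y, d$z), "rank-deficient")
})

test_that("ERS is equivariant under reciprocal scaling of exposures and weights", {
  set.seed(4)
  ex <- as.data.frame(matrix(rexp(60), 20, 3))
  names(ex) <- c("a", "b", "c")
  w <- c(a = 0.4, b = -0.2, c = 0.1)
  s1 <- compute_ers(ex, w)
  s2 <- compute_ers(ex * 5, w / 5)
  expect_equal(s1$score, s2$score, tolerance = 1e-12)
})

test_that("quantile scoring maps values to quartile integers with ties going low", {
  expect_identical(quantile_score(1:8, q = 4), c(0, 0, 1, 1, 2, 2, 3, 3))
  v <- rexp(50)
  qs <- quantile_score(v, q = 4)
  expect_identical(qs[which.min(v)], 0)
  expect_identical(qs[which.max(v)], 3)
  # rank invariance under monotone transforms
  expect_identical(quantile_score(exp(v), q = 4), qs)
  expect_error(quantile_score(rep(1:3, 5), q = 4), "distinct")
})

test_that("WQS bootstrap weights satisfy the simplex constraint and find the signal", {
  set.seed(41)
  n <- 600
  x <- matrix(rnorm(n * 4), n, 4, dimnames = list(NULL, paste0("m", 1:4)))
  q <- apply(x, 2, quantile_score, q = 4)
  y <- rbinom(n, 1, plogis(-2 + 0.7 * x[, 1]))
  z <- data.frame(age = rnorm(n, 30, 5))
  wf <- fit_wqs(q, y, z, B = 30, seed = 6)
  expect_s3_class(wf, "wqs_fit")
  expect_true(all(wf$weights >= 0))
  expect_equal(sum(wf$weights), 1, tolerance = 1e-6)
  expect_identical(names(which.max(wf$weights)), "m1")
  expect_gt(wf$beta1, 0)
  expect_true(all(wf$boot$converged))
  expect_equal(wf$index_std * wf$iqr, wf$index, tolerance = 1e-10)
  expect_error(fit_wqs(q[, 1, drop = FALSE], y, z, B = 10), "m >= 2")
})

test_that("weighted quartile cutpoints reduce to sample quartiles under uniform weights", {
  set.seed(3)
  v <- rnorm(101)
  cat_u <- quartile_categorize(v)
  expect_equal(attr(cat_u, "cuts"),
               unname(quantile(v, c(0.25, 0.5, 0.75), type = 7)),
               tolerance = 1e-10)
  tab <- table(cat_u)
  expect_lte(max(tab) - min(tab), 1)
  # integer-weight replication oracle
  w <- sample(1:3, 101, replace = TRUE)
  cat_w <- quartile_categorize(v, w)
  expect_equal(attr(cat_w, "cuts"),
               unname(quantile(rep(v, w), c(0.25, 0.5, 0.75), type = 7)),
               tolerance = 1e-10)
  expect_error(quartile_categorize(rep(1:2, 10)), "distinct")
})
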