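test_that("generator is seed-deterministic and respects structural invariants", {
  tr <- small_truth(n = 300, seed = 42)
  c1 <- generate_full_cohort(tr)
  c2 <- generate_full_cohort(tr)
  expect_identical(c1$subjects, c2$subjects)
  expect_identical(c1$visits, c2$visits)

  mets <- phthalate_metabolites()
  expect_true(all(as.matrix(c1$visits[mets]) > 0))
  expect_identical(c1$subjects$preterm, as.integer(c1$subjects$T_days < 259))
  # four visits per subject before attrition
  expect_identical(as.integer(table(c1$visits$visit)),
                   rep(nrow(c1$subjects), 4L))
  # visit timing jitter stays inside the configured windows
  for (j in 1:4) {
    wk <- c1$visits$gest_week[c1$visits$visit == j]
    expect_true(all(abs(wk - tr$visit_weeks[j]) <= tr$visit_jitter[j] + 1e-9))
  }
  expect_true(all(c1$visits$sg > 1))
})

test_that("invalid truth configurations are rejected", {
  expect_error(sim_truth(icc = rep(1.2, 9)), "icc")
  bad_cor <- matrix(0.9, 9, 9); diag(bad_cor) <- 1
  bad_cor[1, 2] <- -0.9  # breaks positive semi-definiteness
  bad_cor[2, 1] <- -0.9
  expect_error(sim_truth(cor_between = bad_cor), "positive semi-definite")
  expect_error(sim_truth(visit_weeks = c(10, 9, 26, 35)), "increasing")
  expect_error(sim_truth(sg_center = 0.99), "sg_center")
})

test_that("generated log concentrations reproduce the configured ICC", {
  tr <- sim_truth(n_subjects = 2000, icc = rep(0.5, 9), seed = 5)
  coh <- generate_full_cohort(tr)
  for (m in phthalate_metabolites()) {
    icc_hat <- icc_anova(log(coh$visits[[m]]), coh$visits$subject_id)
    expect_gt(icc_hat, 0.42)
    expect_lt(icc_hat, 0.58)
  }
})

test_that("between-subject correlation of visit means matches the attenuated target", {
  tr <- sim_truth(n_subjects = 2000, seed = 8)
  coh <- generate_full_cohort(tr)
  mets <- phthalate_metabolites()
  means <- sapply(mets, function(m)
    tapply(log(coh$visits[[m]]), coh$visits$subject_id, mean))
  # covariance of 4-visit means: between-subject part plus (correlated visit
  # noise + shared dilution term) divided by the number of visits
  var_b <- diag(tr$cov_log)
  var_w <- var_b * (1 / tr$icc - 1)
  var_d <- phthalmix:::dilution_log_variance(tr)
  cov_w <- phthalmix:::visit_noise_cov(tr) + var_d
  cov_means <- tr$cov_log + cov_w / 4
  expected <- cov_means / outer(sqrt(var_b + var_w / 4), sqrt(var_b + var_w / 4))
  diag(expected) <- 1
  expect_lt(max(abs(cor(means) - expected)), 0.06)
  # the DEHP block shows the strong observed pairwise correlation
  dehp <- dehp_metabolites()
  obs <- cor(means)[dehp, dehp]
  expect_gt(min(obs[upper.tri(obs)]), 0.5)
})

test_that("null effects leave exposure and outcome uncorrelated", {
  zn <- c("maternal_age_c", "insurance_public", "race_black", "race_asian",
          "race_other", "edu_highschool", "edu_graduate", "edu_technical")
  tr <- sim_truth(n_subjects = 2000, outcome_mode = "aft_lognormal",
                  gamma_true = rep(0, 9),
                  covariate_effects = list(
                    log_time = setNames(rep(0, 8), zn),
                    preterm_logit = setNames(rep(0, 8), zn)), seed = 3)
  coh <- generate_full_cohort(tr)
  for (m in c("mecpp", "mep")) {
    xbar <- tapply(log(coh$visits[[m]][coh$visits$visit <= 3]),
                   coh$visits$subject_id[coh$visits$visit <= 3], mean)
    expect_lt(abs(cor(xbar, log(coh$subjects$T_days))), 3 / sqrt(2000))
  }
})

test_that("default mixture outcome hits the preterm fraction and is left-skewed", {
  coh <- generate_full_cohort(sim_truth(n_subjects = 2000, seed = 21))
  frac <- mean(coh$subjects$preterm)
  expect_lt(abs(frac - 0.110), 0.02)
  t_days <- coh$subjects$T_days
  skew <- mean((t_days - mean(t_days))^3) / sd(t_days)^3
  expect_lt(skew, -0.5)
})

test_that("attrition removes post-delivery visits and spares visit 1", {
  visits <- data.frame(subject_id = rep(1:2, each = 4), visit = rep(1:4, 2),
                       gest_week = rep(c(9.7, 17.9, 26.0, 35.1), 2),
                       sg = 1.015)
  outcomes <- data.frame(subject_id = 1:2, T_days = c(230, 280))
  kept <- apply_visit_attrition(visits, outcomes, rep(0, 4))
  # 35.1 wk = 245.7 d >= 230 d: visit 4 impossible for the preterm subject
  expect_false(any(kept$subject_id == 1 & kept$visit == 4))
  expect_identical(nrow(kept[kept$subject_id == 2, ]), 4L)
  expect_error(apply_visit_attrition(visits, outcomes, c(0.1, 0, 0, 0)),
               "visit 1")
})

test_that("preterm subjects have lower visit-4 availability than term subjects", {
  tr <- small_truth(n = 1500, seed = 13)
  coh <- generate_full_cohort(tr)
  set.seed(99)
  vis <- apply_visit_attrition(coh$visits, coh$subjects)
  has4 <- tapply(vis$visit, vis$subject_id, function(v) as.integer(4 %in% v))
  status <- coh$subjects$preterm[match(as.integer(names(has4)),
                                       coh$subjects$subject_id)]
  expect_lt(mean(has4[status == 1]), mean(has4[status == 0]))
})

test_that("nested case-control sampling reproduces the printed design weight", {
  # 130 cases; 1061 non-cases of whom 10 have only a visit-1 sample
  n <- 1191
  outcomes <- data.frame(subject_id = seq_len(n),
                         T_days = c(rep(250, 130), rep(280, n - 130)))
  outcomes$preterm <- as.integer(outcomes$T_days < 259)
  v1 <- data.frame(subject_id = seq_len(n), visit = 1)
  v2 <- data.frame(subject_id = setdiff(seq_len(n), 131:140), visit = 2)
  visits <- rbind(v1, v2)

  out <- sample_nested_case_control(outcomes, visits, n_controls = 352, seed = 4)
  expect_true(all(out$sampled[out$preterm == 1]))
  expect_identical(unique(out$w[out$preterm == 1]), 1)
  ctrl_w <- unique(out$w[out$sampled & out$preterm == 0])
  expect_equal(ctrl_w, 1051 / 352, tolerance = 1e-12)
  # weight identity: weights reconstruct cases + eligible non-cases
  expect_equal(sum(out$w), 130 + 1051, tolerance = 1e-9)
  # ineligible non-cases (visit 1 only) are never sampled as controls
  for (s in 1:5) {
    draw <- sample_nested_case_control(outcomes, visits, 352, seed = s)
    expect_false(any(draw$sampled[draw$subject_id %in% 131:140]))
  }
  # census of the eligible pool gives unit weights
  census <- sample_nested_case_control(outcomes, visits, n_controls = 1051, seed = 1)
  expect_true(all(census$w[census$sampled] == 1))
  expect_error(sample_nested_case_control(outcomes, visits, 1052), "exceeds")
})

test_that("LOD censoring flags strictly-below values and keeps boundary detections", {
  visits <- data.frame(subject_id = 1:3, visit = 1, gest_week = 10, sg = 1.015,
                       mehp = c(0.3, 0.5, 2.0), det_mehp = TRUE)
  cen <- censor_at_lod(visits, c(mehp = 0.5))
  expect_identical(cen$det_mehp, c(FALSE, TRUE, TRUE))
  expect_identical(cen$mehp, c(0.5, 0.5, 2.0))
})

test_that("default detection limits reproduce the targeted non-detect fractions", {
  tr <- sim_truth(n_subjects = 2000, seed = 17)
  coh <- generate_full_cohort(tr)
  cen <- censor_at_lod(coh$visits, default_lod(tr))
  expect_lt(abs(mean(!cen$det_mehp) - 0.047), 0.015)
  others <- setdiff(phthalate_metabolites(), "mehp")
  nd <- vapply(others, function(m) mean(!cen[[paste0("det_", m)]]), numeric(1))
  expect_true(all(nd < 0.03))
})
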