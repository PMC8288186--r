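test_that("standardized weights have HW mean zero and unit variance", {
  expect_equal(standardized_weight(1, 0.5), 0)
  expect_equal(standardized_weight(2, 0.5), sqrt(2))
  for (p in seq(0.05, 0.95, by = 0.09)) {
    w <- standardized_weight(0:2, p)
    probs <- c((1 - p)^2, 2 * p * (1 - p), p^2)
    expect_equal(sum(w * probs), 0, tolerance = 1e-12)
    expect_equal(sum(w^2 * probs), 1, tolerance = 1e-12)
  }
  expect_error(standardized_weight(1, 0), "inside \\(0, 1\\)")
})

test_that("residual variance scales the genetic variance by 1/h2 - 1", {
  expect_equal(residual_variance(0.35, 0.35), 0.65)
  expect_equal(residual_variance(2, 1), 0)
  expect_equal(residual_variance(2, 0.5), 2)
  expect_error(residual_variance(1, 0), "h2")
})

test_that("threshold calibration hits the target within 1/n", {
  set.seed(111)
  scores <- rnorm(100000)
  y0 <- calibrate_threshold(scores, 0.303)
  expect_lt(abs(y0 - qnorm(1 - 0.303)), 0.02)
  expect_lte(abs(mean(scores > y0) - 0.303), 1 / length(scores))
  expect_equal(calibrate_threshold(scores, 0), max(scores))
  expect_lt(abs(calibrate_threshold(scores, 0.5) - median(scores)), 0.02)
  expect_error(calibrate_threshold(scores, 1), "target_prevalence")
})

test_that("a null liability model predicts the calibration target everywhere", {
  set.seed(112)
  G <- matrix(rbinom(6000 * 4, 2, 0.4), 6000, 4)
  cohort <- rep(sprintf("c%d", 1:6), each = 1000)
  model <- liability_model(u = rep(0, 4), p = rep(0.4, 4),
                           target_prevalence = 0.303, n_replicates = 50,
                           seed = 1)
  pred <- predict_prevalence(model, G, cohort)
  expect_true(all(abs(pred$mean_prevalence - 0.303) < 0.02))
})

test_that("rescaling all allelic effects leaves predictions unchanged", {
  set.seed(113)
  G <- matrix(rbinom(3000 * 6, 2, 0.3), 3000, 6)
  cohort <- rep(c("a", "b", "c"), each = 1000)
  u <- runif(6, 0.05, 0.2)
  m1 <- liability_model(u, rep(0.3, 6), n_replicates = 20, seed = 4)
  m2 <- liability_model(5 * u, rep(0.3, 6), n_replicates = 20, seed = 4)
  expect_equal(predict_prevalence(m1, G, cohort)$mean_prevalence,
               predict_prevalence(m2, G, cohort)$mean_prevalence,
               tolerance = 1e-12)
})

test_that("raising risk-allele frequencies never lowers expected prevalence", {
  set.seed(114)
  n <- 4000
  u <- rep(0.3, 5)
  G_lo <- matrix(rbinom(n * 5, 2, 0.3), n, 5)
  G_hi <- matrix(rbinom(n * 5, 2, 0.45), n, 5)
  G <- rbind(G_lo, G_hi)
  cohort <- rep(c("low", "zhigh"), each = n)  # calibration on the low cohort
  model <- liability_model(u, rep(0.3, 5), n_replicates = 50, seed = 9)
  pred <- predict_prevalence(model, G, cohort)
  expect_gt(pred$mean_prevalence[2], pred$mean_prevalence[1])
})

test_that("replicate averaging shrinks the standard error as 1/sqrt(R)", {
  set.seed(115)
  G <- matrix(rbinom(2000 * 4, 2, 0.4), 2000, 4)
  cohort <- rep(c("a", "b"), each = 1000)
  mean_se <- vapply(c(25, 100, 400), function(R) {
    m <- liability_model(rep(0.2, 4), rep(0.4, 4), n_replicates = R, seed = 5)
    mean(predict_prevalence(m, G, cohort)$se)
  }, numeric(1))
  expect_true(all(diff(mean_se) < 0))
  expect_lt(abs(mean_se[1] / mean_se[3] / 4 - 1), 0.2)
})

test_that("the model is self-consistent against generator truth", {
  panel <- tiny_panel(12, freq = runif(12, 0.25, 0.75),
                      u_true = runif(12, 0.1, 0.3),
                      s_true = c(rep(0.3, 4), rep(0, 8)))
  cfg <- sim_config(n_per_cohort = 5000, seed = 116)
  d <- simulate_individuals(panel, cfg)
  prep <- prepare_phenotypes(d$phenotypes, cfg$aging_schedule, min_cohort_n = 0)
  realized <- prep$prevalence
  model <- liability_model(panel$u_true, panel$baseline_freq, h2 = cfg$h2,
                           target_prevalence = realized$prevalence[1],
                           n_replicates = 50, seed = 117)
  cohort <- assign_cohorts(d$phenotypes$birth_year, default_cohort_spec(),
                           min_n = 0)
  pred <- predict_prevalence(model, d$genotypes,
                             factor(cohort, levels = attr(cohort, "levels")))
  mc_se <- sqrt(pred$se^2 + realized$prevalence * (1 - realized$prevalence) /
                  realized$n)
  expect_true(all(abs(pred$mean_prevalence - realized$prevalence) <
                    3 * mc_se + 0.01))
})

test_that("excess-case and share arithmetic follow the stated formulas", {
  expect_equal(excess_cases(0.211, 55429643), 116957)
  expect_equal(excess_cases(0, 1e7), 0)
  expect_equal(excess_cases(100, 12345), 12345)
  expect_equal(signif(fraction_of_increase(0.211, 43.5 - 30.3), 2), 1.6)
  expect_equal(fraction_of_increase(0, 10), 0)
  expect_equal(fraction_of_increase(5, 5), 100)
  expect_error(fraction_of_increase(1, 0), "zero")
})
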