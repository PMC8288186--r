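test_that("cohort allele frequencies are risk-allele dosage fractions", {
  expect_equal(cohort_allele_freq(rep(1, 10)), 0.5)
  expect_equal(cohort_allele_freq(rep(2, 4)), 1.0)
  expect_equal(cohort_allele_freq(c(0, 1, 2, 2)), 0.625)
  by_cohort <- cohort_allele_freq(c(0, 1, 2, 2, NA, 2),
                                  c("a", "a", "a", "a", "b", "b"))
  expect_equal(unname(by_cohort), c(0.625, 1.0))
})

test_that("the trend test is calibrated under the null", {
  set.seed(31)
  by <- rep(1940:1969, length.out = 1200)
  p <- replicate(1000, trend_test(rbinom(1200, 2, 0.4), by)$p)
  expect_gt(mean(p < 0.05), 0.03)
  expect_lt(mean(p < 0.05), 0.07)
})

test_that("trend test handles degenerate inputs explicitly", {
  expect_error(trend_test(rbinom(50, 2, 0.5), rep(1950, 50)), "distinct birth years")
  flat <- trend_test(rep(1, 100), rep(1940:1969, length.out = 100))
  expect_true(flat$degenerate)
  expect_equal(flat$slope_per_year, 0)
})

test_that("a planted frequency trend is recovered with correct slope", {
  panel <- snp_panel("s1", baseline_freq = 0.4, s_true = 0.0375)
  # slope = p0 * s / generation = 0.4 * 0.0375 / 25 = 0.0006 per year
  d <- simulate_individuals(panel, sim_config(n_per_cohort = 10000, seed = 17))
  tt <- trend_test(d$genotypes[, 1], d$phenotypes$birth_year)
  expect_lt(abs(tt$slope_per_year - 0.0006), 3 * tt$se)
  expect_gt(tt$slope_per_year, 0)
})

test_that("selection coefficient converts a yearly slope per the dominant model", {
  expect_equal(selection_coefficient(0, 0.3), 0)
  expect_equal(selection_coefficient(0.001, 0.5), 0.05)
  expect_equal(selection_coefficient(-0.001, 0.5, generation_years = 30), -0.06)
  expect_error(selection_coefficient(0.001, 0), "inside \\(0, 1\\)")
  expect_error(selection_coefficient(0.001, 1), "inside \\(0, 1\\)")
})

test_that("the two-tailed binomial sign test reproduces exact tail doubling", {
  expect_equal(signif(binomial_sign_test(26, 6), 2), 0.00054)
  expect_equal(signif(binomial_sign_test(25, 5), 2), 0.00032)
  expect_equal(binomial_sign_test(16, 16), 1.0)
  # identical to the equally-extreme-outcomes rule at a symmetric null
  for (k in c(0, 3, 10, 15)) {
    expect_equal(binomial_sign_test(30 - k, k), binom.test(k, 30)$p.value)
  }
})

test_that("matched control draws respect both tolerances without replacement", {
  set.seed(41)
  panel <- tiny_panel(20, freq = runif(20, 0.3, 0.7),
                      recomb_rate = runif(20, 0.5, 2))
  pool <- simulate_control_pool(panel, 400, seed = 5)
  sets <- sample_matched_controls(panel, pool, n_sets = 10, seed = 6)
  expect_length(sets, 10)
  for (set in sets) {
    expect_false(any(duplicated(set)))
    idx <- match(set, pool$id)
    expect_true(all(abs(pool$baseline_freq[idx] - panel$baseline_freq) <= 0.01))
    expect_true(all(abs(pool$recomb_rate[idx] - panel$recomb_rate) <= 0.05))
  }
  # an out-of-range pool fails loudly, naming the unmatched SNP
  far_pool <- snp_panel(sprintf("far%02d", 1:50),
                        baseline_freq = panel$baseline_freq[1] + 0.02,
                        recomb_rate = 1)
  expect_error(
    sample_matched_controls(tiny_panel(1, freq = panel$baseline_freq[1]),
                            far_pool, 1),
    "no admissible control match.*snp01")
})

test_that("a planted 26-up/6-down panel reproduces the printed sign-test p", {
  set.seed(51)
  s <- c(runif(26, 0.25, 0.4), -runif(6, 0.25, 0.4))
  panel <- snp_panel(sprintf("s%02d", 1:32), baseline_freq = 0.4, s_true = s)
  d <- simulate_individuals(panel, sim_config(n_per_cohort = 1500, seed = 52))
  scan <- scan_panel(panel, d)
  expect_equal(scan$summary$n_up, 26)
  expect_equal(scan$summary$n_down, 6)
  expect_equal(signif(scan$summary$sign_test_p, 2), 0.00054)
  # estimated s signs match the planted ones among significant SNPs
  est <- scan$estimates
  expect_true(all(sign(est$s[est$direction != "0"]) ==
                  sign(s[est$direction != "0"])))
})

test_that("an empty panel scans to an empty result without crashing", {
  panel <- tiny_panel(2)[0, ]
  class(panel) <- c("snp_panel", "data.frame")
  d <- simulate_individuals(tiny_panel(2), tiny_config(n_per_cohort = 50))
  scan <- scan_panel(panel, d)
  expect_equal(scan$summary$n_sig, 0)
  expect_true(is.na(scan$summary$sign_test_p))
})

test_that("flipping the counted allele negates slope and s, preserving p", {
  panel <- snp_panel("s1", baseline_freq = 0.35, s_true = 0.2)
  d <- simulate_individuals(panel, tiny_config(n_per_cohort = 800, seed = 61))
  by <- d$phenotypes$birth_year
  t1 <- trend_test(d$genotypes[, 1], by)
  t2 <- trend_test(2 - d$genotypes[, 1], by)
  expect_equal(t1$slope_per_year, -t2$slope_per_year, tolerance = 1e-12)
  expect_equal(t1$p, t2$p, tolerance = 1e-12)
  s1 <- selection_coefficient(t1$slope_per_year, 0.35)
  s2 <- selection_coefficient(t2$slope_per_year, 0.65)
  expect_equal(sign(s1), -sign(s2))
})
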