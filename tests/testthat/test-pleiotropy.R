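test_that("the lifespan screen flags planted effects and only those", {
  beta_ls <- c(rep(-1.0, 5), rep(0, 25))
  panel <- tiny_panel(30, freq = runif(30, 0.25, 0.75),
                      beta_lifespan = beta_ls)
  d <- simulate_individuals(panel, tiny_config(n_per_cohort = 1500, seed = 71))
  screen <- lifespan_screen(panel, d)
  planted <- panel$id[beta_ls != 0]
  expect_true(all(planted %in% screen$flagged))
  # false flags are rare after FDR
  expect_lte(length(setdiff(screen$flagged, planted)), 1)
})

test_that("the screen degrades gracefully when a parent is missing", {
  panel <- tiny_panel(3)
  d <- simulate_individuals(panel, tiny_config(n_per_cohort = 100, seed = 72))
  d$phenotypes$father_lifespan <- NA_real_
  expect_warning(res <- lifespan_screen(panel, d), "single parent")
  expect_false(res$skipped)
  d$phenotypes$mother_lifespan <- NA_real_
  expect_warning(res2 <- lifespan_screen(panel, d), "skipped")
  expect_true(res2$skipped)
})

test_that("direction consistency follows the antagonistic-pleiotropy sign logic", {
  sel <- data.frame(snp_id = c("a", "b", "c"), direction = c("+", "+", "-"))
  afb <- data.frame(snp_id = c("a", "b", "c"),
                    beta = c(-0.3, 0.2, 0.4), q = c(0.01, 0.2, 0.01))
  neb <- data.frame(snp_id = c("a", "b", "c"),
                    beta = c(0.1, -0.1, 0.2), q = c(0.2, 0.01, 0.2))
  res <- direction_consistency(sel, afb, neb)
  rec <- res$records
  # a: positively selected, significantly lowers AFB -> consistent
  expect_true(rec$consistent[rec$snp_id == "a"])
  # b: positively selected, significantly lowers NEB -> inconsistent
  expect_false(rec$consistent[rec$snp_id == "b"])
  # c: negatively selected, significantly raises AFB -> consistent
  expect_true(rec$consistent[rec$snp_id == "c"])
  # antisymmetry: negating selection directions and betas preserves verdicts
  sel2 <- sel; sel2$direction <- chartr("+-", "-+", sel$direction)
  afb2 <- afb; afb2$beta <- -afb$beta
  neb2 <- neb; neb2$beta <- -neb$beta
  res2 <- direction_consistency(sel2, afb2, neb2)
  expect_equal(res2$records$consistent, rec$consistent)
})

test_that("unanimous consistency yields the exact binomial tail", {
  sel <- data.frame(snp_id = sprintf("s%02d", 1:15), direction = "+")
  afb <- data.frame(snp_id = sel$snp_id, beta = -0.2, q = 0.01)
  neb <- data.frame(snp_id = sel$snp_id, beta = NA_real_, q = NA_real_)
  res <- direction_consistency(sel, afb, neb)
  expect_equal(res$binomial_p, 2 * 0.5^15)
  expect_lt(res$binomial_p, 1e-4)
})

test_that("correlation p-values follow the t-transform", {
  expect_equal(round(cor_p_from_r(-0.67, 9), 3), 0.048)
  expect_equal(cor_p_from_r(0, 25), 1)
  set.seed(81)
  s <- rnorm(12); b <- 0.5 * s + rnorm(12)
  res <- s_effect_correlation(s, b)
  expect_equal(res$p, cor.test(s, b)$p.value, tolerance = 1e-12)
  expect_equal(res$r, cor(s, b))
  expect_error(s_effect_correlation(rep(1, 5), rnorm(5)), "zero variance")
  expect_error(s_effect_correlation(rnorm(2), rnorm(2)), ">= 3")
})

test_that("group comparisons behave symmetrically and detect planted shifts", {
  x <- c(1, 2, 3, 4)
  same <- group_t_test(x, x)
  expect_equal(same$p, 1)
  expect_equal(same$t, 0)
  set.seed(91)
  myopic <- rnorm(10000, 25.5, 4)
  control <- rnorm(10000, 25.0, 4)
  res <- group_t_test(myopic, control)
  expect_lt(res$p, 0.001)
  swapped <- group_t_test(control, myopic)
  expect_equal(swapped$p, res$p)
  expect_equal(swapped$diff, -res$diff)
  expect_error(group_t_test(1, c(1, 2)), ">= 2 values")
})

test_that("association-proportion chi-square matches the direct formula", {
  res <- association_proportion_chisq(15, 30, 3, 30)
  expect_equal(signif(res$statistic, 3), 11.4)
  expect_equal(signif(res$p, 1), 7e-04)
  eq <- association_proportion_chisq(5, 10, 5, 10)
  expect_equal(eq$statistic, 0)
  expect_equal(eq$p, 1)
  # direct sum((O-E)^2/E) oracle
  oracle <- function(k1, n1, k2, n2) {
    O <- matrix(c(k1, n1 - k1, k2, n2 - k2), 2, byrow = TRUE)
    E <- outer(rowSums(O), colSums(O)) / sum(O)
    sum((O - E)^2 / E)
  }
  res2 <- association_proportion_chisq(8, 10, 2, 10)
  expect_equal(res2$statistic, oracle(8, 10, 2, 10), tolerance = 1e-12)
  # invariant under swapping groups and swapping success/failure
  expect_equal(association_proportion_chisq(3, 30, 15, 30)$statistic,
               res$statistic, tolerance = 1e-12)
  expect_equal(association_proportion_chisq(15, 30, 27, 30)$statistic,
               res$statistic, tolerance = 1e-12)
  expect_error(association_proportion_chisq(0, 5, 0, 5), "zero expected")
})
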