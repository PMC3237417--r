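test_that("Monte Carlo matches the hypergeometric oracle", {
  it <- monte_carlo_intersection(10, 5, 5, 5, reps = 100000, seed = 71)
  expect_equal(it$p_analytic, 1 / choose(10, 5))
  expect_lt(abs(it$p_empirical - it$p_analytic), 0.002)
  expect_equal(it$direction, "enriched")
  # expectation identities
  expect_equal(monte_carlo_intersection(100, 50, 50, 25, reps = 1000,
                                        seed = 72)$expected, 25)
  expect_equal(monte_carlo_intersection(290, 85, 93, 50, reps = 1000,
                                        seed = 73)$expected, 27.26,
               tolerance = 1e-3)
  # depletion direction uses the lower tail
  itd <- monte_carlo_intersection(40, 20, 20, 2, reps = 50000, seed = 74)
  expect_equal(itd$direction, "depleted")
  expect_equal(itd$p_analytic, stats::phyper(2, 20, 20, 20))
  expect_lt(abs(itd$p_empirical - itd$p_analytic),
            3 * sqrt(itd$p_analytic * (1 - itd$p_analytic) / 50000) + 1e-4)
  # paper-literal mode drops the tie mass at N
  itl <- monte_carlo_intersection(10, 5, 5, 4, reps = 50000, seed = 75,
                                  mode = "paper-literal")
  its <- monte_carlo_intersection(10, 5, 5, 4, reps = 50000, seed = 75)
  expect_lt(itl$p_empirical, its$p_empirical)
  # infeasible N errors
  expect_error(monte_carlo_intersection(10, 5, 5, 6), "infeasible")
  expect_error(monte_carlo_intersection(10, 8, 8, 2), "infeasible")
})

test_that("chi-square and Welch t follow the standard formulas", {
  cs <- chi_square_2x2(85, 205, 4, 138)
  expect_equal(cs$statistic, 40.9, tolerance = 0.01)
  expect_lt(cs$p, 1e-3)
  cs0 <- chi_square_2x2(10, 10, 10, 10)
  expect_equal(cs0$statistic, 0)
  expect_equal(cs0$p, 1)
  wt <- welch_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(wt$statistic, 0)
  expect_equal(wt$p, 1)
  # against the stock implementation on unequal groups
  set.seed(76)
  x <- rnorm(20); y <- rnorm(25, 1)
  ref <- stats::t.test(x, y)
  expect_equal(welch_t(x, y)$p, ref$p.value)
})

test_that("cv similarity separates what is separable and only that", {
  set.seed(77)
  f1 <- as.data.frame(matrix(rnorm(100 * 4), 100))
  f2 <- as.data.frame(matrix(rnorm(100 * 4), 100))
  null_acc <- cv_similarity(f1, f2, seed = 78)$mean_accuracy
  expect_gte(null_acc, 0.35)
  expect_lte(null_acc, 0.65)
  f2s <- f2
  f2s$V1 <- f2s$V1 + 10
  sep <- cv_similarity(f1, f2s, seed = 79)
  expect_gte(sep$mean_accuracy, 0.95)
  expect_length(sep$accuracy_per_classifier, 6)
  expect_true(all(sep$accuracy_per_classifier >= 0 &
                    sep$accuracy_per_classifier <= 1))
  # too-small class cannot stratify 5 folds
  expect_error(cv_similarity(f1[1:4, ], f2, seed = 80), "at least")
  # deterministic given the seed
  expect_equal(cv_similarity(f1, f2, seed = 81)$mean_accuracy,
               cv_similarity(f1, f2, seed = 81)$mean_accuracy)
})
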