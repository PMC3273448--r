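test_that("utilization ratios carry exact Poisson-gamma intervals", {
  cc <- areal_counts(letters[1:3], c(8, 10, 0), c(100, 120, 50),
                     expected = c(8, 5, 3))
  iur <- indirect_utilization_ratio(cc, level = 0.95)
  expect_equal(iur$iur, c(1, 2, 0))

  # closed form at o = 0: upper = -log(0.025) / e, lower = 0
  expect_equal(iur$ci_low[3], 0)
  expect_equal(iur$ci_high[3], -log(0.025) / 3, tolerance = 1e-12)

  # agreement with the exact one-sample Poisson interval at o = 10, e = 5
  pt <- poisson.test(10, T = 5)
  expect_equal(c(iur$ci_low[2], iur$ci_high[2]),
               as.numeric(pt$conf.int), tolerance = 1e-10)
  # the central interval excludes 1 iff the central exact test rejects
  p_central <- 2 * min(ppois(10, 5), 1 - ppois(9, 5))
  expect_equal(iur$ci_low[2] > 1 || iur$ci_high[2] < 1,
               p_central < 0.05)
  expect_true(iur$ci_low[2] <= 2 && 2 <= iur$ci_high[2])

  expect_error(indirect_utilization_ratio(
    areal_counts("a", 1, 10, expected = 1), level = 1.5), "level")
})

test_that("extremal quotient follows the interpolated percentile rule", {
  expect_equal(extremal_quotient(rep(3.7, 20)), 1)
  r <- 1:100
  expect_equal(extremal_quotient(r), oracle_eq(r), tolerance = 1e-12)
  expect_equal(extremal_quotient(2 * r), extremal_quotient(r),
               tolerance = 1e-12)
  expect_error(extremal_quotient(c(1, 0, 2)), "> 0")
})

test_that("coefficients of variation match hand arithmetic", {
  expect_equal(coefficient_of_variation(rep(2, 8)), 0)
  expect_equal(coefficient_of_variation(c(1, 3)), sqrt(2) / 2,
               tolerance = 1e-12)
  # weight concentrated on one area drives the weighted CV to zero
  cvw <- coefficient_of_variation(c(1, 3), weights = c(1e9, 1))
  expect_lt(cvw, 1e-4)
})

test_that("SCV and EB match hand-computed examples", {
  cc <- areal_counts(c("a", "b"), c(20, 5), c(100, 100),
                     expected = c(10, 10))
  expect_equal(systematic_component_of_variation(cc), 0.525,
               tolerance = 1e-12)
  expect_equal(empirical_bayes_statistic(cc), 0.4375, tolerance = 1e-12)

  # zero observed variation: SCV is the negative noise correction,
  # EB truncates to zero
  cc0 <- areal_counts(c("a", "b"), c(10, 10), c(100, 100),
                      expected = c(10, 10))
  expect_equal(systematic_component_of_variation(cc0), -0.1,
               tolerance = 1e-12)
  expect_equal(empirical_bayes_statistic(cc0), 0)
})

test_that("scaling counts shrinks only the SCV noise correction", {
  o <- c(20, 5); e <- c(10, 10)
  c1 <- areal_counts(c("a", "b"), o, c(100, 100), expected = e)
  c2 <- areal_counts(c("a", "b"), 10 * o, c(1000, 1000),
                     expected = 10 * e)
  ratio_term <- mean(((10 * o - 10 * e) / (10 * e))^2)
  expect_equal(systematic_component_of_variation(c2),
               ratio_term - mean(1 / (10 * e)), tolerance = 1e-12)
  expect_gt(systematic_component_of_variation(c2),
            systematic_component_of_variation(c1))
})

test_that("all variation statistics are permutation invariant", {
  set.seed(99)
  for (k in 1:10) {
    cc <- random_counts(15)
    ord <- sample(15)
    cp <- areal_counts(cc$area_ids[ord], cc$observed[ord],
                       cc$population[ord], cc$expected[ord])
    rates <- unname(cc$observed / cc$population)
    expect_equal(extremal_quotient(rates[ord]), extremal_quotient(rates),
                 tolerance = 1e-12)
    expect_equal(coefficient_of_variation(rates[ord]),
                 coefficient_of_variation(rates), tolerance = 1e-12)
    expect_equal(systematic_component_of_variation(cp),
                 systematic_component_of_variation(cc), tolerance = 1e-12)
    expect_equal(empirical_bayes_statistic(cp),
                 empirical_bayes_statistic(cc), tolerance = 1e-12)
  }
})

test_that("EB grows with the true between-area relative-risk variance", {
  set.seed(2024)
  mean_eb <- sapply(c(0.02, 0.1, 0.3), function(s2) {
    mean(replicate(500, {
      n <- 30
      e <- runif(n, 30, 80)
      o <- rpois(n, e * exp(rnorm(n, -s2 / 2, sqrt(s2))))
      oracle_eb(o, e)
    }))
  })
  expect_true(all(diff(mean_eb) > 0))
})

test_that("bootstrap intervals are reproducible and behave at the null", {
  cc <- random_counts(20)
  v1 <- variation_statistics(cc, n_boot = 200, seed = 7)
  v2 <- variation_statistics(cc, n_boot = 200, seed = 7)
  expect_identical(v1, v2)
  v3 <- variation_statistics(cc, n_boot = 200, seed = 8)
  expect_false(identical(v1$ci_low, v3$ci_low))

  v0 <- variation_statistics(cc, n_boot = 0)
  expect_true(all(is.na(v0$ci_low)))
  expect_equal(v0$estimate, v1$estimate)

  # constant-risk data with large populations: EQ interval collapses
  # toward its floor of 1, CV interval toward 0
  set.seed(5)
  N <- rep(1e5, 25)
  o <- rpois(25, 0.2 * N)
  cst <- areal_counts(paste0("c", 1:25), o, N)
  v <- variation_statistics(cst, n_boot = 300, seed = 3)
  eq <- v[v$statistic == "eq", ]
  expect_lt(eq$ci_low, 1.05)      # EQ >= 1 by construction
  cv <- v[v$statistic == "cv", ]
  expect_lt(cv$ci_high, 0.02)
})
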