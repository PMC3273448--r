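scm_cfg <- function(seed = 1)
  mcmc_config(n_iter = 2000, burn_in = 2000, thin = 4, seed = seed)

fake_scm_fit <- function(lam, bet, p1, p2, delta) {
  list(samples = list(draws = list(
    lambda = lam, beta = bet, phi1 = p1, phi2 = p2,
    delta = matrix(delta))))
}

test_that("variance partition matches hand-computed fractions", {
  c0 <- 0.6
  lam <- matrix(c(-1, 0, 1) * c0, nrow = 1)
  bet <- matrix(c(-1, 0, 1) * c0 / 2, nrow = 1)
  zero <- matrix(0, nrow = 1, ncol = 3)
  part <- variance_partition(fake_scm_fit(lam, bet, zero, zero, 1))
  expect_equal(part$draws$women$frac_shared, 0.8, tolerance = 1e-12)
  expect_equal(part$draws$women$frac_spatial, 0.2, tolerance = 1e-12)
  expect_equal(part$draws$men$frac_shared, 1)

  # fractions invariant to adding constants to lambda or beta
  part2 <- variance_partition(fake_scm_fit(lam + 5, bet - 2, zero, zero, 1))
  expect_equal(part2$draws$women$frac_shared,
               part$draws$women$frac_shared, tolerance = 1e-12)

  # delta reallocates shared variance between the genders
  part3 <- variance_partition(fake_scm_fit(lam, bet, zero, zero, 2))
  expect_equal(part3$draws$women$frac_shared,
               (0.36 / 4) / (0.36 / 4 + 0.09), tolerance = 1e-12)
})

test_that("component exceedance maps are direct recounts of draws", {
  set.seed(21)
  lam <- matrix(rnorm(200 * 4, 0.05, 0.2), ncol = 4)
  bet <- matrix(-abs(rnorm(200 * 4)), ncol = 4)
  m <- component_exceedance_maps(
    fake_scm_fit(lam, bet, lam * 0, bet * 0, rep(1, 200)))
  expect_equal(m$shared_exceedance, colMeans(exp(lam) > 1))
  expect_equal(m$discrepant_exceedance, rep(0, 4))
})

test_that("shared-dominated data give a high women shared fraction", {
  sim <- simulate_scm(simulation_params(
    female_spatial_var = 0, unstructured_var = c(0, 0), seed = 31))
  fit <- suppressWarnings(fit_scm(sim$dataset, config = scm_cfg(31)))
  expect_gt(fit$partition$summary["women_shared", "median"], 0.9)
  # within each draw the fractions sum to one
  w <- fit$partition$draws$women
  expect_lt(max(abs(w$frac_shared + w$frac_spatial + w$frac_unstr - 1)),
            1e-10)
  m <- fit$partition$draws$men
  expect_lt(max(abs(m$frac_shared + m$frac_specific - 1)), 1e-10)
})

test_that("swapping the genders inverts the delta loading", {
  p <- simulation_params(delta = 1.25, shared_var = 0.1,
                         female_spatial_var = 0,
                         unstructured_var = c(0, 0),
                         mean_population = c(9000, 9000), pop_sdlog = 0.2,
                         seed = 41)
  sim <- simulate_scm(p)
  ds <- sim$dataset
  swapped <- gender_paired_dataset(ds$adjacency, ds$women, ds$men)
  f1 <- suppressWarnings(fit_scm(ds, config = scm_cfg(41)))
  f2 <- suppressWarnings(fit_scm(swapped, config = scm_cfg(41)))
  d1 <- f1$delta$summary[["median"]]
  d2 <- f2$delta$summary[["median"]]
  expect_gt(d1, 1)        # men carry delta * lambda; truth delta = 1.25
  expect_lt(d2, 1)        # swapped data load the shared term as 1/delta
  expect_equal(d2, 1 / d1, tolerance = 0.1)
})

test_that("SCM risks agree with per-gender BYM at large counts", {
  sim <- simulate_scm(simulation_params(
    mean_population = c(15000, 15000), pop_sdlog = 0.2, seed = 51))
  ds <- sim$dataset
  scm <- suppressWarnings(fit_scm(ds, config = scm_cfg(51)))
  bym_m <- suppressWarnings(fit_bym(ds$men, ds$adjacency,
                                    config = scm_cfg(52)))
  bym_w <- suppressWarnings(fit_bym(ds$women, ds$adjacency,
                                    config = scm_cfg(53)))
  expect_gt(cor(scm$rr$men$median, bym_m$rr$median), 0.95)
  expect_gt(cor(scm$rr$women$median, bym_w$rr$median), 0.95)

  cmp <- compare_dic(bym_m, bym_w, scm)
  expect_equal(cmp$delta_dic, bym_m$dic + bym_w$dic - scm$dic)
  expect_true(is.finite(cmp$sd_reduction_pct))
  other <- simulate_scm(simulation_params(n_rows = 12, n_cols = 15,
                                          seed = 99))
  bad <- suppressWarnings(fit_scm(other$dataset, config = scm_cfg(1)))
  expect_error(compare_dic(bym_m, bym_w, bad), "same paired dataset")
})

test_that("exchangeable-only priors trigger the identifiability warning", {
  sim <- simulate_scm(simulation_params(n_rows = 4, n_cols = 4,
                                        seed = 61))
  w <- capture_warnings(
    fit_scm(sim$dataset,
            priors = scm_priors(lambda = "exchangeable",
                                beta = "exchangeable"),
            config = mcmc_config(n_iter = 300, burn_in = 200, thin = 3,
                                 seed = 6)))
  expect_true(any(grepl("weakly identified", w)))
})

test_that("a one-configuration sensitivity grid yields a one-row table", {
  sim <- simulate_scm(simulation_params(n_rows = 5, n_cols = 5,
                                        seed = 71))
  sg <- suppressWarnings(sensitivity_grid(
    sim$dataset, list(default = scm_priors()),
    mcmc_config(n_iter = 500, burn_in = 500, thin = 5, seed = 7)))
  expect_equal(nrow(sg$table), 1L)
  expect_equal(sg$max_logrisk_diff, 0)
  expect_length(sg$failures, 0)
})
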