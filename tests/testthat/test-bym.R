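quick_cfg <- function(seed = 1)
  mcmc_config(n_iter = 1500, burn_in = 1500, thin = 3, seed = seed)

test_that("spatial fraction decomposition matches hand arithmetic", {
  u <- rbind(c(-1, 0, 1), c(0, 0, 0), c(-2, 0, 2))
  s <- spatial_fraction(u, c(1, 1, 0))
  expect_equal(s$draws[1], 0.5)        # s_u2 = 1 against sigma_v2 = 1
  expect_equal(s$draws[2], 0)          # constant field
  expect_equal(s$draws[3], 1)          # sigma_v2 = 0, nonconstant field
  expect_true(all(s$draws >= 0 & s$draws <= 1))
})

test_that("exceedance probabilities are direct draw counts", {
  rr <- matrix(c(rep(1.2, 9500), rep(0.8, 500)), ncol = 1)
  res <- exceedance_probability(rr)
  expect_equal(res$probability, 0.95)
  expect_false(res$flagged)
  expect_equal(exceedance_probability(matrix(2, 10, 2))$probability,
               c(1, 1))
  sym <- matrix(exp(rnorm(4000, 0, 0.3)), ncol = 2)
  expect_equal(unname(exceedance_probability(sym)$probability),
               c(0.5, 0.5), tolerance = 0.05)
})

test_that("null data yield relative risks near one", {
  sim <- simulate_bym(grid_adjacency(6, 6), spatial_var = 0,
                      unstructured_var = 0, mean_population = 20000,
                      pop_sdlog = 0, seed = 2)
  fit <- suppressWarnings(
    fit_bym(sim$counts, sim$adjacency, config = quick_cfg(3)))
  expect_lt(max(abs(fit$rr$median - 1)), 0.05)
  expect_lt(fit$summary["marginal_spatial_variance", "median"], 0.01)
  expect_lt(fit$summary["unstructured_variance", "median"], 0.01)
})

test_that("chains are bit-for-bit reproducible under a fixed seed", {
  sim <- simulate_bym(grid_adjacency(5, 5), mean_population = 3000,
                      seed = 4)
  f1 <- suppressWarnings(fit_bym(sim$counts, sim$adjacency,
                                 config = quick_cfg(9)))
  f2 <- suppressWarnings(fit_bym(sim$counts, sim$adjacency,
                                 config = quick_cfg(9)))
  expect_identical(f1$samples$draws, f2$samples$draws)
  f3 <- suppressWarnings(fit_bym(sim$counts, sim$adjacency,
                                 config = quick_cfg(10)))
  expect_false(identical(f1$samples$draws$u, f3$samples$draws$u))
})

test_that("more information tightens the risk intervals", {
  sim <- simulate_bym(grid_adjacency(5, 5), mean_population = 800,
                      pop_sdlog = 0, seed = 6)
  cc <- sim$counts
  big <- areal_counts(cc$area_ids, 10 * cc$observed, 10 * cc$population,
                      expected = 10 * cc$expected)
  f1 <- suppressWarnings(fit_bym(cc, sim$adjacency, config = quick_cfg(7)))
  f2 <- suppressWarnings(fit_bym(big, sim$adjacency, config = quick_cfg(7)))
  expect_lt(mean(f2$rr$ci_high - f2$rr$ci_low),
            mean(f1$rr$ci_high - f1$rr$ci_low))
})

test_that("posterior risks track raw ratios when counts are large", {
  sim <- simulate_bym(mean_population = 9000, pop_sdlog = 0.3, seed = 8)
  expect_true(all(sim$counts$expected >= 500))
  fit <- suppressWarnings(fit_bym(sim$counts, sim$adjacency,
                                  config = quick_cfg(12)))
  iur <- indirect_utilization_ratio(sim$counts)
  expect_gt(cor(fit$rr$median, iur$iur), 0.95)
})

test_that("the spatial fraction separates spatial from exchangeable noise", {
  cfg <- function(s) mcmc_config(seed = s)   # default, well-mixing schedule
  hits_null <- 0; hits_spat <- 0
  for (s in 1:10) {
    pure_v <- simulate_bym(spatial_var = 0, unstructured_var = 0.05,
                           mean_population = 6000, pop_sdlog = 0.3,
                           seed = 100 + s)
    pure_u <- simulate_bym(spatial_var = 0.05, unstructured_var = 0,
                           mean_population = 6000, pop_sdlog = 0.3,
                           seed = 200 + s)
    fv <- suppressWarnings(fit_bym(pure_v$counts, pure_v$adjacency,
                                   config = cfg(s)))
    fu <- suppressWarnings(fit_bym(pure_u$counts, pure_u$adjacency,
                                   config = cfg(s)))
    hits_null <- hits_null + (fv$spatial_fraction$summary[["median"]] < 0.5)
    hits_spat <- hits_spat + (fu$spatial_fraction$summary[["median"]] > 0.5)
  }
  expect_equal(hits_null, 10)
  expect_equal(hits_spat, 10)
})

test_that("BYM posterior agrees with an independent JAGS implementation", {
  # independent route: the ICAR prior written in its eigenbasis as a
  # proper normal on the sum-to-zero subspace, fitted with JAGS
  sim <- simulate_bym(spatial_var = 0.054, unstructured_var = 0.022,
                      seed = 1009)
  fit <- suppressWarnings(fit_bym(sim$counts, sim$adjacency,
                                  config = mcmc_config(seed = 9)))

  L <- graph_laplacian(sim$adjacency)
  eg <- eigen(L, symmetric = TRUE)
  keep <- eg$values > 1e-9
  model <- "
  model {
    for (a in 1:N) {
      o[a] ~ dpois(mu[a])
      log(mu[a]) <- log(e[a]) + alpha + u[a] + v[a]
      v[a] ~ dnorm(0, tau_v)
      u[a] <- inprod(V[a,], w)
    }
    for (k in 1:K) { w[k] ~ dnorm(0, tau_u * lam[k]) }
    alpha ~ dnorm(0, 1e-6)
    tau_u ~ dgamma(0.5, 0.0005)
    tau_v ~ dgamma(0.5, 0.0005)
    s_u2 <- (inprod(u, u) - N * pow(mean(u), 2)) / (N - 1)
    frac <- s_u2 / (s_u2 + 1 / tau_v)
  }"
  set.seed(9)
  jm <- rjags::jags.model(
    textConnection(model),
    data = list(o = unname(sim$counts$observed),
                e = unname(sim$counts$expected),
                V = eg$vectors[, keep], lam = eg$values[keep],
                N = sim$adjacency$n_areas, K = sum(keep)),
    n.chains = 2, n.adapt = 500, quiet = TRUE)
  update(jm, 2000)
  samp <- rjags::coda.samples(jm, c("frac", "s_u2"), n.iter = 5000,
                              thin = 5)
  q <- summary(samp)$quantiles
  expect_equal(fit$spatial_fraction$summary[["median"]],
               q["frac", "50%"], tolerance = 0.1)
  expect_equal(fit$summary["marginal_spatial_variance", "median"],
               q["s_u2", "50%"], tolerance = 0.1)
})
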