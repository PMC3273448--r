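path_graph <- function(ids) {
  adjacency(ids, cbind(ids[-length(ids)], ids[-1]))
}

test_that("ICAR quadratic form and full conditional follow the graph", {
  adj <- path_graph(c("A", "B", "C"))
  expect_equal(icar_quadratic_form(c(0, 1, 3), adj), 5)
  expect_equal(icar_quadratic_form(rep(2.5, 3), adj), 0)
  u <- c(-1, 0.5, 2)
  expect_equal(icar_quadratic_form(u + 10, adj),
               icar_quadratic_form(u, adj), tolerance = 1e-12)

  fc <- icar_full_conditional(c(2, 0, 4), 2, adj, tau = 1)
  expect_equal(fc$mean, 3)
  expect_equal(fc$precision, 2)
  fc2 <- icar_full_conditional(c(2, 0, 4), 2, adj, tau = 2)
  expect_equal(fc2$precision, 4)
  # all neighbours equal -> conditional mean equals that value
  fc3 <- icar_full_conditional(c(7, 0, 7), 2, adj, tau = 1)
  expect_equal(fc3$mean, 7)

  iso <- adjacency(c("A", "B", "C"), rbind(c("A", "B")))
  expect_error(icar_full_conditional(c(0, 0, 0), 3, iso, 1), "isolated")
})

test_that("ICAR log-density matches the constrained eigenbasis oracle", {
  adj <- adjacency(c("A", "B", "C", "D"),
                   rbind(c("A", "B"), c("B", "C"), c("C", "D"),
                         c("D", "A"), c("A", "C")))
  set.seed(11)
  diffs <- replicate(25, {
    u <- rnorm(4); u <- u - mean(u)
    tau <- exp(runif(1, -2, 3))
    icar_log_density(u, adj, tau) - oracle_icar_logdens(u, adj, tau)
  })
  # equal up to one shared constant across all (u, tau)
  expect_lt(max(diffs) - min(diffs), 1e-8)
})

test_that("precision Gibbs draw has the conjugate posterior", {
  set.seed(1)
  d1 <- gibbs_update_precision(0, 0, 0.5, 0.0005)
  set.seed(1)
  d2 <- gibbs_update_precision(0, 0, 0.5, 0.0005)
  expect_identical(d1, d2)
  set.seed(2)
  expect_false(identical(gibbs_update_precision(0, 0, 0.5, 0.0005), d1))

  # with quadratic = n_eff * v and large n_eff, draws concentrate at 1/v
  set.seed(3)
  v <- 0.25
  draws <- replicate(200, gibbs_update_precision(2e4 * v, 2e4))
  expect_equal(mean(draws), 1 / v, tolerance = 0.02)
  expect_error(gibbs_update_precision(NaN, 10), "finite")
})

test_that("random-walk MH respects its contracts", {
  target <- function(x) -x^2 / 2
  set.seed(4)
  res <- mh_update_site(0.3, target, proposal_sd = 0)
  expect_equal(res$value, 0.3)

  set.seed(5)
  acc <- mean(replicate(500,
    mh_update_site(0, function(x) 0, proposal_sd = 1)$accepted))
  expect_equal(acc, 1)

  options(arealvar.nan_warned = FALSE)
  set.seed(6)
  expect_warning(
    res <- mh_update_site(1, function(x) if (x == 1) 0 else NaN, 1),
    "NaN")
  expect_equal(res$value, 1)
  options(arealvar.nan_warned = FALSE)
})

test_that("MH chain on a Poisson-lognormal site matches quadrature", {
  o <- 17; e <- 12
  logpost <- function(th) o * th - e * exp(th) +
    dnorm(th, 0, 1, log = TRUE)
  set.seed(8)
  n_it <- 20000
  th <- 0; out <- numeric(n_it)
  for (k in seq_len(n_it)) {
    th <- mh_update_site(th, logpost, proposal_sd = 0.5)$value
    out[k] <- th
  }
  out <- out[-(1:2000)]
  orc <- oracle_poisson_lognormal_posterior(o, e)
  se <- batch_se(out)
  expect_lt(abs(mean(out) - orc$mean), 3 * se)
  expect_equal(sd(out), orc$sd, tolerance = 0.1)
})

test_that("sum-to-zero centering works per connected component", {
  adj <- path_graph(c("A", "B", "C"))
  f <- c(-1, 0, 1)
  res <- center_sum_to_zero(f, adj)
  expect_equal(res$field, f)
  expect_equal(res$absorbed, 0)

  res2 <- center_sum_to_zero(rep(4, 3), adj)
  expect_equal(res2$field, rep(0, 3))
  expect_equal(res2$absorbed, 4)

  two <- adjacency(c("A", "B", "C", "D"),
                   rbind(c("A", "B"), c("C", "D")))
  res3 <- center_sum_to_zero(c(1, 3, 10, 20), two)
  expect_equal(res3$field, c(-1, 1, -5, 5))
  expect_equal(res3$absorbed, c(2, 15))
})

test_that("split-chain R-hat separates mixed from unmixed chains", {
  set.seed(9)
  x <- rnorm(1000)
  expect_lt(abs(rhat(cbind(x, x)) - 1), 0.05)
  expect_gt(rhat(cbind(rnorm(500), rnorm(500, 10))), 5)
  expect_lt(rhat(matrix(rnorm(2000), ncol = 2)), 1.05)
  expect_error(rhat(matrix(rnorm(100), ncol = 1)), "chains")

  rep <- convergence_report(list(good = matrix(rnorm(2000), ncol = 2),
                                 bad = cbind(rnorm(500), rnorm(500, 10))))
  expect_true(rep$converged[rep$parameter == "good"])
  expect_false(rep$converged[rep$parameter == "bad"])
})

test_that("DIC reduces to the plain deviance for a degenerate posterior", {
  res <- dic(rep(123.4, 50), 123.4)
  expect_equal(res$pd, 0)
  expect_equal(res$dic, 123.4)
  expect_warning(dic(c(10, 10), 11), "negative pD")
})

test_that("DIC on a conjugate Poisson mean matches the analytic posterior", {
  # o_i ~ Poisson(mu), mu ~ Gamma(a, b): posterior Gamma(a + sum(o), b + n)
  set.seed(10)
  o <- c(4, 7, 5, 6, 3)
  a <- 2; b <- 0.5
  mu_draws <- rgamma(20000, a + sum(o), b + length(o))
  dev_draws <- sapply(mu_draws, function(m)
    -2 * sum(dpois(o, m, log = TRUE)))
  res <- dic(dev_draws, -2 * sum(dpois(o, mean(mu_draws), log = TRUE)))
  # analytic pD for a Poisson mean approaches 1 parameter
  expect_equal(res$pd, 1, tolerance = 0.1)

  # adding an ignorable parameter leaves DIC essentially unchanged
  dev2 <- dev_draws + 0 * rnorm(length(dev_draws))
  res2 <- dic(dev2, -2 * sum(dpois(o, mean(mu_draws), log = TRUE)))
  expect_equal(res2$dic, res$dic, tolerance = 1e-9)
})
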