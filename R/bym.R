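# internal: CSR neighbour arrays + intercept grouping for the samplers.
# One flat intercept per connected component of size >= 2; degree-0 areas
# (whose spatial effect falls back to an exchangeable normal) share one
# pooled intercept.  n_eff is the rank of the spatial-field prior under
# that fallback: n - #(components of size >= 2).
sampler_graph <- function(adj) {
  nb <- neighbour_list(adj)
  deg <- lengths(nb)
  isolated <- deg == 0L
  comp <- adj$components
  sizes <- table(comp)
  big <- as.integer(names(sizes)[sizes >= 2L])
  grp <- integer(adj$n_areas)
  if (length(big)) {
    map <- stats::setNames(seq_along(big) - 1L, big)
    grp[!isolated] <- map[as.character(comp[!isolated])]
  }
  grp[isolated] <- length(big)
  list(adj = as.integer(unlist(nb) - 1L),
       ptr = as.integer(c(0L, cumsum(deg))),
       igrp = as.integer(grp),
       n_grp = length(big) + as.integer(any(isolated)),
       n_center = length(big),
       isolated = isolated,
       n_eff = adj$n_areas - length(big))
}

row_vars <- function(m) {
  if (ncol(m) < 2L) stop("need at least 2 areas")
  rowSums((m - rowMeans(m))^2) / (ncol(m) - 1L)
}

summ_qi <- function(x, level = 0.95) {
  a <- (1 - level) / 2
  q <- stats::quantile(x, c(0.5, a, 1 - a), names = FALSE, type = 7)
  c(median = q[1L], ci_low = q[2L], ci_high = q[3L])
}

#' Fit the Besag-York-Mollie model
#'
#' Poisson log-linear model for per-area counts,
#' `o_i ~ Poisson(e_i * rho_i)` with
#' `log rho_i = alpha + u_i + v_i`: `u` an intrinsic CAR (spatially
#' structured) field, `v` an exchangeable heterogeneity field, `alpha` a
#' flat intercept.  Precisions carry `Gamma(0.5, 0.0005)` hyperpriors by
#' default.  Fitted by single-site Metropolis-within-Gibbs with conjugate
#' precision draws; ICAR fields are re-centered (per connected component)
#' after every sweep with the constants absorbed into the intercept.
#'
#' @param counts an [areal_counts()] object.
#' @param adjacency an [adjacency()] object aligned with `counts`.
#' @param priors list with elements `tau_u` and `tau_v`, each
#'   `c(shape, rate)` of the Gamma hyperprior on the precision.
#' @param config an [mcmc_config()].
#' @return object of class `"bym_fit"` with elements
#'   \describe{
#'     \item{samples}{kept draws (`u`, `v`, `alpha`, `sigma_u2`
#'       (conditional, `1/tau_u`), `sigma_v2`, `s_u2` (empirical marginal
#'       spatial variance per draw), `spatial_fraction`, `deviance`),
#'       plus `chain`/`iteration` indices.}
#'     \item{rr}{per-area posterior summary of `rho_i` with exceedance
#'       probabilities `Pr(rho_i > 1)`.}
#'     \item{spatial_fraction}{summary (median, central 95\% interval).}
#'     \item{summary}{posterior summaries of the variance parameters.}
#'     \item{dic}{DIC, pD, mean deviance.}
#'     \item{convergence}{split-chain R-hat table; `converged` is FALSE
#'       (with a warning at fit time) if any monitored R-hat > 1.1.}
#'   }
#' @export
fit_bym <- function(counts, adjacency,
                    priors = list(tau_u = c(0.5, 0.0005),
                                  tau_v = c(0.5, 0.0005)),
                    config = mcmc_config()) {
  stopifnot(inherits(counts, "areal_counts"),
            inherits(adjacency, "adjacency"),
            inherits(config, "mcmc_config"))
  if (!identical(as.character(counts$area_ids),
                 as.character(adjacency$area_ids)))
    stop("counts and adjacency area ids are misaligned")
  g <- sampler_graph(adjacency)
  o <- unname(counts$observed)
  e <- unname(counts$expected)
  n <- length(o)
  n_keep <- config$n_iter %/% config$thin
  if (n_keep < 2L) stop("schedule keeps fewer than 2 draws per chain")

  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    set.seed(config$seed + ch - 1L)
    a0 <- log(sum(o) / sum(e)) + stats::rnorm(g$n_grp, 0, 0.2)
    u0 <- stats::rnorm(n, 0, 0.05)
    u0 <- center_sum_to_zero(u0, adjacency)$field
    v0 <- stats::rnorm(n, 0, 0.05)
    t0 <- exp(stats::rnorm(2L, log(20), 0.5))
    chains[[ch]] <- bym_chain_cpp(
      o, e, g$adj, g$ptr, g$igrp, g$n_grp, g$n_center, g$isolated,
      g$n_eff,
      priors$tau_u[1L], priors$tau_u[2L],
      priors$tau_v[1L], priors$tau_v[2L],
      config$burn_in, config$n_iter, config$thin,
      config$proposal_sd, config$adapt,
      u0, v0, a0, t0[1L], t0[2L])
  }

  bind <- function(nm) do.call(rbind, lapply(chains, function(x)
    as.matrix(x[[nm]])))
  u <- bind("u"); v <- bind("v"); alpha <- bind("alpha")
  tau_u <- unlist(lapply(chains, `[[`, "tau_u"))
  tau_v <- unlist(lapply(chains, `[[`, "tau_v"))
  deviance <- unlist(lapply(chains, `[[`, "deviance"))
  chain <- rep(seq_len(config$n_chains), each = n_keep)
  iteration <- rep(seq_len(n_keep), times = config$n_chains)

  eta <- alpha[, g$igrp + 1L, drop = FALSE] + u + v
  rho <- exp(eta)
  s_u2 <- row_vars(u)
  sigma_v2 <- 1 / tau_v
  frac <- s_u2 / (s_u2 + sigma_v2)

  exc <- exceedance_probability(rho, threshold = 1)
  rr <- data.frame(area_id = counts$area_ids,
                   t(apply(rho, 2L, summ_qi)),
                   exceedance = exc$probability,
                   flagged = exc$flagged,
                   stringsAsFactors = FALSE)

  mu_hat <- e * colMeans(rho)
  fit_dic <- dic(deviance, poisson_deviance(o, mu_hat))

  per_chain <- function(x) matrix(x, nrow = n_keep,
                                  ncol = config$n_chains)
  monitored <- list(alpha = per_chain(alpha[, 1L]),
                    sigma_v2 = per_chain(sigma_v2),
                    s_u2 = per_chain(s_u2),
                    spatial_fraction = per_chain(frac),
                    deviance = per_chain(deviance))
  conv <- if (config$n_chains >= 2L) {
    rep <- convergence_report(monitored)
    lr_rh <- apply(eta, 2L, function(x) rhat(per_chain(x)))
    rep <- rbind(rep, data.frame(parameter = "log_rr (max over areas)",
                                 rhat = max(lr_rh, na.rm = TRUE),
                                 converged = max(lr_rh, na.rm = TRUE) <= 1.1,
                                 stringsAsFactors = FALSE))
    rep
  } else NULL
  converged <- is.null(conv) || all(conv$converged)
  if (!converged)
    warning("BYM fit shows R-hat > 1.1 for: ",
            paste(conv$parameter[!conv$converged], collapse = ", "),
            "; consider a longer schedule", call. = FALSE)

  structure(list(
    samples = list(
      draws = list(u = u, v = v, alpha = alpha,
                   sigma_u2 = matrix(1 / tau_u),
                   sigma_v2 = matrix(sigma_v2),
                   s_u2 = matrix(s_u2),
                   spatial_fraction = matrix(frac),
                   deviance = matrix(deviance)),
      chain = chain, iteration = iteration),
    rr = rr,
    spatial_fraction = list(draws = frac, summary = summ_qi(frac)),
    summary = rbind(marginal_spatial_variance = summ_qi(s_u2),
                    unstructured_variance = summ_qi(sigma_v2),
                    spatial_fraction = summ_qi(frac),
                    alpha = summ_qi(alpha[, 1L])),
    dic = fit_dic$dic, pd = fit_dic$pd,
    deviance_mean = fit_dic$mean_deviance,
    convergence = conv, converged = converged,
    acceptance = chains[[1L]]$accept,
    config = config, area_ids = counts$area_ids,
    igrp = g$igrp + 1L,
    observed = o, expected = e),
    class = "bym_fit")
}

#' @export
print.bym_fit <- function(x, ...) {
  cat("BYM fit:", length(x$area_ids), "areas,",
      x$config$n_chains, "chains\n")
  cat(sprintf("  spatial fraction: %.3f (%.3f, %.3f)\n",
              x$spatial_fraction$summary[1L],
              x$spatial_fraction$summary[2L],
              x$spatial_fraction$summary[3L]))
  cat(sprintf("  DIC %.2f (pD = %.2f)\n", x$dic, x$pd))
  if (!x$converged) cat("  WARNING: R-hat > 1.1 for some parameters\n")
  invisible(x)
}

#' Spatial-fraction variance decomposition
#'
#' Per posterior draw, the empirical marginal variance of the spatial
#' field, `s_u^2 = sum((u_i - mean(u))^2) / (n - 1)`, is compared with
#' the unstructured variance: `fraction = s_u^2 / (s_u^2 + sigma_v^2)`,
#' the share of log-relative-risk variability attributable to spatial
#' dependence.
#'
#' @param u_draws draws-by-areas matrix of spatial-field values.
#' @param sigma_v2_draws vector of unstructured-variance draws, aligned
#'   with the rows of `u_draws`.
#' @return list with `draws` (per-draw fractions) and `summary`
#'   (median and central 95\% interval).
#' @export
spatial_fraction <- function(u_draws, sigma_v2_draws) {
  u_draws <- as.matrix(u_draws)
  if (ncol(u_draws) < 2L) stop("need at least 2 areas")
  if (length(sigma_v2_draws) != nrow(u_draws))
    stop("sigma_v2_draws must align with rows of u_draws")
  s_u2 <- row_vars(u_draws)
  f <- s_u2 / (s_u2 + sigma_v2_draws)
  f[s_u2 == 0 & sigma_v2_draws == 0] <- NA_real_
  list(draws = f, summary = summ_qi(f[is.finite(f)]))
}

#' Posterior exceedance probabilities
#'
#' Share of kept draws in which an area's relative risk exceeds a
#' threshold, `Pr(rho_i > threshold | data)` — the quantity plotted in
#' posterior-probability maps.  Areas with probability above 0.95 are
#' flagged.
#'
#' @param rr_draws draws-by-areas matrix of relative-risk draws.
#' @param threshold exceedance threshold (> 0; default 1).
#' @param flag_above flag level (default 0.95).
#' @return list with `probability` (per area) and logical `flagged`.
#' @export
exceedance_probability <- function(rr_draws, threshold = 1,
                                   flag_above = 0.95) {
  if (threshold <= 0) stop("threshold must be > 0")
  rr_draws <- as.matrix(rr_draws)
  p <- colMeans(rr_draws > threshold)
  list(probability = p, flagged = p > flag_above)
}
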