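#' MCMC schedule configuration
#'
#' Defaults are a 1/10-scale version of the production schedule of
#' [production_schedule()] (burn-in 5,000 then 10,000 iterations keeping
#' every 10th, two chains), which mixes adequately for the lattice sizes
#' used in examples and simulation studies.
#'
#' @param n_iter post-burn-in sampling iterations per chain.
#' @param burn_in discarded iterations per chain.
#' @param thin keep every `thin`-th post-burn-in iteration.
#' @param n_chains number of chains (>= 2 needed for convergence
#'   diagnostics).
#' @param seed integer seed; chain `c` uses `seed + c - 1`.
#' @param proposal_sd initial random-walk proposal scale.
#' @param adapt adapt proposal scales during burn-in (Robbins-Monro,
#'   targeting acceptance 0.3-0.5); scales are frozen after burn-in so
#'   kept draws satisfy detailed balance.
#' @return list of class `"mcmc_config"`.
#' @export
mcmc_config <- function(n_iter = 10000, burn_in = 5000, thin = 10,
                        n_chains = 2, seed = 1, proposal_sd = 0.1,
                        adapt = TRUE) {
  stopifnot(n_iter > 0, burn_in >= 0, thin >= 1, n_chains >= 1,
            proposal_sd >= 0)
  structure(list(n_iter = as.integer(n_iter),
                 burn_in = as.integer(burn_in), thin = as.integer(thin),
                 n_chains = as.integer(n_chains), seed = as.integer(seed),
                 proposal_sd = proposal_sd, adapt = isTRUE(adapt)),
            class = "mcmc_config")
}

#' The MCMC schedule used in long production runs
#'
#' 100,000 sampling iterations keeping every 10th after a burn-in of
#' 50,000, the WinBUGS-era schedule typical for disease-mapping models
#' of this size.
#'
#' @param n_chains,seed see [mcmc_config()].
#' @return an [mcmc_config()].
#' @export
production_schedule <- function(n_chains = 2, seed = 1) {
  mcmc_config(n_iter = 100000, burn_in = 50000, thin = 10,
              n_chains = n_chains, seed = seed)
}

#' Intrinsic CAR quadratic form
#'
#' `Q(u) = sum over unordered neighbour pairs (i, j) of (u_i - u_j)^2`,
#' the pairwise-difference quadratic form of the intrinsic conditional
#' autoregressive (ICAR) prior.  Translation-invariant: adding a constant
#' (per connected component) leaves it unchanged.
#'
#' @param u per-area values aligned to `adj` (length `n_areas`).
#' @param adj an [adjacency()] object.
#' @return scalar `Q(u)`.
#' @export
icar_quadratic_form <- function(u, adj) {
  stopifnot(inherits(adj, "adjacency"))
  if (length(u) != adj$n_areas)
    stop("u must have one value per area (", adj$n_areas, ")")
  if (!nrow(adj$edges)) return(0)
  idx <- stats::setNames(seq_len(adj$n_areas), adj$area_ids)
  i <- idx[adj$edges[, 1L]]
  j <- idx[adj$edges[, 2L]]
  sum((u[i] - u[j])^2)
}

#' Intrinsic CAR log-density
#'
#' Improper joint density of the ICAR field, defined up to a constant on
#' the per-component sum-to-zero subspace:
#' `(n_eff / 2) * log(tau) - (tau / 2) * Q(u)` with
#' `n_eff = n - #components` (the rank of the graph Laplacian).
#'
#' @param u per-area values.
#' @param adj an [adjacency()] object.
#' @param tau conditional precision (> 0).
#' @return unnormalized log-density (constant omitted).
#' @export
icar_log_density <- function(u, adj, tau) {
  stopifnot(tau > 0)
  n_eff <- adj$n_areas - adj$n_components
  (n_eff / 2) * log(tau) - (tau / 2) * icar_quadratic_form(u, adj)
}

#' ICAR full conditional for one area
#'
#' Under the ICAR prior, `u_i | u_{-i} ~ Normal(mean of neighbours,
#' 1 / (tau * d_i))`.  Undefined for isolated areas (degree 0), whose
#' spatial effect falls back to an exchangeable `Normal(0, 1/tau)` in
#' the samplers.
#'
#' @param u per-area values.
#' @param i area index (1-based).
#' @param adj an [adjacency()] object.
#' @param tau conditional precision.
#' @return list with `mean` and `precision`.
#' @export
icar_full_conditional <- function(u, i, adj, tau) {
  stopifnot(inherits(adj, "adjacency"))
  if (length(u) != adj$n_areas) stop("u misaligned with adjacency")
  nb <- neighbour_list(adj)[[i]]
  if (!length(nb))
    stop("area ", adj$area_ids[i],
         " is isolated (degree 0); ICAR conditional undefined ",
         "(samplers use an exchangeable Normal(0, tau) fallback)")
  list(mean = mean(u[nb]), precision = tau * length(nb))
}

#' Conjugate Gibbs draw for a precision parameter
#'
#' With a `Gamma(prior_shape, prior_rate)` prior on the precision and a
#' Gaussian quadratic form of rank `n_eff` (ICAR: `Q(u)` with
#' `n_eff = n - #components`; exchangeable: `sum(x^2)` with `n_eff = n`),
#' the full conditional is
#' `Gamma(prior_shape + n_eff/2, prior_rate + quadratic/2)`.
#'
#' @param quadratic the quadratic form value (>= 0, finite).
#' @param n_eff effective rank.
#' @param prior_shape,prior_rate Gamma prior parameters (> 0).
#' @return one precision draw (uses the current R RNG stream).
#' @export
gibbs_update_precision <- function(quadratic, n_eff, prior_shape = 0.5,
                                   prior_rate = 0.0005) {
  if (!is.finite(quadratic) || quadratic < 0)
    stop("quadratic form must be finite and >= 0")
  stopifnot(prior_shape > 0, prior_rate > 0, n_eff >= 0)
  stats::rgamma(1L, shape = prior_shape + n_eff / 2,
                rate = prior_rate + quadratic / 2)
}

#' Single-site random-walk Metropolis update
#'
#' Symmetric Gaussian random-walk proposal; accepts with probability
#' `min(1, exp(log_target(prop) - log_target(current)))`.  A proposal
#' where `log_target` is `NaN` is rejected (with a one-time warning);
#' `-Inf` proposals are rejected silently (hard constraint).
#'
#' @param current current value (log_target must be finite here).
#' @param log_target function returning the unnormalized log posterior.
#' @param proposal_sd random-walk standard deviation.
#' @return list with `value` and logical `accepted`.
#' @export
mh_update_site <- function(current, log_target, proposal_sd) {
  lt0 <- log_target(current)
  if (!is.finite(lt0)) stop("log_target must be finite at current value")
  prop <- current + stats::rnorm(1L, 0, proposal_sd)
  lt1 <- log_target(prop)
  if (is.nan(lt1)) {
    if (!isTRUE(getOption("arealvar.nan_warned"))) {
      warning("log_target returned NaN at a proposal; rejecting",
              call. = FALSE)
      options(arealvar.nan_warned = TRUE)
    }
    return(list(value = current, accepted = FALSE))
  }
  if (is.finite(lt1) && log(stats::runif(1L)) < lt1 - lt0)
    list(value = prop, accepted = TRUE)
  else
    list(value = current, accepted = FALSE)
}

#' Per-component sum-to-zero centering
#'
#' Subtracts the mean of `field` within each connected component of the
#' graph, returning the centered field and the absorbed constants so the
#' caller can fold them into intercepts.  Applied after every full sweep
#' over an ICAR field to keep it identified against the flat intercept.
#'
#' @param field per-area values.
#' @param adj an [adjacency()] object.
#' @return list with `field` (centered) and `absorbed` (one constant per
#'   component, in component order).
#' @export
center_sum_to_zero <- function(field, adj) {
  stopifnot(inherits(adj, "adjacency"))
  if (length(field) != adj$n_areas) stop("field misaligned with adjacency")
  comp <- adj$components
  means <- tapply(field, comp, mean)
  list(field = field - as.numeric(means[as.character(comp)]),
       absorbed = as.numeric(means))
}

#' Split-chain potential scale reduction factor
#'
#' Brooks-Gelman-Rubin diagnostic, computed on split chains: each chain
#' is halved, and the PSRF `sqrt(((n-1)/n * W + B/n) / W)` compares
#' between- to within-half variances.  Values above ~1.1 indicate
#' non-convergence.
#'
#' @param draws matrix of draws, one column per chain (>= 2 chains,
#'   >= 10 kept iterations each), for a single scalar parameter.
#' @return scalar R-hat (NA if the parameter is constant everywhere).
#' @export
rhat <- function(draws) {
  draws <- as.matrix(draws)
  if (ncol(draws) < 2L)
    stop("rhat needs >= 2 chains; rerun with n_chains >= 2")
  if (nrow(draws) < 10L) stop("rhat needs >= 10 kept iterations per chain")
  half <- floor(nrow(draws) / 2)
  splits <- cbind(draws[seq_len(half), , drop = FALSE],
                  draws[half + seq_len(half), , drop = FALSE])
  m <- ncol(splits)
  n <- nrow(splits)
  means <- colMeans(splits)
  vars <- apply(splits, 2L, stats::var)
  W <- mean(vars)
  B <- n * stats::var(means)
  if (!is.finite(W) || W == 0) {
    # constant within every split: identical chains converge trivially
    return(if (B == 0 || !is.finite(B)) NA_real_ else Inf)
  }
  sqrt(((n - 1) / n * W + B / n) / W)
}

#' Convergence report over a set of monitored scalars
#'
#' @param draws_list named list of chain matrices (rows = kept
#'   iterations, cols = chains), one entry per monitored scalar.
#' @param threshold flag parameters with R-hat above this (default 1.1).
#' @return data.frame with `parameter`, `rhat`, `converged`.
#' @export
convergence_report <- function(draws_list, threshold = 1.1) {
  rh <- vapply(draws_list, rhat, numeric(1))
  data.frame(parameter = names(draws_list), rhat = unname(rh),
             converged = is.na(rh) | rh <= threshold,
             stringsAsFactors = FALSE)
}

#' Deviance information criterion
#'
#' `pD = mean(deviance draws) - deviance at the posterior mean of the
#' parameters`; `DIC = mean(deviance) + pD`.  The Poisson deviance used
#' throughout the package is `-2 * sum(dpois(o, m, log = TRUE))` (no
#' saturated term), matching the WinBUGS convention, so DIC values are
#' comparable across models fitted by this package.
#'
#' @param deviance_draws vector of deviance evaluations over kept draws.
#' @param deviance_at_mean deviance at the posterior mean parameters.
#' @return list with `dic`, `pd`, `mean_deviance`.  A negative `pD` is
#'   returned with a warning (a recognized pathology of DIC).
#' @export
dic <- function(deviance_draws, deviance_at_mean) {
  if (any(!is.finite(deviance_draws)) || !is.finite(deviance_at_mean))
    stop("deviance inputs must be finite")
  dbar <- mean(deviance_draws)
  pd <- dbar - deviance_at_mean
  if (pd < 0)
    warning("negative pD (", format(pd),
            "); DIC is unreliable for this fit", call. = FALSE)
  list(dic = dbar + pd, pd = pd, mean_deviance = dbar)
}

poisson_deviance <- function(o, mu) {
  -2 * sum(stats::dpois(o, lambda = mu, log = TRUE))
}

#' Persist posterior draws as a long-format table
#'
#' @param fit a `bym_fit` or `scm_fit` object.
#' @param path output path (`.tsv` for tab, otherwise comma).
#' @param parameters which scalar/vector parameters to write (default:
#'   all stored).
#' @return `path`, invisibly.
#' @export
write_draws <- function(fit, path, parameters = NULL) {
  s <- fit$samples
  if (is.null(parameters)) parameters <- names(s$draws)
  rows <- list()
  for (p in parameters) {
    m <- s$draws[[p]]
    for (d in seq_len(ncol(m))) {
      nm <- if (ncol(m) == 1L) p else paste0(p, "[", d, "]")
      rows[[length(rows) + 1L]] <- data.frame(
        chain = s$chain, iteration = s$iteration, parameter = nm,
        value = m[, d], stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(tab, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
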