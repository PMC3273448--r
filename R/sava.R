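#' Indirect utilization ratios with exact Poisson intervals
#'
#' The indirect utilization ratio `IUR_i = o_i / e_i` is the maximum
#' likelihood estimate of the area risk `rho_i` under the saturated model
#' `o_i ~ Poisson(e_i * rho_i)`.  Exact intervals come from the
#' Poisson-gamma relationship (Garwood intervals): at coverage `level`,
#' `lower = qgamma((1 - level)/2, o_i) / e_i` (0 when `o_i = 0`) and
#' `upper = qgamma(1 - (1 - level)/2, o_i + 1) / e_i`.
#'
#' @param counts an [areal_counts()] object.
#' @param level interval coverage probability, in (0, 1).
#' @return data.frame with columns `area_id`, `observed`, `expected`,
#'   `iur`, `ci_low`, `ci_high`, `significant_high`, `significant_low`
#'   (interval entirely above / below 1).
#' @export
indirect_utilization_ratio <- function(counts, level = 0.95) {
  stopifnot(inherits(counts, "areal_counts"))
  if (!(level > 0 && level < 1)) stop("level must be in (0, 1)")
  o <- unname(counts$observed)
  e <- unname(counts$expected)
  if (any(e <= 0)) stop("all expected counts must be > 0")
  a <- (1 - level) / 2
  lo <- ifelse(o == 0, 0, stats::qgamma(a, shape = o) / e)
  hi <- stats::qgamma(1 - a, shape = o + 1) / e
  data.frame(area_id = counts$area_ids, observed = o, expected = e,
             iur = o / e, ci_low = lo, ci_high = hi,
             significant_high = lo > 1, significant_low = hi < 1,
             stringsAsFactors = FALSE)
}

#' Extremal quotient of per-area rates
#'
#' Ratio of a high to a low percentile of the area rate distribution
#' (default 95th over 5th), a classical scale-free spread measure for
#' utilization rates.  Percentiles use linear interpolation between
#' order statistics (`stats::quantile` type 7).
#'
#' @param rates positive per-area rates.
#' @param lo,hi percentile bounds in (0, 100), `lo < hi`.
#' @return scalar ratio (>= 1 for `hi > lo`).
#' @export
extremal_quotient <- function(rates, lo = 5, hi = 95) {
  if (any(!is.finite(rates)) || any(rates <= 0))
    stop("all rates must be > 0")
  if (!(lo < hi)) stop("lo must be < hi")
  q <- stats::quantile(rates, c(lo, hi) / 100, names = FALSE, type = 7)
  q[2L] / q[1L]
}

#' Coefficient of variation of per-area rates
#'
#' Unweighted: sample standard deviation (n - 1 denominator) over the
#' mean.  Weighted (typically by population): standard deviation about
#' the weighted mean with weights normalized to sum to one,
#' `sqrt(sum(w * (r - mw)^2)) / mw`.
#'
#' @param rates per-area rates.
#' @param weights optional positive weights aligned with `rates`.
#' @return scalar CV (>= 0).
#' @export
coefficient_of_variation <- function(rates, weights = NULL) {
  if (!length(rates)) stop("rates must be non-empty")
  if (is.null(weights)) {
    m <- mean(rates)
    if (m <= 0) stop("mean rate must be > 0")
    if (length(rates) < 2L) return(0)
    return(stats::sd(rates) / m)
  }
  if (length(weights) != length(rates) || any(weights <= 0))
    stop("weights must be positive and aligned with rates")
  w <- weights / sum(weights)
  mw <- sum(w * rates)
  if (mw <= 0) stop("weighted mean rate must be > 0")
  sqrt(sum(w * (rates - mw)^2)) / mw
}

#' Systematic component of variation
#'
#' McPherson's noise-corrected measure of between-area variation in
#' observed/expected ratios, on the natural scale:
#' `SCV = (1/n) * sum(((o_i - e_i)/e_i)^2 - 1/e_i)`.
#' The `1/e_i` term removes the within-area Poisson sampling variance, so
#' SCV estimates the systematic (between-area) component only; it can be
#' negative when observed variation is below Poisson expectation.
#'
#' @param counts an [areal_counts()] object.
#' @return scalar SCV.
#' @export
systematic_component_of_variation <- function(counts) {
  stopifnot(inherits(counts, "areal_counts"))
  o <- unname(counts$observed)
  e <- unname(counts$expected)
  if (any(e <= 0)) stop("all expected counts must be > 0")
  mean(((o - e) / e)^2 - 1 / e)
}

#' Empirical-Bayes variance statistic
#'
#' Marshall-type method-of-moments estimate of the between-area variance
#' of the relative risks: with `r_i = o_i/e_i` and the pooled ratio
#' `rbar = sum(o)/sum(e)`,
#' `EB = max(0, sum(e_i * (r_i - rbar)^2) / sum(e) - rbar * n / sum(e))`.
#' The subtracted term is the expected contribution of Poisson noise;
#' the estimate is truncated at zero.
#'
#' @param counts an [areal_counts()] object.
#' @return scalar EB (>= 0).
#' @export
empirical_bayes_statistic <- function(counts) {
  stopifnot(inherits(counts, "areal_counts"))
  o <- unname(counts$observed)
  e <- unname(counts$expected)
  if (any(e <= 0)) stop("all expected counts must be > 0")
  rbar <- sum(o) / sum(e)
  r <- o / e
  max(0, sum(e * (r - rbar)^2) / sum(e) - rbar * length(o) / sum(e))
}

sava_point_estimates <- function(o, e, N, eq_lo, eq_hi) {
  rates <- o / N
  cc <- areal_counts(paste0("a", seq_along(o)), o, N, expected = e)
  c(eq  = if (all(rates > 0)) extremal_quotient(rates, eq_lo, eq_hi)
          else NA_real_,
    cv  = coefficient_of_variation(rates),
    cvw = coefficient_of_variation(rates, weights = N),
    scv = systematic_component_of_variation(cc),
    eb  = empirical_bayes_statistic(cc))
}

#' Statistics of variation with bootstrap intervals
#'
#' Assembles the five classical small-area variation statistics — EQ
#' (95th/5th percentile ratio of crude rates), CV, population-weighted
#' CV, SCV and the EB variance statistic — with percentile confidence
#' intervals from a parametric bootstrap: each replicate redraws
#' `o_i* ~ Poisson(e_i * (o_i/e_i)) = Poisson(o_i)` and recomputes every
#' statistic (expected counts are held fixed; rates use the fixed
#' populations).  Replicates where a statistic is undefined (e.g. a zero
#' bootstrap rate for EQ) are dropped for that statistic.
#'
#' @param counts an [areal_counts()] object with at least 2 areas.
#' @param n_boot bootstrap replicates (0 = point estimates only).
#' @param level interval coverage probability.
#' @param seed integer seed; results are reproducible given the seed.
#' @param eq_lo,eq_hi percentile bounds for the extremal quotient.
#' @return object of class `"variation_statistics"`: data.frame with one
#'   row per statistic and columns `statistic`, `estimate`, `ci_low`,
#'   `ci_high`, `n_boot_used`.
#' @export
variation_statistics <- function(counts, n_boot = 1000, level = 0.95,
                                 seed = 1, eq_lo = 5, eq_hi = 95) {
  stopifnot(inherits(counts, "areal_counts"))
  if (counts$n_areas < 2L) stop("at least 2 areas are required")
  o <- unname(counts$observed)
  e <- unname(counts$expected)
  N <- unname(counts$population)
  est <- sava_point_estimates(o, e, N, eq_lo, eq_hi)
  out <- data.frame(statistic = names(est), estimate = unname(est),
                    ci_low = NA_real_, ci_high = NA_real_,
                    n_boot_used = 0L, stringsAsFactors = FALSE)
  if (n_boot > 0) {
    set.seed(seed)
    boot <- matrix(NA_real_, nrow = n_boot, ncol = length(est),
                   dimnames = list(NULL, names(est)))
    for (b in seq_len(n_boot)) {
      ob <- stats::rpois(length(o), lambda = o)
      boot[b, ] <- tryCatch(sava_point_estimates(ob, e, N, eq_lo, eq_hi),
                            error = function(err) rep(NA_real_, 5L))
    }
    a <- (1 - level) / 2
    for (k in seq_along(est)) {
      v <- boot[, k]
      v <- v[is.finite(v)]
      out$n_boot_used[k] <- length(v)
      if (length(v)) {
        ci <- stats::quantile(v, c(a, 1 - a), names = FALSE, type = 7)
        out$ci_low[k] <- ci[1L]
        out$ci_high[k] <- ci[2L]
      }
    }
  }
  class(out) <- c("variation_statistics", "data.frame")
  out
}
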