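#' Rook-neighbourhood lattice adjacency
#'
#' Regular `n_rows` by `n_cols` grid in which two cells are neighbours
#' when they share an edge — a generic stand-in for small-area maps
#' where areas sharing a boundary are neighbours.  Areas are ordered
#' row-major and labelled `r<row>c<col>`.
#'
#' @param n_rows,n_cols grid dimensions (>= 1).
#' @return an [adjacency()] object with `n_rows * n_cols` areas.
#' @examples
#' grid_adjacency(3, 3)$degrees  # corners 2, edges 3, centre 4
#' @export
grid_adjacency <- function(n_rows, n_cols) {
  stopifnot(n_rows >= 1, n_cols >= 1)
  id <- function(r, c) sprintf("r%dc%d", r, c)
  ids <- as.vector(t(outer(seq_len(n_rows), seq_len(n_cols), id)))
  edges <- NULL
  right <- expand.grid(r = seq_len(n_rows), c = seq_len(n_cols - 1))
  down <- expand.grid(r = seq_len(n_rows - 1), c = seq_len(n_cols))
  if (nrow(right))
    edges <- rbind(edges, cbind(id(right$r, right$c),
                                id(right$r, right$c + 1)))
  if (nrow(down))
    edges <- rbind(edges, cbind(id(down$r, down$c),
                                id(down$r + 1, down$c)))
  adjacency(ids, edges)
}

#' Forward draw from the intrinsic CAR prior
#'
#' Samples a field from the ICAR distribution restricted to the
#' sum-to-zero subspace, via the eigen-decomposition of the graph
#' Laplacian (the zero eigenvalue excluded), then rescales it so its
#' empirical marginal variance `sum((x - mean(x))^2) / (n - 1)` equals
#' `target_marginal_variance` exactly.  The variance-partition
#' quantities estimated by the models are defined on exactly this
#' empirical variance, so simulations control the estimand directly.
#'
#' @param adj a connected [adjacency()] object (>= 2 areas).
#' @param target_marginal_variance target empirical variance (>= 0;
#'   0 returns the zero field).
#' @param seed optional integer seed; if `NULL` the current RNG stream
#'   is used.
#' @return numeric per-area field with mean exactly 0.
#' @export
sample_icar_field <- function(adj, target_marginal_variance,
                              seed = NULL) {
  stopifnot(inherits(adj, "adjacency"),
            target_marginal_variance >= 0)
  if (adj$n_components > 1L)
    stop("sample_icar_field requires a connected adjacency graph")
  n <- adj$n_areas
  if (n < 2L) stop("need at least 2 areas")
  if (!is.null(seed)) set.seed(seed)
  if (target_marginal_variance == 0) return(numeric(n))
  idx <- stats::setNames(seq_len(n), adj$area_ids)
  L <- matrix(0, n, n)
  i <- idx[adj$edges[, 1L]]; j <- idx[adj$edges[, 2L]]
  for (k in seq_along(i)) {
    L[i[k], j[k]] <- L[i[k], j[k]] - 1
    L[j[k], i[k]] <- L[j[k], i[k]] - 1
  }
  diag(L) <- unname(adj$degrees)
  eg <- eigen(L, symmetric = TRUE)
  keep <- eg$values > 1e-9 * max(eg$values)
  z <- stats::rnorm(sum(keep))
  x <- eg$vectors[, keep, drop = FALSE] %*% (z / sqrt(eg$values[keep]))
  x <- as.numeric(x)
  x <- x - mean(x)
  x * sqrt(target_marginal_variance / (sum(x^2) / (n - 1)))
}

#' Simulation parameters for paired areal count data
#'
#' Defaults emulate a national hospital-admission study of elderly
#' patients across ~180 healthcare areas: a 12 x 15 lattice, per-area
#' gender populations in the thousands-to-tens-of-thousands (lognormal),
#' baseline admission rates 21.4 per 100 (men) and 14 per 100 (women),
#' a dominant shared spatial surface (marginal variance 0.08) and small
#' gender-specific spatial (0.004) and unstructured (0.0005 men /
#' 0.0015 women) components, with symmetric loading `delta = 1`.
#'
#' @param n_rows,n_cols lattice dimensions.
#' @param mean_population mean per-area population per gender,
#'   `c(men, women)`.
#' @param pop_sdlog lognormal dispersion of populations (sd of logs).
#' @param rates baseline admission rates per gender, in (0, 1).
#' @param shared_var marginal variance of the shared spatial field.
#' @param female_spatial_var marginal variance of the women-specific
#'   spatial field.
#' @param unstructured_var unstructured variances, `c(men, women)`.
#' @param delta shared-component scaling (> 0).
#' @param seed integer seed.
#' @return list of class `"simulation_params"`.
#' @export
simulation_params <- function(n_rows = 12, n_cols = 15,
                              mean_population = c(men = 6800,
                                                  women = 10900),
                              pop_sdlog = 0.7,
                              rates = c(men = 0.214, women = 0.14),
                              shared_var = 0.08,
                              female_spatial_var = 0.004,
                              unstructured_var = c(men = 0.0005,
                                                   women = 0.0015),
                              delta = 1, seed = 1) {
  stopifnot(all(rates > 0), all(rates < 1), delta > 0,
            shared_var >= 0, female_spatial_var >= 0,
            all(unstructured_var >= 0), all(mean_population > 0),
            pop_sdlog >= 0)
  structure(list(n_rows = n_rows, n_cols = n_cols,
                 mean_population = mean_population,
                 pop_sdlog = pop_sdlog, rates = rates,
                 shared_var = shared_var,
                 female_spatial_var = female_spatial_var,
                 unstructured_var = unstructured_var,
                 delta = delta, seed = as.integer(seed)),
            class = "simulation_params")
}

draw_populations <- function(n, mean_pop, sdlog) {
  if (sdlog == 0) return(rep(mean_pop, n))
  stats::rlnorm(n, meanlog = log(mean_pop) - sdlog^2 / 2, sdlog = sdlog)
}

iid_field <- function(n, variance) {
  if (variance == 0) return(numeric(n))
  stats::rnorm(n, 0, sqrt(variance))
}

#' Simulate paired counts from the shared component generative model
#'
#' Draws populations, latent fields and counts forward from the SCM:
#' `m_1i = e_1i * exp(delta * lambda_i + phi_1i)`,
#' `m_2i = e_2i * exp(lambda_i / delta + beta_i + phi_2i)` with
#' `e_gi = rate_g * N_gi` and `o_gi ~ Poisson(m_gi)`.  The returned
#' dataset carries indirectly standardized expected counts recomputed
#' from the realized observations (as an analyst would construct them);
#' the generative expecteds and all latent fields are kept in the truth
#' record, together with the realized empirical variances and
#' shared/specific variance fractions per gender — the exact estimands
#' of the model's variance partition.
#'
#' @param params a [simulation_params()] object.
#' @return list with `dataset` (a [gender_paired_dataset()]) and
#'   `truth` (latent fields, generative expecteds, realized variances
#'   and fractions).
#' @export
simulate_scm <- function(params = simulation_params()) {
  stopifnot(inherits(params, "simulation_params"))
  set.seed(params$seed)
  adj <- grid_adjacency(params$n_rows, params$n_cols)
  n <- adj$n_areas
  N1 <- draw_populations(n, params$mean_population[[1L]], params$pop_sdlog)
  N2 <- draw_populations(n, params$mean_population[[2L]], params$pop_sdlog)
  e1g <- params$rates[[1L]] * N1
  e2g <- params$rates[[2L]] * N2
  lambda <- sample_icar_field(adj, params$shared_var)
  beta <- sample_icar_field(adj, params$female_spatial_var)
  phi1 <- iid_field(n, params$unstructured_var[[1L]])
  phi2 <- iid_field(n, params$unstructured_var[[2L]])
  d <- params$delta
  m1 <- e1g * exp(d * lambda + phi1)
  m2 <- e2g * exp(lambda / d + beta + phi2)
  o1 <- stats::rpois(n, m1)
  o2 <- stats::rpois(n, m2)

  men <- areal_counts(adj$area_ids, o1, N1)
  women <- areal_counts(adj$area_ids, o2, N2)
  ds <- gender_paired_dataset(adj, men, women)

  v <- function(x) if (all(x == 0)) 0 else stats::var(x)
  rv <- list(men_shared = v(d * lambda), men_unstr = v(phi1),
             women_shared = v(lambda / d), women_spatial = v(beta),
             women_unstr = v(phi2))
  truth <- list(
    lambda = lambda, beta = beta, phi1 = phi1, phi2 = phi2,
    delta = d, e1_generative = e1g, e2_generative = e2g,
    m1 = m1, m2 = m2,
    realized_variances = rv,
    realized_fractions = list(
      men_shared = if (rv$men_shared + rv$men_unstr > 0)
        rv$men_shared / (rv$men_shared + rv$men_unstr) else NA_real_,
      women_shared = if (rv$women_shared + rv$women_spatial +
                           rv$women_unstr > 0)
        rv$women_shared /
          (rv$women_shared + rv$women_spatial + rv$women_unstr)
        else NA_real_),
    params = params)
  list(dataset = ds, truth = truth)
}

#' Simulate single-outcome counts from the BYM generative model
#'
#' Single-outcome analogue of [simulate_scm()]:
#' `o_i ~ Poisson(e_i * exp(u_i + v_i))` with `u` an ICAR field scaled
#' to `spatial_var` and `v` iid `Normal(0, unstructured_var)`.  The
#' truth record stores the fields and the realized spatial fraction
#' `var(u) / (var(u) + var(v))`.
#'
#' @param adjacency a connected [adjacency()] object; `NULL` for the
#'   default 12 x 15 lattice.
#' @param spatial_var target marginal variance of `u`.
#' @param unstructured_var variance of `v`.
#' @param mean_population,pop_sdlog,rate population and rate settings
#'   (defaults at the men's scale of [simulation_params()]).
#' @param seed integer seed.
#' @return list with `counts` (an [areal_counts()]) and `truth`.
#' @export
simulate_bym <- function(adjacency = NULL, spatial_var = 0.054,
                         unstructured_var = 0.022,
                         mean_population = 6800, pop_sdlog = 0.7,
                         rate = 0.214, seed = 1) {
  set.seed(seed)
  adj <- if (is.null(adjacency)) grid_adjacency(12, 15) else adjacency
  stopifnot(inherits(adj, "adjacency"))
  n <- adj$n_areas
  N <- draw_populations(n, mean_population, pop_sdlog)
  e <- rate * N
  u <- sample_icar_field(adj, spatial_var)
  v <- iid_field(n, unstructured_var)
  o <- stats::rpois(n, e * exp(u + v))
  vv <- function(x) if (all(x == 0)) 0 else stats::var(x)
  truth <- list(u = u, v = v, e_generative = e,
                realized_spatial_variance = vv(u),
                realized_unstructured_variance = vv(v),
                realized_spatial_fraction =
                  if (vv(u) + vv(v) > 0) vv(u) / (vv(u) + vv(v))
                  else NA_real_)
  list(counts = areal_counts(adj$area_ids, o, N), adjacency = adj,
       truth = truth)
}

# binary-weight Moran's I; used to verify spatial autocorrelation of
# simulated fields
moran_i <- function(x, adj) {
  idx <- stats::setNames(seq_len(adj$n_areas), adj$area_ids)
  i <- idx[adj$edges[, 1L]]; j <- idx[adj$edges[, 2L]]
  xc <- x - mean(x)
  num <- 2 * sum(xc[i] * xc[j])      # both directions
  w <- 2 * nrow(adj$edges)
  (length(x) / w) * num / sum(xc^2)
}
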