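# Independent literal-formula transcriptions used as oracles.  These are
# deliberately naive (explicit loops, no shared code with the package).

oracle_scv <- function(o, e) {
  n <- length(o)
  acc <- 0
  for (i in seq_len(n)) acc <- acc + ((o[i] - e[i]) / e[i])^2 - 1 / e[i]
  acc / n
}

oracle_eb <- function(o, e) {
  rbar <- sum(o) / sum(e)
  num <- 0
  for (i in seq_along(o)) num <- num + e[i] * (o[i] / e[i] - rbar)^2
  val <- num / sum(e) - rbar * length(o) / sum(e)
  if (val < 0) 0 else val
}

oracle_cv <- function(x) {
  m <- sum(x) / length(x)
  s2 <- 0
  for (xi in x) s2 <- s2 + (xi - m)^2
  sqrt(s2 / (length(x) - 1)) / m
}

oracle_cvw <- function(x, w) {
  w <- w / sum(w)
  mw <- sum(w * x)
  sqrt(sum(w * (x - mw)^2)) / mw
}

# percentile by linear interpolation between order statistics (type 7)
oracle_percentile <- function(x, p) {
  xs <- sort(x)
  h <- (length(xs) - 1) * p + 1
  lo <- floor(h)
  hi <- ceiling(h)
  xs[lo] + (h - lo) * (xs[hi] - xs[lo])
}

oracle_eq <- function(x, lo = 0.05, hi = 0.95) {
  oracle_percentile(x, hi) / oracle_percentile(x, lo)
}

# graph Laplacian of an adjacency object
graph_laplacian <- function(adj) {
  n <- adj$n_areas
  idx <- setNames(seq_len(n), adj$area_ids)
  L <- matrix(0, n, n)
  if (nrow(adj$edges)) {
    i <- idx[adj$edges[, 1]]
    j <- idx[adj$edges[, 2]]
    for (k in seq_along(i)) {
      L[i[k], j[k]] <- L[i[k], j[k]] - 1
      L[j[k], i[k]] <- L[j[k], i[k]] - 1
    }
  }
  diag(L) <- -rowSums(L) + diag(L) * 0
  diag(L) <- unname(adj$degrees)
  L
}

# ICAR log-density via the degenerate multivariate normal on the
# sum-to-zero subspace: eigen-decompose the Laplacian, drop the null
# space, evaluate the proper normal in the eigenbasis.
oracle_icar_logdens <- function(u, adj, tau) {
  L <- graph_laplacian(adj)
  eg <- eigen(L, symmetric = TRUE)
  keep <- eg$values > 1e-9 * max(eg$values)
  w <- as.numeric(t(eg$vectors[, keep, drop = FALSE]) %*% u)
  lam <- eg$values[keep]
  sum(0.5 * log(tau * lam / (2 * pi)) - 0.5 * tau * lam * w^2)
}

# posterior moments of theta for o ~ Poisson(e * exp(theta)),
# theta ~ Normal(mu0, sd0), by adaptive quadrature
oracle_poisson_lognormal_posterior <- function(o, e, mu0 = 0, sd0 = 1) {
  logpost <- function(th) o * th - e * exp(th) +
    dnorm(th, mu0, sd0, log = TRUE)
  mode <- optimize(logpost, c(-20, 20), maximum = TRUE)$maximum
  C <- logpost(mode)
  f0 <- function(th) exp(logpost(th) - C)
  z <- integrate(f0, -20, 20, rel.tol = 1e-10)$value
  m1 <- integrate(function(th) th * f0(th), -20, 20,
                  rel.tol = 1e-10)$value / z
  m2 <- integrate(function(th) th^2 * f0(th), -20, 20,
                  rel.tol = 1e-10)$value / z
  list(mean = m1, sd = sqrt(m2 - m1^2))
}

# Monte-Carlo standard error by batch means
batch_se <- function(x, n_batch = 40) {
  bs <- floor(length(x) / n_batch)
  m <- colMeans(matrix(x[seq_len(bs * n_batch)], nrow = bs))
  sd(m) / sqrt(n_batch)
}

# random small count dataset for oracle comparisons
random_counts <- function(n = 12) {
  N <- round(runif(n, 200, 5000))
  o <- rpois(n, 0.15 * N * exp(rnorm(n, 0, 0.3)))
  o[o == 0] <- 1
  areal_counts(paste0("z", seq_len(n)), o, N)
}
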