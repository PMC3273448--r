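test_that("adjacency construction validates and symmetrizes", {
  adj <- adjacency(c("A", "B", "C", "D"),
                   rbind(c("A", "B"), c("A", "C"), c("B", "D"),
                         c("C", "D")))
  expect_equal(adj$n_areas, 4L)
  expect_equal(unname(adj$degrees), rep(2L, 4))
  expect_equal(adj$n_components, 1L)

  # duplicated direction and duplicated pair stored once
  adj2 <- adjacency(c("A", "B"), rbind(c("A", "B"), c("B", "A"),
                                       c("A", "B")))
  expect_equal(nrow(adj2$edges), 1L)

  expect_error(adjacency(c("A", "A")), "duplicate")
  expect_error(adjacency(c("A", "B"), rbind(c("A", "A"))), "self-loop")
  expect_error(adjacency(c("A", "B"), rbind(c("A", "Z"))), "undeclared")
})

test_that("degenerate single-area structure is accepted", {
  adj <- adjacency("only")
  expect_equal(adj$n_areas, 1L)
  expect_equal(unname(adj$degrees), 0L)
  expect_equal(adj$n_components, 1L)
})

test_that("adjacency files round-trip in both dialects", {
  adj <- grid_adjacency(3, 3)
  expect_equal(unname(adj$degrees), c(2, 3, 2, 3, 4, 3, 2, 3, 2))

  for (fmt in c("adjacency-list", "edge-list")) {
    path <- tempfile(fileext = if (fmt == "edge-list") ".csv" else ".txt")
    write_adjacency(adj, path, fmt)
    back <- load_adjacency(path, fmt, area_ids = adj$area_ids)
    expect_identical(back$area_ids, adj$area_ids)
    expect_identical(back$degrees, adj$degrees)
    expect_identical(sort(paste(back$edges[, 1], back$edges[, 2])),
                     sort(paste(adj$edges[, 1], adj$edges[, 2])))
    # idempotence on the round-tripped output
    path2 <- tempfile(fileext = if (fmt == "edge-list") ".csv" else ".txt")
    write_adjacency(back, path2, fmt)
    expect_identical(load_adjacency(path2, fmt, area_ids = adj$area_ids),
                     back)
  }
})

test_that("degree sum equals twice the edge count on random lattices", {
  for (dims in list(c(1, 2), c(4, 7), c(12, 15))) {
    adj <- grid_adjacency(dims[1], dims[2])
    expect_equal(sum(adj$degrees), 2L * nrow(adj$edges))
  }
})

test_that("expected counts are indirect standardization conserving totals", {
  e <- expected_counts(c(10, 30), c(100, 100))
  expect_equal(attr(e, "rate"), 0.2)
  expect_equal(as.numeric(e), c(20, 20))

  # equal populations and counts -> e_i = o_i
  e2 <- expected_counts(rep(7, 5), rep(350, 5))
  expect_equal(as.numeric(e2), rep(7, 5))

  set.seed(42)
  for (k in 1:20) {
    N <- runif(30, 50, 1e5)
    o <- rpois(30, 0.1 * N)
    e <- expected_counts(o, N)
    expect_lt(abs(sum(e) - sum(o)), 1e-8 * sum(o))
  }
  expect_error(expected_counts(c(1, 2), c(10, 0)), "> 0")
})

test_that("paired dataset validation reports violations without error", {
  sim <- simulate_scm(simulation_params(n_rows = 3, n_cols = 4, seed = 7))
  ds <- sim$dataset
  rep <- validate_paired_dataset(ds)
  expect_length(rep$errors, 0)
  expect_length(rep$warnings, 0)

  perm <- ds
  w <- perm$women
  ord <- rev(seq_len(w$n_areas))
  perm$women <- areal_counts(w$area_ids[ord], w$observed[ord],
                             w$population[ord], w$expected[ord])
  rep2 <- validate_paired_dataset(perm)
  expect_true(any(grepl("misaligned|permuted", rep2$errors)))

  zero <- ds
  zero$men$expected[3] <- 0
  rep3 <- validate_paired_dataset(zero)
  expect_true(any(grepl("non-positive expected", rep3$errors)))

  # disconnected graph: warning, not error
  disc <- ds
  disc$adjacency <- adjacency(ds$adjacency$area_ids)  # no edges at all
  rep4 <- validate_paired_dataset(disc)
  expect_length(rep4$errors, 0)
  expect_true(any(grepl("disconnected", rep4$warnings)))
})

test_that("counts files round-trip, including a gender column", {
  sim <- simulate_scm(simulation_params(n_rows = 2, n_cols = 3, seed = 3))
  path <- tempfile(fileext = ".csv")
  write_counts(sim$dataset$men, path, gender = "men")
  back <- read_counts(path, gender = "men")
  expect_equal(back$observed, sim$dataset$men$observed)
  expect_equal(back$expected, sim$dataset$men$expected, tolerance = 1e-12)
  expect_error(read_counts(path, gender = "women"), "no rows")
  expect_error(read_counts(tempfile(), ), "not found")
})
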