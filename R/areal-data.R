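#' Per-area observed/expected counts
#'
#' Bundles aligned per-area vectors: observed event counts `o_i`,
#' populations at risk `N_i`, and expected counts `e_i`.  If `expected`
#' is omitted it is computed by single-stratum indirect standardization
#' via [expected_counts()].
#'
#' @param area_ids ordered unique area labels.
#' @param observed non-negative integer counts.
#' @param population positive populations at risk.
#' @param expected optional positive expected counts; computed when `NULL`.
#' @return object of class `"areal_counts"`; a list with the four aligned
#'   vectors and `n_areas`.
#' @export
areal_counts <- function(area_ids, observed, population, expected = NULL) {
  area_ids <- as.character(area_ids)
  n <- length(area_ids)
  if (anyDuplicated(area_ids)) stop("duplicate area id(s)")
  if (length(observed) != n || length(population) != n)
    stop("observed and population must align with area_ids")
  observed <- as.numeric(observed)
  if (any(!is.finite(observed)) || any(observed < 0) ||
      any(observed != round(observed)))
    stop("observed must be non-negative integers")
  if (any(!is.finite(population)) || any(population <= 0))
    stop("population must be strictly positive")
  if (is.null(expected)) {
    expected <- expected_counts(observed, population)
  } else {
    if (length(expected) != n) stop("expected must align with area_ids")
    if (any(!is.finite(expected)) || any(expected <= 0))
      stop("expected must be strictly positive")
  }
  structure(
    list(n_areas = n, area_ids = area_ids,
         observed = stats::setNames(observed, area_ids),
         population = stats::setNames(as.numeric(population), area_ids),
         expected = stats::setNames(as.numeric(expected), area_ids)),
    class = "areal_counts"
  )
}

#' @export
print.areal_counts <- function(x, ...) {
  cat("Areal counts:", x$n_areas, "areas; total observed",
      format(sum(x$observed), big.mark = ","), "; crude rate",
      sprintf("%.2f per 100", 100 * sum(x$observed) / sum(x$population)),
      "\n")
  invisible(x)
}

#' Indirectly standardized expected counts
#'
#' Single-stratum indirect standardization: the whole-region rate
#' `r = sum(o) / sum(N)` is applied to each area's population,
#' `e_i = r * N_i`.  The expected count is the number of events the area
#' would record if the region-wide rate held everywhere, so by
#' construction `sum(e) == sum(o)`.  When outcomes are stratified (e.g.
#' by gender) the caller applies this separately per stratum.
#'
#' @param observed per-area counts.
#' @param population per-area populations at risk (all `> 0`).
#' @return numeric vector of expected counts, with the region rate in
#'   attribute `"rate"`.
#' @examples
#' expected_counts(c(10, 30), c(100, 100)) # rate 0.2 -> e = (20, 20)
#' @export
expected_counts <- function(observed, population) {
  if (length(observed) != length(population))
    stop("observed and population must have equal length")
  if (any(!is.finite(population)) || any(population <= 0))
    stop("all populations must be > 0")
  if (any(observed < 0)) stop("observed counts must be >= 0")
  if (sum(population) <= 0) stop("total population must be > 0")
  rate <- sum(observed) / sum(population)
  e <- rate * population
  attr(e, "rate") <- rate
  e
}

#' Pair two outcomes on a common adjacency
#'
#' Aligns per-area counts for two outcomes (conventionally men = outcome
#' 1 and women = outcome 2) on one adjacency structure.  Both outcomes
#' must use exactly the adjacency's area ids in the adjacency's order.
#'
#' @param adjacency an [adjacency()] object.
#' @param men,women [areal_counts()] objects for outcomes 1 and 2.
#' @return object of class `"gender_paired"`.
#' @export
gender_paired_dataset <- function(adjacency, men, women) {
  stopifnot(inherits(adjacency, "adjacency"),
            inherits(men, "areal_counts"),
            inherits(women, "areal_counts"))
  ds <- structure(list(adjacency = adjacency, men = men, women = women),
                  class = "gender_paired")
  rep <- validate_paired_dataset(ds)
  if (length(rep$errors))
    stop("invalid paired dataset:\n  ",
         paste(rep$errors, collapse = "\n  "))
  for (w in rep$warnings) warning(w, call. = FALSE)
  ds
}

#' @export
print.gender_paired <- function(x, ...) {
  cat("Paired areal dataset:", x$adjacency$n_areas, "areas\n")
  cat("  men:   ", sum(x$men$observed), "events /",
      format(sum(x$men$population), big.mark = ","), "at risk\n")
  cat("  women: ", sum(x$women$observed), "events /",
      format(sum(x$women$population), big.mark = ","), "at risk\n")
  invisible(x)
}

#' Validate a paired areal dataset
#'
#' Reporting operation: never throws.  Checks id alignment between the
#' two outcomes and the adjacency, positivity of expected counts, and
#' graph connectivity (a disconnected graph is a warning, not an error;
#' intrinsic CAR machinery handles it by per-component centering).
#'
#' @param ds a list/`"gender_paired"` with `adjacency`, `men`, `women`.
#' @return list with character vectors `errors` and `warnings`; both
#'   empty for a well-formed dataset.
#' @export
validate_paired_dataset <- function(ds) {
  errors <- character(0)
  warnings <- character(0)
  adj <- ds$adjacency
  for (nm in c("men", "women")) {
    cc <- ds[[nm]]
    if (!identical(as.character(cc$area_ids),
                   as.character(adj$area_ids))) {
      errors <- c(errors, paste0(
        nm, ": area ids misaligned with adjacency (same set, different ",
        "order, or different set)"))
    }
    zero <- which(!is.finite(cc$expected) | cc$expected <= 0)
    if (length(zero)) {
      errors <- c(errors, paste0(
        nm, ": non-positive expected count in area(s) ",
        paste(cc$area_ids[zero], collapse = ", ")))
    }
  }
  if (!identical(as.character(ds$men$area_ids),
                 as.character(ds$women$area_ids))) {
    errors <- c(errors, "men and women area ids differ or are permuted")
  }
  if (adj$n_components > 1L) {
    warnings <- c(warnings, paste0(
      "adjacency graph is disconnected (", adj$n_components,
      " components); ICAR fields will be centered per component"))
  }
  list(errors = unique(errors), warnings = warnings)
}

#' Read per-area counts from a delimited file
#'
#' Expects a header with columns `area_id`, `observed`, `population` and
#' optionally `expected` and `gender`.  The delimiter is auto-detected
#' from the extension (`.tsv` = tab, otherwise comma).  With a `gender`
#' column the file holds both outcomes and `gender` selects one.
#'
#' @param path file path.
#' @param gender optional value to filter the `gender` column on
#'   (`"men"` or `"women"`).
#' @return an [areal_counts()] object.
#' @export
read_counts <- function(path, gender = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  tab <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  need <- c("area_id", "observed", "population")
  miss <- setdiff(need, names(tab))
  if (length(miss)) stop("missing column(s): ", paste(miss, collapse = ", "))
  if (!is.null(gender)) {
    if (!"gender" %in% names(tab))
      stop("file has no gender column but gender = \"", gender,
           "\" was requested")
    tab <- tab[tab$gender == gender, , drop = FALSE]
    if (!nrow(tab)) stop("no rows with gender == \"", gender, "\"")
  }
  areal_counts(tab$area_id, tab$observed, tab$population,
               expected = if ("expected" %in% names(tab)) tab$expected)
}

#' Write per-area counts to a delimited file
#'
#' @param counts an [areal_counts()] object.
#' @param path output path (`.tsv` for tab, otherwise comma).
#' @param gender optional label written in a `gender` column.
#' @return `path`, invisibly.
#' @export
write_counts <- function(counts, path, gender = NULL) {
  stopifnot(inherits(counts, "areal_counts"))
  df <- data.frame(area_id = counts$area_ids,
                   observed = unname(counts$observed),
                   population = unname(counts$population),
                   expected = unname(counts$expected),
                   stringsAsFactors = FALSE)
  if (!is.null(gender)) df$gender <- gender
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}
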