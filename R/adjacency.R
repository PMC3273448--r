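#' Build a validated adjacency structure
#'
#' An adjacency structure records which small areas are neighbours
#' (classically, areas sharing a common boundary).  It is the `W` matrix
#' of conditional autoregressive models, stored sparsely as an unordered
#' edge set.  The area ordering fixed here is the canonical index for
#' every per-area vector used downstream.
#'
#' @param area_ids character or integer vector of unique area labels; the
#'   order given is kept.
#' @param edges two-column matrix or data.frame of area ids, one row per
#'   neighbour pair.  Pairs are stored unordered; a pair listed in both
#'   directions (or twice) is kept once.
#' @return An object of class `"adjacency"`: a list with `n_areas`,
#'   `area_ids`, `edges` (two-column character matrix, each unordered pair
#'   once, lexicographically ordered within row), `degrees` (named integer
#'   vector), `components` (integer membership vector, 1-based) and
#'   `n_components`.
#' @examples
#' adj <- adjacency(c("A", "B", "C"), rbind(c("A", "B"), c("B", "C")))
#' adj$degrees
#' @export
adjacency <- function(area_ids, edges = NULL) {
  area_ids <- as.character(area_ids)
  if (anyDuplicated(area_ids)) {
    stop("duplicate area id(s): ",
         paste(unique(area_ids[duplicated(area_ids)]), collapse = ", "))
  }
  n <- length(area_ids)
  if (n < 1L) stop("at least one area is required")

  if (is.null(edges) || NROW(edges) == 0L) {
    em <- matrix(character(0), ncol = 2L)
  } else {
    em <- as.matrix(edges)[, 1:2, drop = FALSE]
    storage.mode(em) <- "character"
    unknown <- setdiff(c(em), area_ids)
    if (length(unknown)) {
      stop("edge refers to undeclared area id(s): ",
           paste(unknown, collapse = ", "))
    }
    if (any(em[, 1L] == em[, 2L])) {
      bad <- unique(em[em[, 1L] == em[, 2L], 1L])
      stop("self-loop on area id(s): ", paste(bad, collapse = ", "))
    }
    # store each unordered pair once
    em <- t(apply(em, 1L, sort))
    em <- em[!duplicated(paste(em[, 1L], em[, 2L], sep = "\r")), ,
             drop = FALSE]
  }

  idx <- stats::setNames(seq_len(n), area_ids)
  deg <- integer(n)
  if (nrow(em)) {
    tab <- table(factor(c(em), levels = area_ids))
    deg <- as.integer(tab)
  }
  names(deg) <- area_ids

  g <- igraph::graph_from_data_frame(
    d = as.data.frame(em, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = area_ids, stringsAsFactors = FALSE)
  )
  comp <- igraph::components(g)
  membership <- as.integer(comp$membership[area_ids])

  structure(
    list(n_areas = n, area_ids = area_ids, edges = em, degrees = deg,
         components = membership, n_components = comp$no),
    class = "adjacency"
  )
}

#' @export
print.adjacency <- function(x, ...) {
  cat("Adjacency structure:", x$n_areas, "areas,", nrow(x$edges),
      "edges,", x$n_components,
      if (x$n_components == 1L) "component\n" else "components\n")
  if (x$n_components > 1L)
    cat("  (disconnected graph: per-component centering applies)\n")
  invisible(x)
}

#' Neighbour index list of an adjacency structure
#'
#' @param adj an [adjacency()] object.
#' @return list of integer vectors; element `i` holds the (1-based)
#'   indices of the neighbours of area `i`.
#' @export
neighbour_list <- function(adj) {
  stopifnot(inherits(adj, "adjacency"))
  idx <- stats::setNames(seq_len(adj$n_areas), adj$area_ids)
  nb <- vector("list", adj$n_areas)
  for (i in seq_len(adj$n_areas)) nb[[i]] <- integer(0)
  if (nrow(adj$edges)) {
    a <- idx[adj$edges[, 1L]]
    b <- idx[adj$edges[, 2L]]
    for (k in seq_along(a)) {
      nb[[a[k]]] <- c(nb[[a[k]]], b[k])
      nb[[b[k]]] <- c(nb[[b[k]]], a[k])
    }
  }
  lapply(nb, sort)
}

#' Read an adjacency structure from a file
#'
#' Two common interchange dialects for lattice data are supported:
#' \describe{
#'   \item{`"adjacency-list"`}{whitespace-delimited, one line per area:
#'     the area id followed by the ids of its neighbours.  Every area must
#'     have a line (possibly with no neighbours); an edge listed from only
#'     one side is symmetrized.}
#'   \item{`"edge-list"`}{a delimited table (comma or tab, auto-detected
#'     from the `.csv`/`.tsv` extension) with a header and two columns of
#'     area ids.  Areas present only in edges are declared implicitly, in
#'     first-appearance order.}
#' }
#'
#' @param path file path.
#' @param format `"adjacency-list"` or `"edge-list"`.
#' @param area_ids optional full ordered id vector (needed with edge-list
#'   input when some areas have no neighbours).
#' @return an [adjacency()] object.
#' @export
load_adjacency <- function(path, format = c("adjacency-list", "edge-list"),
                           area_ids = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "adjacency-list") {
    lines <- readLines(path)
    lines <- trimws(lines)
    lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
    toks <- strsplit(lines, "[[:space:]]+")
    ids <- vapply(toks, `[`, character(1), 1L)
    edges <- do.call(rbind, lapply(toks, function(tk) {
      if (length(tk) < 2L) return(NULL)
      cbind(tk[1L], tk[-1L])
    }))
    if (any(duplicated(ids))) {
      stop("duplicate area id(s): ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    }
    adjacency(if (is.null(area_ids)) ids else area_ids, edges)
  } else {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    tab <- utils::read.table(path, header = TRUE, sep = sep,
                             colClasses = "character",
                             stringsAsFactors = FALSE)
    if (ncol(tab) < 2L) stop("edge-list must have two columns")
    em <- as.matrix(tab[, 1:2, drop = FALSE])
    ids <- if (is.null(area_ids)) unique(c(t(em))) else area_ids
    adjacency(ids, em)
  }
}

#' Write an adjacency structure
#'
#' Round-trips with [load_adjacency()]: writing and re-reading yields an
#' identical structure.
#'
#' @param adj an [adjacency()] object.
#' @param path output file path.
#' @param format `"adjacency-list"` or `"edge-list"` (the latter uses the
#'   delimiter implied by the path extension).
#' @return `path`, invisibly.
#' @export
write_adjacency <- function(adj, path,
                            format = c("adjacency-list", "edge-list")) {
  format <- match.arg(format)
  stopifnot(inherits(adj, "adjacency"))
  if (format == "adjacency-list") {
    nb <- neighbour_list(adj)
    lines <- vapply(seq_len(adj$n_areas), function(i) {
      paste(c(adj$area_ids[i], adj$area_ids[nb[[i]]]), collapse = " ")
    }, character(1))
    writeLines(lines, path)
  } else {
    sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
    df <- data.frame(from = adj$edges[, 1L], to = adj$edges[, 2L],
                     stringsAsFactors = FALSE)
    utils::write.table(df, path, sep = sep, row.names = FALSE,
                       quote = FALSE)
  }
  invisible(path)
}
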