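#' Construct a protein graph (P-graph) object
#'
#' A `pgraph` is a simple undirected graph with 1-based integer vertex ids
#' and, optionally, a geometry: either explicit coordinates (from which a full
#' Euclidean distance table is derived) or a pairwise distance table supplied
#' directly. Geometry is what the edge-adjustment operations rank candidate
#' edges by; purely topological operations (entropy, spectra) ignore it.
#'
#' Edges are stored canonically: each pair sorted so `u < v`, rows sorted
#' lexicographically, duplicates rejected. Graphs are immutable values —
#' operations that change the edge set ([add_edge()], [remove_edge()]) return
#' a new `pgraph`.
#'
#' @param edges two-column matrix or data frame of vertex pairs (one edge per
#'   row), or anything coercible to that; may have zero rows.
#' @param n vertex count. Defaults to the largest endpoint seen; must be given
#'   explicitly when trailing vertices are isolated.
#' @param coords optional numeric matrix of vertex coordinates (one row per
#'   vertex, 2 or 3 columns). Units are those of the source, Angstroms for
#'   proteins.
#' @param dist optional full symmetric pairwise distance matrix (`n x n`,
#'   zero diagonal, positive off-diagonal; `NA` allowed for unknown pairs).
#'   Ignored when `coords` is given.
#' @return an object of class `pgraph` with fields `n`, `edges` (m x 2 integer
#'   matrix), `geom` (distance matrix or `NULL`), `coords` (or `NULL`), and
#'   optional `segments`/`threshold` filled in by [build_pgraph()].
#' @examples
#' g <- pgraph(rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4)))
#' g
#' graph_density(g)
#' @export
pgraph <- function(edges, n = NULL, coords = NULL, dist = NULL) {
  edges <- canonical_edges(edges)
  n_seen <- if (nrow(edges) > 0) max(edges) else 0L
  if (is.null(n)) {
    n <- n_seen
    if (n < 1L) stop("cannot infer vertex count from an empty edge set; supply `n`")
  }
  n <- as.integer(n)
  if (length(n) != 1L || is.na(n) || n < 1L) stop("`n` must be a positive integer")
  if (n_seen > n) stop("edge endpoint ", n_seen, " exceeds vertex count n = ", n)

  geom <- NULL
  if (!is.null(coords)) {
    coords <- as.matrix(coords)
    storage.mode(coords) <- "double"
    if (nrow(coords) != n) stop("`coords` must have one row per vertex")
    geom <- as.matrix(stats::dist(coords))
    dimnames(geom) <- NULL
  } else if (!is.null(dist)) {
    geom <- as.matrix(dist)
    storage.mode(geom) <- "double"
    if (nrow(geom) != n || ncol(geom) != n) stop("`dist` must be an n x n matrix")
    check_geometry(geom)
    dimnames(geom) <- NULL
  }

  structure(
    list(n = n, edges = edges, geom = geom, coords = coords,
         segments = NULL, threshold = NULL),
    class = "pgraph"
  )
}

# Canonicalize an edge container: integer m x 2, u < v, lexicographic order.
canonical_edges <- function(edges) {
  if (is.null(edges) || (is.matrix(edges) && nrow(edges) == 0) ||
      (!is.matrix(edges) && length(edges) == 0)) {
    return(matrix(integer(0), ncol = 2L))
  }
  if (is.data.frame(edges)) edges <- as.matrix(edges[, 1:2])
  if (!is.matrix(edges)) edges <- matrix(edges, ncol = 2L, byrow = TRUE)
  if (ncol(edges) < 2L) stop("edges must have two columns")
  e <- edges[, 1:2, drop = FALSE]
  if (any(!is.finite(e)) || any(e != round(e)) || any(e < 1))
    stop("edge endpoints must be positive integers")
  storage.mode(e) <- "integer"
  if (any(e[, 1] == e[, 2])) stop("self-loops are not allowed")
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  e <- e[order(e[, 1], e[, 2]), , drop = FALSE]
  if (nrow(e) > 1 && anyDuplicated(paste(e[, 1], e[, 2])))
    stop("duplicate edges are not allowed")
  dimnames(e) <- NULL
  e
}

check_geometry <- function(geom) {
  offd <- geom[row(geom) != col(geom)]
  if (any(abs(diag(geom)) > 1e-12, na.rm = TRUE))
    stop("distance table must have a zero diagonal")
  if (any(offd <= 0, na.rm = TRUE))
    stop("off-diagonal distances must be strictly positive")
  if (any(abs(geom - t(geom)) > 1e-9, na.rm = TRUE))
    stop("distance table must be symmetric")
  invisible(geom)
}

#' @export
print.pgraph <- function(x, ...) {
  cat(sprintf("P-graph: %d vertices, %d edges", x$n, nrow(x$edges)))
  if (x$n >= 2) cat(sprintf(", density %.3f", graph_density(x)))
  cat("\n")
  if (!is.null(x$geom)) cat("  geometry: pairwise distance table present\n")
  if (!is.null(x$threshold))
    cat(sprintf("  contact threshold (AVG): %.3f\n", x$threshold))
  if (!is.null(x$segments))
    cat(sprintf("  built from %d secondary-structure segments (%s)\n",
                nrow(x$segments), paste(x$segments$class, collapse = "")))
  invisible(x)
}

#' @export
plot.pgraph <- function(x, ...) {
  ig <- as_igraph(x)
  layout <- if (!is.null(x$coords)) x$coords[, 1:2, drop = FALSE] else NULL
  igraph::plot.igraph(ig, layout = layout, ...)
  invisible(x)
}

# igraph view of a pgraph; used for shortest paths and connectivity.
as_igraph <- function(g) {
  igraph::make_graph(as.integer(t(g$edges)), n = g$n, directed = FALSE)
}

#' Number of vertices and edges
#'
#' @param g a [pgraph()] object.
#' @return integer count.
#' @export
n_vertices <- function(g) {
  stopifnot(inherits(g, "pgraph"))
  g$n
}

#' @rdname n_vertices
#' @export
n_edges <- function(g) {
  stopifnot(inherits(g, "pgraph"))
  nrow(g$edges)
}

#' Add or remove a single edge, returning a new graph
#'
#' Geometry, coordinates and any builder metadata are carried over unchanged;
#' only the edge set differs.
#'
#' @param g a [pgraph()] object.
#' @param edge length-2 vector of endpoints.
#' @return a new `pgraph`.
#' @export
add_edge <- function(g, edge) {
  stopifnot(inherits(g, "pgraph"))
  edge <- sort(as.integer(edge))
  if (has_edge(g, edge)) stop("edge (", edge[1], ",", edge[2], ") already present")
  out <- g
  out$edges <- canonical_edges(rbind(g$edges, edge))
  out
}

#' @rdname add_edge
#' @export
remove_edge <- function(g, edge) {
  stopifnot(inherits(g, "pgraph"))
  edge <- sort(as.integer(edge))
  hit <- g$edges[, 1] == edge[1] & g$edges[, 2] == edge[2]
  if (!any(hit)) stop("edge (", edge[1], ",", edge[2], ") not present")
  out <- g
  out$edges <- g$edges[!hit, , drop = FALSE]
  out
}

#' @rdname add_edge
#' @export
has_edge <- function(g, edge) {
  stopifnot(inherits(g, "pgraph"))
  edge <- sort(as.integer(edge))
  any(g$edges[, 1] == edge[1] & g$edges[, 2] == edge[2])
}

#' All non-adjacent vertex pairs
#'
#' @param g a [pgraph()] object.
#' @return m x 2 integer matrix of the unordered pairs not joined by an edge.
#' @export
non_edges <- function(g) {
  stopifnot(inherits(g, "pgraph"))
  if (g$n < 2) return(matrix(integer(0), ncol = 2L))
  all_pairs <- t(utils::combn(g$n, 2))
  if (nrow(g$edges) == 0) return(all_pairs)
  key <- function(m) paste(m[, 1], m[, 2])
  all_pairs[!(key(all_pairs) %in% key(g$edges)), , drop = FALSE]
}

#' Degree sequence
#'
#' @param g a [pgraph()] object.
#' @return integer vector of length `n`, entry `i` the degree of vertex `i`.
#' @export
degrees <- function(g) {
  stopifnot(inherits(g, "pgraph"))
  tabulate(as.integer(g$edges), nbins = g$n)
}
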