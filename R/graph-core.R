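#' Shortest-path hop distances from one vertex
#'
#' Breadth-first shortest-path (hop) distances from `u` to every vertex it
#' can reach. Hop distance is kept strictly distinct from geometric edge
#' length throughout the package: `d(u, v)` counts edges, never Angstroms.
#'
#' @param g a [pgraph()] object.
#' @param u vertex id in `1..n`.
#' @return named integer vector mapping reachable vertex ids (names) to hop
#'   distances; `u` itself maps to 0, unreachable vertices are absent.
#' @examples
#' p4 <- named_fixture("P4")
#' bfs_distances(p4, 1)
#' @export
bfs_distances <- function(g, u) {
  stopifnot(inherits(g, "pgraph"))
  u <- as.integer(u)
  if (length(u) != 1L || is.na(u) || u < 1L || u > g$n)
    stop("unknown vertex id: ", u)
  d <- igraph::distances(as_igraph(g), v = u)[1, ]
  names(d) <- seq_len(g$n)
  d <- d[is.finite(d)]
  out <- as.integer(d)
  names(out) <- names(d)
  out
}

# Full hop-distance matrix (Inf marks unreachable pairs).
all_hop_distances <- function(g) {
  igraph::distances(as_igraph(g))
}

#' k-sphere sizes of a vertex
#'
#' The k-distance neighborhood (k-sphere) `N_k(u)` is the set of vertices at
#' hop distance exactly `k` from `u`. This returns the sphere sizes
#' `|N_1(u)|, ..., |N_ecc(u)|` up to the eccentricity of `u`, the largest `k`
#' with a non-empty sphere. On a connected graph the sizes sum to `n - 1`;
#' on a disconnected graph the profile covers only `u`'s component.
#'
#' @inheritParams bfs_distances
#' @return integer vector of sphere sizes; attribute `vertex` records `u`.
#' @examples
#' sphere_sizes(named_fixture("P4"), 1)  # 1, 1, 1
#' sphere_sizes(named_fixture("Y"), 5)   # 1, 2, 1
#' @export
sphere_sizes <- function(g, u) {
  d <- bfs_distances(g, u)
  d <- d[d > 0]
  sizes <- if (length(d) == 0) integer(0) else tabulate(d, nbins = max(d))
  structure(sizes, vertex = as.integer(u))
}

#' Is the graph connected?
#'
#' @param g a [pgraph()] object.
#' @return `TRUE` iff one component spans all vertices (a single vertex
#'   counts as connected).
#' @export
is_connected <- function(g) {
  stopifnot(inherits(g, "pgraph"))
  if (g$n == 1L) return(TRUE)
  igraph::is_connected(as_igraph(g))
}

#' Graph density
#'
#' The fraction of realized vertex pairs, `2|E| / (|V| (|V| - 1))`, ranging
#' from 0 (edgeless) to 1 (complete).
#'
#' @param g a [pgraph()] object with at least two vertices.
#' @return density in `[0, 1]`.
#' @examples
#' graph_density(named_fixture("P4"))  # 0.5
#' @export
graph_density <- function(g) {
  stopifnot(inherits(g, "pgraph"))
  if (g$n < 2) stop("density is undefined for fewer than two vertices")
  2 * nrow(g$edges) / (g$n * (g$n - 1))
}
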