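#' Named reference graphs
#'
#' Small graphs used throughout the documentation and tests, each with a
#' canonical planar embedding so the geometric adjustment operations have
#' lengths to rank:
#'
#' * `C4` — cycle on 4 vertices (unit square, side edges).
#' * `K4` — complete graph on 4 vertices (unit square, all pairs).
#' * `P4` — path 1-2-3-4 (unit-spaced points on a line).
#' * `S4` — star with center `v1` and three leaves.
#' * `X`  — `K4` with edge (2,4) removed (one diagonal of the square).
#' * `Y`  — the 5-vertex graph with edges
#'   (1,2), (1,3), (1,4), (2,3), (3,5); degree sequence (3,2,3,1,1). A
#'   coarse secondary-structure contact graph of the small plant protein
#'   crambin.
#'
#' @param name one of `"C4"`, `"K4"`, `"P4"`, `"S4"`, `"X"`, `"Y"`.
#' @return a [pgraph()] with coordinates; attribute `"provenance"` records
#'   what the fixture is.
#' @examples
#' named_fixture("Y")
#' @export
named_fixture <- function(name) {
  square <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  defs <- list(
    C4 = list(edges = rbind(c(1, 2), c(2, 3), c(3, 4), c(1, 4)),
              coords = square, prov = "cycle on four vertices"),
    K4 = list(edges = t(utils::combn(4, 2)),
              coords = square, prov = "clique on four vertices"),
    P4 = list(edges = rbind(c(1, 2), c(2, 3), c(3, 4)),
              coords = cbind(0:3, 0), prov = "path on four vertices"),
    S4 = list(edges = rbind(c(1, 2), c(1, 3), c(1, 4)),
              coords = rbind(c(0, 0), c(1, 0), c(0, 1), c(-1, 0)),
              prov = "star with three leaves"),
    X = list(edges = rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(3, 4)),
             coords = square, prov = "K4 minus edge (2,4)"),
    Y = list(edges = rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(3, 5)),
             coords = rbind(c(0, 0), c(1, 0), c(0, 1), c(-1, 0), c(0, 2)),
             prov = "five-vertex crambin secondary-structure graph")
  )
  if (!name %in% names(defs))
    stop("unknown fixture '", name, "'; valid names: ",
         paste(names(defs), collapse = ", "))
  d <- defs[[name]]
  g <- pgraph(d$edges, n = nrow(d$coords), coords = d$coords)
  attr(g, "provenance") <- d$prov
  g
}

# Save/restore the caller's RNG stream around seeded generation.
with_seed <- function(seed, code) {
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Seeded random geometric graph
#'
#' Scatters `n` points uniformly in the unit cube, takes the full pairwise
#' Euclidean distance table as geometry, and joins every pair at distance no
#' greater than `multiplier` times the mean pairwise distance — the same
#' mean-distance (AVG) edge rule used for protein contact graphs, so these
#' serve as seeded stand-ins for real P-graphs. `multiplier = 1` reproduces
#' the AVG threshold itself; larger values densify, smaller sparsify.
#'
#' @param n number of vertices (at least 2).
#' @param multiplier threshold multiplier applied to the mean pairwise
#'   distance.
#' @param seed integer seed; the same seed always yields the same graph, and
#'   the caller's RNG stream is left untouched.
#' @return a [pgraph()] with coordinates, geometry, and `threshold` set.
#' @examples
#' g <- random_geometric_graph(8, seed = 42)
#' graph_density(g)
#' @export
random_geometric_graph <- function(n, multiplier = 1, seed = 1L) {
  stopifnot(n >= 2, multiplier >= 0)
  pts <- with_seed(seed, matrix(stats::runif(3 * n), nrow = n, ncol = 3))
  D <- as.matrix(stats::dist(pts))
  thr <- multiplier * mean(D[upper.tri(D)])
  pairs <- t(utils::combn(n, 2))
  edges <- pairs[D[pairs] <= thr + 1e-9 * (1 + thr), , drop = FALSE]
  g <- pgraph(edges, n = n, coords = pts)
  g$threshold <- thr
  g
}

#' Enumerate all connected labeled graphs on up to six vertices
#'
#' Exhaustive generator used as an oracle substrate in property tests: every
#' connected simple graph on `n` labeled vertices appears exactly once (1
#' graph for n = 2, 4 for n = 3, 38 for n = 4, 728 for n = 5, 26704 for
#' n = 6). Guarded at `n <= 6` because the count explodes combinatorially.
#'
#' @param n vertex count, `1 <= n <= 6`.
#' @return list of [pgraph()] objects (no geometry).
#' @examples
#' length(all_connected_graphs(4))  # 38
#' @export
all_connected_graphs <- function(n) {
  stopifnot(n >= 1)
  if (n > 6) stop("n > 6 would enumerate too many graphs; refusing")
  n <- as.integer(n)
  if (n == 1L) return(list(pgraph(NULL, n = 1L)))
  pairs <- t(utils::combn(n, 2))
  m <- nrow(pairs)
  bit <- bitwShiftL(1L, seq_len(n) - 1L)
  full <- sum(bit)
  powers <- bitwShiftL(1L, seq_len(m) - 1L)
  out <- vector("list", 0L)
  for (code in seq_len(2L^m - 1L)) {
    sel <- which(bitwAnd(code, powers) > 0L)
    nb <- integer(n)
    for (j in sel) {
      u <- pairs[j, 1]; v <- pairs[j, 2]
      nb[u] <- bitwOr(nb[u], bit[v])
      nb[v] <- bitwOr(nb[v], bit[u])
    }
    reach <- bit[1L]
    repeat {
      nxt <- reach
      for (v in which(bitwAnd(reach, bit) > 0L)) nxt <- bitwOr(nxt, nb[v])
      if (nxt == reach) break
      reach <- nxt
    }
    if (reach == full)
      out[[length(out) + 1L]] <- pgraph(pairs[sel, , drop = FALSE], n = n)
  }
  out
}
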