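# Independent brute-force oracles: all-pairs shortest paths by matrix
# powers and literal summation of the entropy formulas. Kept deliberately
# naive and separate from the package's own code paths.

oracle_adjacency <- function(g) {
  A <- matrix(0, g$n, g$n)
  if (nrow(g$edges) > 0) {
    A[g$edges] <- 1
    A[g$edges[, 2:1, drop = FALSE]] <- 1
  }
  A
}

oracle_hop_distances <- function(g) {
  n <- g$n
  A <- oracle_adjacency(g)
  D <- matrix(Inf, n, n)
  diag(D) <- 0
  P <- diag(n)
  for (k in seq_len(max(n - 1, 1))) {
    P <- P %*% A
    D[P > 0 & !is.finite(D)] <- k
  }
  D
}

# Literal f(u) = sum_{i=1..ecc(u)} |N_i(u)| / (n - i + 1), per vertex.
oracle_impact <- function(g) {
  D <- oracle_hop_distances(g)
  n <- g$n
  vapply(seq_len(n), function(u) {
    f <- 0
    i <- 1
    repeat {
      Ni <- sum(D[u, ] == i)
      if (Ni == 0) break
      f <- f + Ni / (n - i + 1)
      i <- i + 1
    }
    f
  }, numeric(1))
}

oracle_extended_entropy <- function(g) {
  f <- oracle_impact(g)
  q <- f / sum(f)
  -sum(q * log2(q))
}

# Every labeled simple graph on n vertices (connected or not).
oracle_all_graphs <- function(n) {
  pairs <- t(utils::combn(n, 2))
  m <- nrow(pairs)
  lapply(0:(2^m - 1), function(code) {
    sel <- bitwAnd(code, bitwShiftL(1L, seq_len(m) - 1L)) > 0L
    pgraph(pairs[sel, , drop = FALSE], n = n)
  })
}

# Relabel vertices: new id perm[u] takes the role of old id u.
relabel_pgraph <- function(g, perm) {
  edges <- if (nrow(g$edges) > 0)
    cbind(perm[g$edges[, 1]], perm[g$edges[, 2]]) else NULL
  dist <- NULL
  if (!is.null(g$geom)) {
    dist <- g$geom
    dist[perm, perm] <- g$geom
  }
  pgraph(edges, n = g$n, dist = dist)
}

# Seeded random connected geometric graph; widens the contact threshold
# until the sample is connected so the seed fully determines the result.
rand_connected <- function(seed, n = NULL) {
  if (is.null(n)) n <- 5L + (seed %% 4L)
  mult <- 1
  repeat {
    g <- random_geometric_graph(n, mult, seed = seed)
    if (n_edges(g) > 0 && is_connected(g)) return(g)
    mult <- mult * 1.15
  }
}

fixture_names <- c("C4", "K4", "P4", "S4", "X", "Y")
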