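# Typed conditions for the two table sentinels: NaC ("not a connected
# graph", entropy undefined) and NaN ("no candidate edge remains").
stop_nac <- function(msg) {
  stop(structure(class = c("pg_nac_error", "pg_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

stop_nan <- function(msg) {
  stop(structure(class = c("pg_nan_error", "pg_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

#' Classic degree-sequence graph entropy
#'
#' Shannon entropy of the degree distribution: each vertex gets probability
#' `p_i = deg(v_i) / sum_j deg(v_j)` and the entropy is
#' `I(G) = -sum_i p_i log2 p_i`, in bits. Vertices of degree zero contribute
#' nothing (`0 log 0 = 0` by convention).
#'
#' @param g a [pgraph()] object with at least one edge.
#' @return entropy in bits.
#' @examples
#' degree_entropy(named_fixture("C4"))  # 2
#' degree_entropy(named_fixture("P4"))  # 1.918
#' @export
degree_entropy <- function(g) {
  stopifnot(inherits(g, "pgraph"))
  deg <- degrees(g)
  total <- sum(deg)
  if (total == 0) stop("degree entropy is undefined on an edgeless graph")
  p <- deg[deg > 0] / total
  -sum(p * log2(p))
}

#' k-sphere impact score of a vertex
#'
#' The impact score underlying the extended entropy:
#' `f(u) = sum_{i=1}^{ecc(u)} |N_i(u)| / (n - i + 1)`,
#' summing each k-sphere size weighted by `1 / (n - i + 1)`. Every other
#' vertex contributes, nearer vertices through earlier terms.
#'
#' @param g a connected [pgraph()] with `n >= 2`.
#' @param u vertex id.
#' @return the impact score (dimensionless).
#' @examples
#' vertex_impact(named_fixture("Y"), 1)  # 3/5 + 1/4 = 0.85
#' @export
vertex_impact <- function(g, u) {
  unname(impact_scores(g)[as.integer(u)])
}

#' @describeIn vertex_impact impact scores of all vertices at once.
#' @export
impact_scores <- function(g) {
  stopifnot(inherits(g, "pgraph"))
  if (g$n < 2) stop("impact scores need at least two vertices")
  D <- all_hop_distances(g)
  if (any(!is.finite(D)))
    stop_nac("NaC: graph is not connected, extended entropy is undefined")
  n <- g$n
  f <- vapply(seq_len(n), function(u) {
    d <- D[u, -u]
    sum(1 / (n - d + 1))
  }, numeric(1))
  names(f) <- seq_len(n)
  f
}

#' Impact-normalized vertex distribution
#'
#' Normalizes the impact scores to a probability distribution,
#' `q_i = f(v_i) / f(V)` with `f(V) = sum_v f(v)`.
#'
#' @inheritParams impact_scores
#' @return named numeric vector summing to 1.
#' @export
q_distribution <- function(g) {
  f <- impact_scores(g)
  f / sum(f)
}

#' Extended k-sphere graph entropy
#'
#' The entropy of the impact distribution, `I'(G) = -sum_i q_i log2 q_i`,
#' in bits. Defined only on connected graphs: a disconnected input raises a
#' typed condition (class `pg_nac_error`) carrying the `NaC` sentinel that
#' report writers print in sweep tables.
#'
#' @inheritParams impact_scores
#' @return entropy in bits, in `(0, log2 n]`.
#' @examples
#' extended_entropy(named_fixture("K4"))  # 2
#' extended_entropy(named_fixture("S4"))  # 1.995
#' @export
extended_entropy <- function(g) {
  q <- q_distribution(g)
  -sum(q * log2(q))
}

#' Full entropy summary of a graph
#'
#' Computes the per-vertex impact scores and q-distribution, the extended
#' entropy, the classic degree entropy, and the density, bundled for
#' printing and report writers.
#'
#' @inheritParams impact_scores
#' @return an object of class `graph_entropy` with fields `f`, `q`,
#'   `extended`, `classic`, `density`, `n`.
#' @examples
#' graph_entropy(named_fixture("S4"))
#' @export
graph_entropy <- function(g) {
  f <- impact_scores(g)
  q <- f / sum(f)
  structure(
    list(f = f, q = q,
         extended = -sum(q * log2(q)),
         classic = if (nrow(g$edges) > 0) degree_entropy(g) else NA_real_,
         density = graph_density(g),
         n = g$n),
    class = "graph_entropy"
  )
}

#' @export
print.graph_entropy <- function(x, digits = 3, ...) {
  cat(sprintf("Graph entropy (%d vertices, density %.*f)\n",
              x$n, digits, x$density))
  cat(sprintf("  extended I'(G): %.*f bits\n", digits, x$extended))
  if (!is.na(x$classic))
    cat(sprintf("  classic  I(G):  %.*f bits\n", digits, x$classic))
  tab <- data.frame(vertex = names(x$f),
                    f = round(unname(x$f), digits + 1),
                    q = round(unname(x$q), digits + 1))
  print(tab, row.names = FALSE)
  invisible(x)
}
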