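# Geometric lengths of a set of vertex pairs; errors if geometry is missing
# for any requested pair.
pair_lengths <- function(g, pairs, what) {
  if (is.null(g$geom))
    stop("graph has no geometry; ", what, " needs edge lengths")
  len <- g$geom[pairs]
  if (any(is.na(len)))
    stop("geometry is incomplete for some ", what, " candidates")
  len
}

#' Geometrically longest edge / shortest non-edge
#'
#' Candidate selection for the edge-adjustment rule: `longest_edge()` returns
#' the existing edge of maximal geometric length; `shortest_nonedge()` the
#' non-adjacent pair of minimal length. Ties are broken deterministically by
#' sorting candidates on (length, smaller endpoint, larger endpoint).
#'
#' @param g a [pgraph()] with geometry.
#' @return length-2 integer vector `(u, v)` with `u < v`.
#' @examples
#' longest_edge(named_fixture("X"))    # the diagonal of the square
#' shortest_nonedge(named_fixture("C4"))
#' @export
longest_edge <- function(g) {
  stopifnot(inherits(g, "pgraph"))
  if (nrow(g$edges) == 0) stop("graph has no edges")
  len <- pair_lengths(g, g$edges, "edge")
  ord <- order(-len, g$edges[, 1], g$edges[, 2])
  g$edges[ord[1], ]
}

#' @rdname longest_edge
#' @export
shortest_nonedge <- function(g) {
  stopifnot(inherits(g, "pgraph"))
  cand <- non_edges(g)
  if (nrow(cand) == 0)
    stop_nan("NaN: graph is complete, no edge can be added")
  len <- pair_lengths(g, cand, "non-edge")
  ord <- order(len, cand[, 1], cand[, 2])
  cand[ord[1], ]
}

#' Entropy-driven edge-adjustment decision
#'
#' Evaluates the extended entropy of the current graph (`x`), of the graph
#' with its longest edge removed (`y`), and of the graph with its shortest
#' non-edge added (`z`), then classifies the triple:
#'
#' * **case1** — removing the longest edge disconnects the graph; `y` is
#'   reported as the `NaC` sentinel and iteration stops.
#' * **case2** — `z > x > y`: adding the candidate edge makes the graph more
#'   stable; action `add`.
#' * **case3** — `x > z > y`: the graph is stable enough; action `none`.
#'   A complete graph (no addable edge, `z` unavailable) is also reported
#'   stable.
#' * **case4** — `y > x > z`: removing the candidate edge makes the graph
#'   more stable; action `remove`.
#' * **uncovered** — any other ordering (including exact ties); no action is
#'   taken rather than guessing intent.
#'
#' Higher entropy is read as greater structural stability, so the rule moves
#' one edge at a time in the direction that raises `I'`.
#'
#' @param g a connected [pgraph()] with geometry.
#' @return an object of class `adjustment_decision` with fields `x`, `y`,
#'   `z` (`NA` where unavailable), `y_is_nac`, `z_is_nan`, `case`, `action`
#'   (`"none"`, `"add"`, `"remove"`, or `"stop-disconnected"`),
#'   `removed_edge`, `added_edge`, and the evaluated candidates.
#' @examples
#' adjust_decision(named_fixture("X"))
#' @export
adjust_decision <- function(g) {
  stopifnot(inherits(g, "pgraph"))
  if (!is_connected(g))
    stop_nac("NaC: adjustment needs a connected graph")
  x <- extended_entropy(g)

  e_rm <- longest_edge(g)
  g_minus <- remove_edge(g, e_rm)
  y_is_nac <- !is_connected(g_minus)
  y <- if (y_is_nac) NA_real_ else extended_entropy(g_minus)

  z_is_nan <- nrow(non_edges(g)) == 0
  if (z_is_nan) {
    e_add <- NULL
    z <- NA_real_
  } else {
    e_add <- shortest_nonedge(g)
    z <- extended_entropy(add_edge(g, e_add))
  }

  if (y_is_nac) {
    case <- "case1"; action <- "stop-disconnected"
  } else if (z_is_nan) {
    # x = log2(n) is maximal on a complete graph, so y < x barring ties.
    if (x > y) { case <- "case3"; action <- "none" }
    else { case <- "uncovered"; action <- "none" }
  } else if (z > x && x > y) {
    case <- "case2"; action <- "add"
  } else if (x > z && z > y) {
    case <- "case3"; action <- "none"
  } else if (y > x && x > z) {
    case <- "case4"; action <- "remove"
  } else {
    case <- "uncovered"; action <- "none"
  }

  structure(
    list(x = x, y = y, z = z, y_is_nac = y_is_nac, z_is_nan = z_is_nan,
         case = case, action = action,
         longest_edge = e_rm, shortest_nonedge = e_add,
         removed_edge = if (action == "remove") e_rm else NULL,
         added_edge = if (action == "add") e_add else NULL),
    class = "adjustment_decision"
  )
}

#' @export
print.adjustment_decision <- function(x, digits = 3, ...) {
  fmt <- function(v, sentinel) if (is.na(v)) sentinel else sprintf("%.*f", digits, v)
  cat("Edge-adjustment decision\n")
  cat(sprintf("  x = I'(G)     = %s\n", fmt(x$x, "?")))
  cat(sprintf("  y = I'(G - e) = %s  (e = %d-%d)\n",
              fmt(x$y, "NaC"), x$longest_edge[1], x$longest_edge[2]))
  if (is.null(x$shortest_nonedge)) {
    cat("  z = I'(G + e) = NaN  (graph is complete)\n")
  } else {
    cat(sprintf("  z = I'(G + e) = %s  (e = %d-%d)\n",
                fmt(x$z, "NaN"), x$shortest_nonedge[1], x$shortest_nonedge[2]))
  }
  cat(sprintf("  %s -> action: %s\n", x$case, x$action))
  invisible(x)
}

#' Iterate the adjustment rule
#'
#' Repeatedly applies [adjust_decision()], performing the recommended add or
#' remove, until the rule reports the graph stable (`case3`), removal would
#' disconnect it (`case1`), the ordering is `uncovered`, or `max_steps`
#' decisions have been evaluated.
#'
#' @inheritParams adjust_decision
#' @param max_steps maximum number of decisions to evaluate.
#' @return list with the final `graph` and `trail`, the list of
#'   `adjustment_decision`s in order.
#' @export
adjust_graph <- function(g, max_steps = 10L) {
  stopifnot(inherits(g, "pgraph"), max_steps >= 0)
  trail <- list()
  step <- 0L
  while (step < max_steps) {
    d <- adjust_decision(g)
    trail[[length(trail) + 1L]] <- d
    step <- step + 1L
    if (d$action == "add") g <- add_edge(g, d$added_edge)
    else if (d$action == "remove") g <- remove_edge(g, d$removed_edge)
    else break
  }
  list(graph = g, trail = trail)
}

#' Cumulative +/-ke entropy/density sweep
#'
#' Starting from the input graph (offset 0, the `AVG` column of a sweep
#' table), removes the `k` geometrically longest edges (offset `-k`) or adds
#' the `k` geometrically shortest non-edges (offset `+k`), reporting the
#' extended entropy and density at each offset. Candidates are ranked once
#' from the offset-0 graph and applied cumulatively, so each column is
#' independent of the path taken to reach it.
#'
#' Sentinels: entropy is `NaC` when the pruned graph is disconnected (its
#' density is still well defined and recorded), and a row is `NaN` when no
#' candidate remains (removing more edges than exist, or adding to a
#' complete graph).
#'
#' @param g a [pgraph()] with geometry.
#' @param k_max largest offset swept on either side.
#' @return a data frame of class `entropy_sweep` with columns `offset`,
#'   `label` (`-ke`..`AVG`..`+ke`), `entropy`, `status`
#'   (`"ok"`, `"NaC"`, `"NaN"`), `density`, `n_edges`.
#' @examples
#' entropy_sweep(named_fixture("X"), k_max = 1)
#' @export
entropy_sweep <- function(g, k_max = 3L) {
  stopifnot(inherits(g, "pgraph"), k_max >= 1)
  if (is.null(g$geom)) stop("sweep needs a graph with geometry")
  k_max <- as.integer(k_max)

  rm_len <- pair_lengths(g, g$edges, "edge")
  rm_rank <- g$edges[order(-rm_len, g$edges[, 1], g$edges[, 2]), , drop = FALSE]
  add_cand <- non_edges(g)
  if (nrow(add_cand) > 0) {
    add_len <- pair_lengths(g, add_cand, "non-edge")
    add_rank <- add_cand[order(add_len, add_cand[, 1], add_cand[, 2]), , drop = FALSE]
  } else {
    add_rank <- add_cand
  }

  eval_offset <- function(k) {
    if (k < 0 && -k > nrow(rm_rank)) return(list(NA_real_, "NaN", NA_real_, NA_integer_))
    if (k > 0 && k > nrow(add_rank)) return(list(NA_real_, "NaN", NA_real_, NA_integer_))
    gk <- g
    if (k < 0) for (j in seq_len(-k)) gk <- remove_edge(gk, rm_rank[j, ])
    if (k > 0) for (j in seq_len(k)) gk <- add_edge(gk, add_rank[j, ])
    dens <- graph_density(gk)
    if (!is_connected(gk)) return(list(NA_real_, "NaC", dens, nrow(gk$edges)))
    list(extended_entropy(gk), "ok", dens, nrow(gk$edges))
  }

  offsets <- seq.int(-k_max, k_max)
  rows <- lapply(offsets, eval_offset)
  out <- data.frame(
    offset = offsets,
    label = ifelse(offsets == 0, "AVG",
                   ifelse(offsets < 0, paste0(offsets, "e"), paste0("+", offsets, "e"))),
    entropy = vapply(rows, `[[`, numeric(1), 1),
    status = vapply(rows, `[[`, character(1), 2),
    density = vapply(rows, `[[`, numeric(1), 3),
    n_edges = vapply(rows, `[[`, integer(1), 4),
    stringsAsFactors = FALSE
  )
  class(out) <- c("entropy_sweep", "data.frame")
  out
}

#' @export
print.entropy_sweep <- function(x, digits = 3, ...) {
  cells <- ifelse(x$status == "ok", sprintf("%.*f", digits, x$entropy), x$status)
  dens <- ifelse(x$status == "NaC", "-",
                 ifelse(x$status == "NaN", "NaN", sprintf("%.*f", digits, x$density)))
  tab <- rbind(`I'` = cells, Dens = dens)
  colnames(tab) <- x$label
  print(tab, quote = FALSE)
  invisible(x)
}
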