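#' Graph Laplacian matrix
#'
#' `L = D - A`, with `A` the 0/1 adjacency matrix and `D` the diagonal
#' degree matrix. Symmetric, rows sum to zero, positive semidefinite.
#'
#' @param g a [pgraph()] object.
#' @return an `n x n` integer matrix.
#' @examples
#' graph_laplacian(named_fixture("Y"))
#' @export
graph_laplacian <- function(g) {
  stopifnot(inherits(g, "pgraph"))
  A <- matrix(0L, g$n, g$n)
  if (nrow(g$edges) > 0) {
    A[g$edges] <- 1L
    A[g$edges[, 2:1, drop = FALSE]] <- 1L
  }
  diag(degrees(g), nrow = g$n) - A
}

#' Laplacian spectrum of a graph
#'
#' Eigenvalues of the Laplacian, sorted descending. The spectrum is a
#' relabeling-invariant of the graph: isomorphic graphs are cospectral. Its
#' smallest eigenvalue is 0, and the multiplicity of 0 equals the number of
#' connected components.
#'
#' @param g a [pgraph()] object.
#' @return an object of class `graph_spectrum`: list with `values`
#'   (descending eigenvalues) and `n` (vertex count of the source graph).
#' @examples
#' graph_spectrum(named_fixture("X"))  # 4, 4, 2, 0
#' @export
graph_spectrum <- function(g) {
  L <- graph_laplacian(g)
  values <- eigen(L, symmetric = TRUE, only.values = TRUE)$values
  structure(list(values = values, n = g$n), class = "graph_spectrum")
}

#' @export
print.graph_spectrum <- function(x, digits = 3, ...) {
  cat(sprintf("Laplacian spectrum (n = %d): [%s]\n", x$n,
              paste(sprintf("%.*f", digits, x$values), collapse = ", ")))
  invisible(x)
}

as_spectrum <- function(x) {
  if (inherits(x, "pgraph")) return(graph_spectrum(x))
  if (inherits(x, "graph_spectrum")) return(x)
  if (is.numeric(x)) return(structure(list(values = sort(x, decreasing = TRUE),
                                           n = length(x)),
                                      class = "graph_spectrum"))
  stop("cannot interpret object as a spectrum")
}

#' Zero-padded Euclidean distance between two spectra
#'
#' Compares Laplacian spectra of graphs that may have different vertex
#' counts: the shorter descending eigenvalue vector is padded with trailing
#' zeros to equalize lengths (padding ascendingly would displace the zero
#' eigenvalue), then the Euclidean norm of the difference is returned.
#' Smaller values mean more similar spectra; 0 for cospectral graphs.
#'
#' @param a,b `graph_spectrum` objects, [pgraph()]s, or bare numeric
#'   eigenvalue vectors.
#' @return non-negative real distance.
#' @examples
#' spectral_distance(named_fixture("X"), named_fixture("Y"))
#' @export
spectral_distance <- function(a, b) {
  va <- as_spectrum(a)$values
  vb <- as_spectrum(b)$values
  len <- max(length(va), length(vb))
  va <- c(va, rep(0, len - length(va)))
  vb <- c(vb, rep(0, len - length(vb)))
  sqrt(sum((va - vb)^2))
}

#' Pairwise spectral-distance matrix
#'
#' @param graphs list of [pgraph()] objects (at least two).
#' @param labels optional row/column names; defaults to the list's names or
#'   `G1..Gk`.
#' @return symmetric numeric matrix with zero diagonal, entry `(i, j)` the
#'   zero-padded spectral distance between graphs `i` and `j`.
#' @examples
#' spectral_distance_matrix(list(X = named_fixture("X"), Y = named_fixture("Y")))
#' @export
spectral_distance_matrix <- function(graphs, labels = NULL) {
  if (length(graphs) < 2) stop("need at least two graphs to compare")
  specs <- lapply(graphs, as_spectrum)
  k <- length(specs)
  if (is.null(labels)) {
    labels <- names(graphs)
    if (is.null(labels) || any(labels == "")) labels <- paste0("G", seq_len(k))
  }
  m <- matrix(0, k, k, dimnames = list(labels, labels))
  for (i in seq_len(k - 1)) for (j in (i + 1):k) {
    m[i, j] <- m[j, i] <- spectral_distance(specs[[i]], specs[[j]])
  }
  m
}
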