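#' Old-versus-new comparison verdict
#'
#' Compares a spectral distance obtained under the old graph construction
#' with the one obtained after entropy-driven adjustment: `"+"` when the new
#' distance is smaller (better), `"-"` when larger (worse), and `"="` when
#' the two agree within a relative tolerance (default 0.5%, "not bad").
#'
#' @param old,new non-negative finite distances.
#' @param tol relative tolerance for calling the two equal.
#' @return one of `"+"`, `"="`, `"-"` (vectorized over inputs).
#' @examples
#' verdict(7.93, 7.75)    # "+"
#' verdict(19.33, 19.35)  # "="
#' @export
verdict <- function(old, new, tol = 0.005) {
  stopifnot(is.finite(old), is.finite(new))
  scale <- pmax(abs(old), abs(new))
  out <- ifelse(abs(new - old) <= tol * pmax(scale, .Machine$double.eps), "=",
                ifelse(new < old, "+", "-"))
  unname(out)
}

#' Format a sweep as a Table-style character matrix
#'
#' Two rows per graph — extended entropy (or the `NaC`/`NaN` sentinel) and
#' density — with one column per offset, `-Ke .. AVG .. +Ke`. Density cells
#' print `-` where the graph is disconnected. Values at 3 decimals.
#'
#' @param sweeps a single [entropy_sweep()] result or a named list of them
#'   (all with the same `k_max`).
#' @param digits decimals for entropy and density cells.
#' @return character matrix ready for [write_sweep_report()] or printing.
#' @export
format_sweep_table <- function(sweeps, digits = 3) {
  if (inherits(sweeps, "entropy_sweep")) sweeps <- list(graph = sweeps)
  if (is.null(names(sweeps))) names(sweeps) <- paste0("G", seq_along(sweeps))
  labels <- sweeps[[1]]$label
  rows <- lapply(names(sweeps), function(nm) {
    s <- sweeps[[nm]]
    stopifnot(identical(s$label, labels))
    ent <- ifelse(s$status == "ok", sprintf("%.*f", digits, s$entropy), s$status)
    den <- ifelse(s$status == "NaC", "-",
                  ifelse(s$status == "NaN", "NaN",
                         sprintf("%.*f", digits, s$density)))
    m <- rbind(ent, den)
    rownames(m) <- c(nm, "Dens")
    m
  })
  out <- do.call(rbind, rows)
  colnames(out) <- labels
  out
}

#' Write a sweep report as TSV
#'
#' @inheritParams format_sweep_table
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_sweep_report <- function(sweeps, path, digits = 3) {
  tab <- format_sweep_table(sweeps, digits = digits)
  utils::write.table(cbind(PID = rownames(tab), tab), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Pairwise old-versus-new spectral comparison report
#'
#' For matched lists of graphs built under two constructions (`old`: plain
#' threshold; `new`: after entropy-driven adjustment), computes both
#' pairwise spectral-distance matrices and a [verdict()] for every pair.
#'
#' @param old,new equally long named lists of [pgraph()]s (or spectra).
#' @param tol relative tolerance passed to [verdict()].
#' @return object of class `pgraph_comparison`: list of matrices `old`,
#'   `new`, and character matrix `result`.
#' @export
compare_remodelings <- function(old, new, tol = 0.005) {
  stopifnot(length(old) == length(new), length(old) >= 2)
  d_old <- spectral_distance_matrix(old)
  d_new <- spectral_distance_matrix(new)
  dimnames(d_new) <- dimnames(d_old)
  res <- matrix("·", nrow(d_old), ncol(d_old), dimnames = dimnames(d_old))
  ut <- upper.tri(d_old)
  res[ut] <- verdict(d_old[ut], d_new[ut], tol = tol)
  structure(list(old = d_old, new = d_new, result = res),
            class = "pgraph_comparison")
}

#' @export
print.pgraph_comparison <- function(x, digits = 2, ...) {
  labs <- rownames(x$old)
  k <- length(labs)
  cat("Old vs new spectral distances (upper triangle)\n")
  for (i in seq_len(k - 1)) {
    cells <- function(m, f) vapply((i + 1):k, function(j) f(m[i, j]), "")
    num <- function(v) sprintf("%.*f", digits, v)
    cat(labs[i], "\n")
    cat("  Old:   ", paste(cells(x$old, num), collapse = "\t"), "\n")
    cat("  New:   ", paste(cells(x$new, num), collapse = "\t"), "\n")
    cat("  Result:", paste(cells(x$result, identity), collapse = "\t"), "\n")
  }
  invisible(x)
}

#' Write an old-versus-new comparison report as TSV
#'
#' Upper-triangular layout: per graph a trio of rows (Old, New, Result).
#'
#' @param cmp a [compare_remodelings()] result.
#' @param path output file.
#' @param digits decimals for distance cells.
#' @return `path`, invisibly.
#' @export
write_comparison_report <- function(cmp, path, digits = 2) {
  stopifnot(inherits(cmp, "pgraph_comparison"))
  labs <- rownames(cmp$old)
  k <- length(labs)
  lines <- paste(c("PID", "", labs[-1]), collapse = "\t")
  for (i in seq_len(k - 1)) {
    cell <- function(m, j, f) if (j <= i) "·" else f(m[i, j])
    num <- function(v) sprintf("%.*f", digits, v)
    row3 <- function(tag, m, f)
      paste(c(if (tag == "Old") labs[i] else "", tag,
              vapply(2:k, function(j) cell(m, j, f), "")), collapse = "\t")
    lines <- c(lines,
               row3("Old", cmp$old, num),
               row3("New", cmp$new, num),
               row3("Result", cmp$result, identity))
  }
  writeLines(lines, path)
  invisible(path)
}
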