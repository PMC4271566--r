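#' Read a graph from an edge-list file
#'
#' One edge per line, `u v [length]`, whitespace- or comma-separated; lines
#' starting with `#` and blank lines are skipped. 0-based vertex ids are
#' accepted (detected by the presence of a 0 endpoint) and normalized to
#' 1-based. An optional third column of edge lengths populates a partial
#' distance table (non-edge distances unknown, `NA`); supply a coordinate
#' file via `coords` for full geometry.
#'
#' @param path edge-list file.
#' @param n vertex count override (needed if trailing vertices are isolated).
#' @param coords optional path to a coordinate table, see [read_coords()].
#' @return a [pgraph()].
#' @export
read_edgelist <- function(path, n = NULL, coords = NULL) {
  if (!file.exists(path)) stop("cannot open edge list: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0 && is.null(n)) stop("no edges found in ", path)
  toks <- strsplit(gsub(",", " ", lines), "[[:space:]]+")
  bad <- which(vapply(toks, length, 1L) < 2L)
  if (length(bad) > 0) stop("malformed edge line ", bad[1], " in ", path)
  u <- as.numeric(vapply(toks, `[[`, "", 1L))
  v <- as.numeric(vapply(toks, `[[`, "", 2L))
  if (any(is.na(u)) || any(is.na(v))) stop("non-numeric vertex id in ", path)
  if (any(u == 0) || any(v == 0)) { u <- u + 1; v <- v + 1 }  # 0-based input
  len <- rep(NA_real_, length(u))
  has3 <- vapply(toks, length, 1L) >= 3L
  len[has3] <- as.numeric(vapply(toks[has3], `[[`, "", 3L))

  xyz <- if (!is.null(coords)) read_coords(coords) else NULL
  nn <- if (!is.null(n)) n else max(c(u, v, if (!is.null(xyz)) nrow(xyz)))
  g <- pgraph(cbind(u, v), n = nn, coords = xyz)
  if (is.null(xyz) && any(!is.na(len))) {
    geom <- matrix(NA_real_, nn, nn)
    diag(geom) <- 0
    idx <- cbind(pmin(u, v), pmax(u, v))
    geom[idx] <- len
    geom[idx[, 2:1, drop = FALSE]] <- len
    check_geometry(geom)
    g$geom <- geom
  }
  g
}

#' Write a graph as a canonical edge list
#'
#' Endpoints sorted within each edge and edges sorted lexicographically;
#' when the graph has geometry, a third column carries the edge length.
#'
#' @param g a [pgraph()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_edgelist <- function(g, path) {
  stopifnot(inherits(g, "pgraph"))
  lines <- c(sprintf("# pgraph: n=%d m=%d", g$n, nrow(g$edges)))
  if (nrow(g$edges) > 0) {
    if (!is.null(g$geom)) {
      lines <- c(lines, sprintf("%d %d %.9g", g$edges[, 1], g$edges[, 2],
                                g$geom[g$edges]))
    } else {
      lines <- c(lines, sprintf("%d %d", g$edges[, 1], g$edges[, 2]))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

#' Read a graph from a square adjacency-matrix CSV
#'
#' A header-less CSV of 0/1 entries; must be symmetric with a zero diagonal.
#'
#' @param path CSV file.
#' @return a [pgraph()].
#' @export
read_adjacency <- function(path) {
  A <- as.matrix(utils::read.csv(path, header = FALSE))
  dimnames(A) <- NULL
  if (nrow(A) != ncol(A)) stop("adjacency matrix must be square")
  if (any(A != t(A))) stop("adjacency matrix must be symmetric")
  if (any(diag(A) != 0)) stop("adjacency matrix must have a zero diagonal")
  if (!all(A %in% c(0, 1))) stop("adjacency entries must be 0 or 1")
  idx <- which(upper.tri(A) & A == 1, arr.ind = TRUE)
  pgraph(idx, n = nrow(A))
}

#' Read a per-vertex coordinate table
#'
#' Whitespace/TSV/CSV table `id x y [z]`, optionally with a header line;
#' comment lines start with `#`. Rows are ordered by id (0-based ids
#' accepted and normalized).
#'
#' @param path coordinate file.
#' @return numeric matrix with one row per vertex and 2-3 columns.
#' @export
read_coords <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  toks <- strsplit(gsub("[,\t]", " ", lines), "[[:space:]]+")
  if (suppressWarnings(is.na(as.numeric(toks[[1]][1])))) toks <- toks[-1]
  tab <- do.call(rbind, lapply(toks, function(t) as.numeric(t[1:min(4, length(t))])))
  if (any(is.na(tab))) stop("malformed coordinate table in ", path)
  ids <- tab[, 1]
  if (any(ids == 0)) ids <- ids + 1
  if (!setequal(ids, seq_len(nrow(tab)))) stop("coordinate ids must cover 1..n")
  tab[order(ids), -1, drop = FALSE]
}

#' Write a per-vertex coordinate table
#'
#' @param g a [pgraph()] with coordinates.
#' @param path output file (TSV: `id x y z`).
#' @return `path`, invisibly.
#' @export
write_coords <- function(g, path) {
  stopifnot(inherits(g, "pgraph"))
  if (is.null(g$coords)) stop("graph has no coordinates")
  xyz <- g$coords
  if (ncol(xyz) == 2) xyz <- cbind(xyz, 0)
  tab <- cbind(id = seq_len(g$n), xyz)
  colnames(tab) <- c("id", "x", "y", "z")
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a per-residue secondary-structure TSV
#'
#' Plain-text fixture format for P-graph construction: a tab-separated table
#' with header columns `chain`, `resnum`, `code`, `x`, `y`, `z` (one row per
#' residue, coordinates in Angstroms).
#'
#' @param path TSV file.
#' @return data frame with those six columns.
#' @export
read_sse_tsv <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE, comment.char = "#")
  need <- c("chain", "resnum", "code", "x", "y", "z")
  if (!all(need %in% names(tab)))
    stop("SSE table must have columns: ", paste(need, collapse = ", "))
  tab[need]
}

#' Read per-residue records from a DSSP output file
#'
#' Parses the classic fixed-column DSSP text format: data lines follow the
#' `#  RESIDUE AA STRUCTURE ...` header; the secondary-structure summary
#' letter sits in column 17 and the C-alpha coordinates in columns 116-136
#' (three 7.1f fields). Chain-break records (`!` in the AA column) are
#' skipped.
#'
#' @param path `.dssp` file.
#' @return data frame with columns `chain`, `resnum`, `code`, `x`, `y`, `z`.
#' @export
read_dssp <- function(path) {
  lines <- readLines(path, warn = FALSE)
  hdr <- grep("^\\s*#\\s+RESIDUE", lines)
  if (length(hdr) == 0) stop("not a DSSP file: residue header not found in ", path)
  body <- lines[(hdr[1] + 1):length(lines)]
  body <- body[nchar(body) >= 136]
  aa <- substr(body, 14, 14)
  body <- body[aa != "!"]
  if (length(body) == 0) stop("no residue records in ", path)
  data.frame(
    chain = trimws(substr(body, 12, 12)),
    resnum = as.integer(substr(body, 6, 10)),
    code = substr(body, 17, 17),
    x = as.numeric(substr(body, 116, 122)),
    y = as.numeric(substr(body, 123, 129)),
    z = as.numeric(substr(body, 130, 136)),
    stringsAsFactors = FALSE
  )
}

#' Extract C-alpha coordinates from a PDB structure file
#'
#' Thin wrapper over `bio3d::read.pdb()` for pairing a structure file with
#' externally supplied per-residue codes.
#'
#' @param path PDB file.
#' @return data frame with columns `chain`, `resnum`, `x`, `y`, `z`, one row
#'   per C-alpha atom in file order.
#' @export
read_pdb_ca <- function(path) {
  if (!requireNamespace("bio3d", quietly = TRUE))
    stop("reading PDB files requires the 'bio3d' package")
  pdb <- bio3d::read.pdb(path)
  ca <- pdb$atom[pdb$atom$elety == "CA", , drop = FALSE]
  data.frame(chain = ca$chain, resnum = ca$resno,
             x = ca$x, y = ca$y, z = ca$z, stringsAsFactors = FALSE)
}

#' Build a P-graph straight from an SSE table or DSSP file
#'
#' Dispatches on file extension: `.dssp` goes through [read_dssp()],
#' anything else through [read_sse_tsv()]; the records then feed
#' [build_pgraph()].
#'
#' @param path input file.
#' @inheritParams build_pgraph
#' @return a [pgraph()].
#' @export
build_pgraph_from_file <- function(path, threshold_multiplier = 1) {
  tab <- if (grepl("\\.dssp$", path, ignore.case = TRUE)) read_dssp(path)
         else read_sse_tsv(path)
  build_pgraph(tab$code, as.matrix(tab[, c("x", "y", "z")]),
               chain = tab$chain, threshold_multiplier = threshold_multiplier)
}
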