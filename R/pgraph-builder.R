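#' Reduce DSSP secondary-structure codes to three classes
#'
#' Maps the eight-letter DSSP alphabet onto the three vertex classes of a
#' P-graph: helix codes `G`, `H`, `I` become `H`; hydrogen-turn/strand codes
#' `T`, `E`, `B` become `T`; coil `C` stays `C`. DSSP's blank (no assigned
#' structure) and `S` (bend) are normalized to coil, the catch-all class of
#' standard 3-state reductions. Any other code is an error.
#'
#' @param code character vector of single-letter DSSP codes.
#' @return character vector over `{"H", "T", "C"}`.
#' @examples
#' classify_sse(c("G", "H", "E", "C", " "))
#' @export
classify_sse <- function(code) {
  code <- toupper(as.character(code))
  code[code %in% c(" ", "", "S", "-")] <- "C"
  map <- c(G = "H", H = "H", I = "H", T = "T", E = "T", B = "T", C = "C")
  bad <- setdiff(unique(code), names(map))
  if (length(bad) > 0)
    stop("unknown secondary-structure code(s): ",
         paste(shQuote(bad), collapse = ", "))
  unname(map[code])
}

#' Segment a per-residue class sequence into runs
#'
#' Maximal runs of identical class become the secondary-structure elements
#' (segments) that will be the vertices of the P-graph. When `chain` is
#' supplied, runs never cross chain boundaries.
#'
#' @param classes character vector of per-residue classes (`H`/`T`/`C`).
#' @param chain optional parallel vector of chain identifiers.
#' @return data frame with columns `start`, `end` (1-based positions into
#'   `classes`, inclusive), `class`, and `chain` (`NA` when not supplied).
#' @examples
#' sse_segments(strsplit("HHHTTC", "")[[1]])
#' @export
sse_segments <- function(classes, chain = NULL) {
  stopifnot(length(classes) > 0)
  key <- if (is.null(chain)) classes else paste(chain, classes, sep = "\r")
  r <- rle(key)
  end <- cumsum(r$lengths)
  start <- end - r$lengths + 1L
  data.frame(start = start, end = end,
             class = classes[start],
             chain = if (is.null(chain)) NA_character_ else chain[start],
             stringsAsFactors = FALSE)
}

#' Representative coordinate of a segment
#'
#' The arithmetic centroid of the segment's C-alpha coordinates; for a
#' single-residue segment, that residue's coordinate.
#'
#' @param segment length-2 vector `(start, end)` of residue positions.
#' @param coords numeric matrix of per-residue coordinates (rows aligned to
#'   positions, 3 columns).
#' @return length-3 numeric coordinate.
#' @export
segment_representative <- function(segment, coords) {
  idx <- segment[1]:segment[2]
  if (max(idx) > nrow(coords))
    stop("missing coordinate for residue ", max(idx))
  block <- coords[idx, , drop = FALSE]
  if (any(is.na(block))) {
    bad <- idx[apply(is.na(block), 1, any)][1]
    stop("missing coordinate for residue ", bad)
  }
  colMeans(block)
}

#' Mean pairwise distance (the AVG contact threshold)
#'
#' The arithmetic mean of the Euclidean distances over all unordered pairs
#' of representative points. This is the AVG value: pairs at distance no
#' greater than it are joined by an edge when the P-graph is built. The mean
#' runs over all vertex pairs, not only eventual edges — the threshold must
#' exist before any edge does.
#'
#' @param points numeric matrix of representative coordinates (>= 2 rows).
#' @return mean pairwise distance, in the units of `points` (Angstroms for
#'   proteins).
#' @export
avg_threshold <- function(points) {
  points <- as.matrix(points)
  if (nrow(points) < 2) stop("need at least two points for a mean distance")
  mean(stats::dist(points))
}

#' Build a P-graph from per-residue secondary structure and coordinates
#'
#' The construction pipeline: classify each residue into H/T/C
#' ([classify_sse()]), merge maximal runs into segments ([sse_segments()]),
#' take each segment's C-alpha centroid as its representative
#' ([segment_representative()]), compute the AVG threshold over all segment
#' pairs ([avg_threshold()]), and join every pair at distance `<=` AVG
#' (inclusive). A disconnected result is legal and returned as-is — sparse
#' thresholds can fragment a protein graph, which downstream entropy code
#' reports through the `NaC` sentinel.
#'
#' @param codes per-residue DSSP codes (or already-reduced H/T/C classes).
#' @param coords per-residue C-alpha coordinate matrix (3 columns, one row
#'   per residue, Angstroms).
#' @param chain optional per-residue chain ids; segments never span chains.
#'   Multimeric inputs build one joint graph over all supplied chains by
#'   default; pass a subset of rows to build per-chain graphs.
#' @param threshold_multiplier scale factor on the AVG threshold (1 = the
#'   plain mean distance).
#' @return a [pgraph()] whose vertices are the segments (in sequence order),
#'   with geometry, `segments`, and `threshold` fields set.
#' @examples
#' codes <- strsplit("HHHHCCEEEECCHHH", "")[[1]]
#' coords <- cbind(seq_along(codes) * 1.5, 0, 0)
#' build_pgraph(codes, coords)
#' @export
build_pgraph <- function(codes, coords, chain = NULL, threshold_multiplier = 1) {
  classes <- classify_sse(codes)
  coords <- as.matrix(coords)
  storage.mode(coords) <- "double"
  if (nrow(coords) != length(classes))
    stop("`coords` must have one row per residue")
  segs <- sse_segments(classes, chain)
  reps <- t(vapply(seq_len(nrow(segs)),
                   function(i) segment_representative(c(segs$start[i], segs$end[i]), coords),
                   numeric(ncol(coords))))
  if (nrow(segs) < 2) stop("need at least two segments to build a graph")
  thr <- threshold_multiplier * avg_threshold(reps)
  D <- as.matrix(stats::dist(reps))
  pairs <- t(utils::combn(nrow(segs), 2))
  # inclusive boundary, with an epsilon so pairs sitting exactly at the
  # threshold (e.g. all-equidistant representatives) are not lost to
  # floating-point noise in the mean
  edges <- pairs[D[pairs] <= thr + 1e-9 * (1 + thr), , drop = FALSE]
  g <- pgraph(edges, n = nrow(segs), coords = reps)
  g$segments <- segs
  g$threshold <- thr
  g
}
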