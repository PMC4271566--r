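test_that("DSSP codes reduce to the three-class alphabet", {
  expect_equal(classify_sse(c("G", "H", "I")), c("H", "H", "H"))
  expect_equal(classify_sse(c("T", "E", "B")), c("T", "T", "T"))
  expect_equal(classify_sse("C"), "C")
  # blank and bend normalize to coil, the catch-all class
  expect_equal(classify_sse(c(" ", "", "S", "-")), rep("C", 4))
  expect_error(classify_sse("Q"), "unknown secondary-structure code")
})

test_that("segmentation takes maximal runs and respects chain boundaries", {
  segs <- sse_segments(strsplit("HHHTTC", "")[[1]])
  expect_equal(segs$start, c(1L, 4L, 6L))
  expect_equal(segs$end, c(3L, 5L, 6L))
  expect_equal(segs$class, c("H", "T", "C"))

  expect_equal(nrow(sse_segments("H")), 1L)
  expect_equal(nrow(sse_segments(strsplit("HTHTH", "")[[1]])), 5L)

  # same class across a chain break still starts a new segment
  segs <- sse_segments(rep("H", 4), chain = c("A", "A", "B", "B"))
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$chain, c("A", "B"))
})

test_that("segment representatives are C-alpha centroids", {
  coords <- rbind(c(0, 0, 0), c(2, 0, 0), c(4, 0, 0))
  expect_equal(segment_representative(c(1, 1), coords), c(0, 0, 0))
  expect_equal(segment_representative(c(1, 2), coords), c(1, 0, 0))
  expect_equal(segment_representative(c(1, 3), coords), c(2, 0, 0))

  coords[2, 1] <- NA
  expect_error(segment_representative(c(1, 3), coords), "residue 2")
  expect_error(segment_representative(c(1, 5), coords), "residue 5")
})

test_that("AVG threshold is the mean over all unordered pairs", {
  expect_equal(avg_threshold(rbind(c(0, 0, 0), c(4, 0, 0))), 4)
  sq <- rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))
  expect_equal(avg_threshold(sq), (4 * 1 + 2 * sqrt(2)) / 6)
  expect_equal(avg_threshold(cbind(c(0, 1, 2), 0)), 4 / 3)
  expect_error(avg_threshold(rbind(c(0, 0))), "two points")
})

test_that("build joins segment pairs at distance <= AVG (inclusive)", {
  # four single-residue segments on the unit square: sides 1 <= AVG ~ 1.138,
  # diagonals sqrt(2) > AVG, so the result is exactly C4
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  g <- build_pgraph(c("H", "T", "H", "T"), sq)
  expect_equal(g$edges, named_fixture("C4")$edges)
  expect_equal(g$threshold, (4 + 2 * sqrt(2)) / 6)

  # two segments: the lone distance equals its own mean -> one edge
  g2 <- build_pgraph(c("H", "E"), rbind(c(0, 0, 0), c(5, 0, 0)))
  expect_equal(n_edges(g2), 1L)

  # equilateral triangle: every distance equals the mean, boundary is inclusive
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0))
  g3 <- build_pgraph(c("H", "T", "C"), tri)
  expect_equal(n_edges(g3), 3L)
})

test_that("built graphs carry consistent geometry and segment metadata", {
  codes <- strsplit("HHHHCCEEEECCHHH", "")[[1]]
  coords <- cbind(seq_along(codes) * 1.9, sin(seq_along(codes)), 0)
  g <- build_pgraph(codes, coords)
  expect_equal(nrow(g$segments), 5L)
  expect_equal(g$geom, as.matrix(stats::dist(g$coords)), ignore_attr = TRUE)
  expect_equal(g$geom, t(g$geom))
})

test_that("density of built graphs falls as the threshold multiplier falls", {
  set.seed(404)
  codes <- sample(c("H", "E", "C"), 40, replace = TRUE)
  coords <- matrix(stats::runif(120, 0, 30), ncol = 3)
  dens <- vapply(c(0.5, 0.8, 1, 1.3, 2),
                 function(m) graph_density(build_pgraph(codes, coords,
                                                        threshold_multiplier = m)),
                 numeric(1))
  expect_true(all(diff(dens) >= 0))
  expect_gt(dens[5], dens[1])
})

test_that("P-graphs round-trip through the edge-list + coordinates format", {
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  g <- build_pgraph(c("H", "T", "H", "T"), sq)
  ef <- tempfile(fileext = ".edges")
  cf <- tempfile(fileext = ".tsv")
  write_edgelist(g, ef)
  write_coords(g, cf)
  g2 <- read_edgelist(ef, coords = cf)
  expect_equal(g2$edges, g$edges)
  expect_equal(g2$geom, g$geom, tolerance = 1e-9)
})

test_that("the fixed-column DSSP reader and file builder reproduce in-memory builds", {
  codes <- strsplit("HHHHSSEEEE", "")[[1]]
  coords <- cbind(seq_along(codes) * 2.5, 0, 0)
  f <- tempfile(fileext = ".dssp")
  write_synthetic_dssp(f, codes, coords)
  tab <- read_dssp(f)
  expect_equal(tab$code, codes)
  expect_equal(tab$x, coords[, 1], tolerance = 0.051)  # file stores 1 decimal
  expect_equal(tab$chain, rep("A", length(codes)))

  g_file <- build_pgraph_from_file(f)
  g_mem <- build_pgraph(codes, cbind(tab$x, tab$y, tab$z))
  expect_equal(g_file$edges, g_mem$edges)

  # TSV path gives the same graph as the in-memory build, at full precision
  tf <- tempfile(fileext = ".tsv")
  utils::write.table(
    data.frame(chain = "A", resnum = seq_along(codes), code = codes,
               x = coords[, 1], y = coords[, 2], z = coords[, 3]),
    tf, sep = "\t", quote = FALSE, row.names = FALSE)
  g_tsv <- build_pgraph_from_file(tf)
  expect_equal(g_tsv$edges, build_pgraph(codes, coords)$edges)
})
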