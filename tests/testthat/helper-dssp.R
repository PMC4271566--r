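# Writes a SYNTHETIC miniature DSSP-format file (fixed-column dialect:
# chain in column 12, summary letter in column 17, CA coordinates as three
# 7.1f fields in columns 116-136). Residues lie on a line so segment
# centroids are easy to check by hand.
write_synthetic_dssp <- function(path, codes, coords, chain = "A") {
  stopifnot(length(codes) == nrow(coords))
  header <- c(
    "==== Secondary Structure Definition, synthetic test fixture ====",
    "  #  RESIDUE AA STRUCTURE BP1 BP2  ACC     N-H-->O    O-->H-N    N-H-->O    O-->H-N    TCO  KAPPA ALPHA  PHI   PSI    X-CA   Y-CA   Z-CA"
  )
  body <- vapply(seq_along(codes), function(i) {
    lead <- sprintf("%5d%5d %s A  %s", i, i, chain, codes[i])
    pad <- strrep(" ", 115 - nchar(lead))
    sprintf("%s%s%7.1f%7.1f%7.1f", lead, pad,
            coords[i, 1], coords[i, 2], coords[i, 3])
  }, "")
  writeLines(c(header, body), path)
  path
}
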