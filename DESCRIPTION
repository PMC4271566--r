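Package: pgentropy
Title: Graph Entropy, Edge Adjustment and Spectral Comparison for Protein Graphs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for measuring and remodeling protein graphs (P-graphs) with
    graph entropy. Implements the classic degree-sequence graph entropy, an
    extended entropy built from k-distance neighborhood (k-sphere) impact
    scores, an entropy-driven edge-adjustment rule that decides whether a
    geometric graph should gain, lose, or keep edges, a cumulative +/-ke
    density sweep, and zero-padded Laplacian spectral distances for comparing
    graphs of different sizes. Includes builders that turn per-residue
    secondary-structure assignments (DSSP-style H/T/C classes) and C-alpha
    coordinates into distance-threshold contact graphs, in-memory reference
    fixtures, seeded synthetic generators, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    stats,
    utils
Suggests:
    bio3d,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
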