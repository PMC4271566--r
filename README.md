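# pgentropy

Graph entropy, entropy-driven edge adjustment, and Laplacian spectral
comparison for protein graphs.

## The problem

Comparing protein structures by full 3-D superposition is hard; a common
alternative is to remodel each protein as a **P-graph** — vertices are
secondary-structure elements (DSSP segments reduced to three classes:
H helix, T turn/strand, C coil), and edges join elements whose
representative coordinates lie within a distance threshold. Before such a
graph is used for structural comparison, one wants a criterion for whether
its edge set is a *stable* representation: too few edges and the graph
fragments, too many and it degenerates toward a clique. `pgentropy`
implements an entropy-based criterion for that decision, plus the spectral
machinery to compare the resulting graphs. It is aimed at structural
bioinformaticians experimenting with graph remodeling of protein folds, and
at anyone who needs k-sphere graph entropy on small geometric graphs.

## The measures

**Classic graph entropy** places the degree distribution on the vertices:

    p_i = deg(v_i) / sum_j deg(v_j),     I(G) = -sum_i p_i log2 p_i   (bits)

**Extended (k-sphere) entropy** replaces degree with an impact score built
from the k-distance neighborhoods `N_k(u) = {v : d(u,v) = k}` (`d` = hop
distance):

    f(u) = sum_{i=1..ecc(u)} |N_i(u)| / (n - i + 1)
    q_i  = f(v_i) / f(V),                I'(G) = -sum_i q_i log2 q_i

Unlike degree entropy, `I'` sees beyond the first sphere, so e.g. the
compact 4-vertex star scores higher than the 4-vertex path
(`I'(P4) = 1.988 < I'(S4) = 1.995`) although both have density 0.5.

**Edge adjustment.** With `x = I'(G)`, `y = I'(G - e)` (longest edge
removed) and `z = I'(G + e)` (shortest non-edge added), the rule
classifies: `z > x > y` → add (case 2), `x > z > y` → keep (case 3),
`y > x > z` → remove (case 4); removal that disconnects the graph is case 1
(`y` is the `NaC` sentinel: entropy is undefined on disconnected graphs).
The cumulative `±ke` sweep (`entropy_sweep()`) tracks `I'` and density
while the k longest edges are removed / k shortest non-edges are added.

**Spectral comparison.** Graphs are compared by the Euclidean distance
between their descending Laplacian spectra (`L = D - A`), the shorter
spectrum zero-padded at the tail so graphs of different sizes remain
comparable.

## Worked example

```r
library(pgentropy)

y <- named_fixture("Y")      # 5-vertex contact graph of crambin's segments
graph_entropy(y)
#> Graph entropy (5 vertices, density 0.500)
#>   extended I'(G): 2.316 bits
#>   classic  I(G):  2.171 bits
#>  vertex      f      q
#>       1 0.8500 0.1821
#>       2 0.9000 0.1929
#>       3 0.8500 0.1821
#>       4 1.0333 0.2214
#>       5 1.0333 0.2214
```

Vertices 4 and 5 (the pendant segments) carry the largest impact scores;
`I' = 2.316` bits sits below the `log2 5 = 2.322` maximum, i.e. the graph
is nearly as stable as a 5-vertex graph can be.

```r
x <- named_fixture("X")      # K4 minus one edge, on the unit square
graph_spectrum(x)
#> Laplacian spectrum (n = 4): [4.000, 4.000, 2.000, 0.000]
graph_spectrum(y)
#> Laplacian spectrum (n = 5): [4.303, 3.618, 1.382, 0.697, 0.000]
spectral_distance(x, y)      # pads X's spectrum with a trailing zero
#> [1] 1.051503
```

Building a P-graph from per-residue secondary structure (a bundled
synthetic mini-protein; real DSSP files work the same way):

```r
f <- system.file("extdata", "synthetic_miniprotein_sse.tsv", package = "pgentropy")
g <- build_pgraph_from_file(f, threshold_multiplier = 0.3)
g
#> P-graph: 21 vertices, 28 edges, density 0.133
#>   geometry: pairwise distance table present
#>   contact threshold (AVG): 24.715
#>   built from 21 secondary-structure segments (HCTCHTCHCTHCTCHCTCHTC)

adjust_decision(g)
#> Edge-adjustment decision
#>   x = I'(G)     = 4.384
#>   y = I'(G - e) = 4.381  (e = 8-10)
#>   z = I'(G + e) = 4.384  (e = 7-9)
#>   case3 -> action: none

entropy_sweep(g, 3)
#>      -3e   -2e   -1e   AVG   +1e   +2e   +3e
#> I'   4.377 4.377 4.381 4.384 4.384 4.384 4.385
#> Dens 0.119 0.124 0.129 0.133 0.138 0.143 0.148
```

The rule judges this graph stable at its AVG threshold (case 3: the
current entropy `x` beats both the add and the remove candidate), and the
sweep confirms the plateau: density climbs steadily but `I'` barely moves.

A command-line interface wraps the same functions:

```sh
exec/pgentropy entropy Y.edges
exec/pgentropy sweep Y.edges --coords Y.coords.tsv --k 2
exec/pgentropy compare X.edges Y.edges
exec/pgentropy build protein.dssp --out graph.edges --coords-out coords.tsv
```

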