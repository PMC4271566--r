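---
title: "Graph entropy for protein-graph remodeling: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Graph entropy for protein-graph remodeling}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pgentropy)
```

## The model

A protein is reduced to a **P-graph**: each maximal run of residues with
the same 3-state secondary-structure class (H = helix from DSSP codes
G/H/I, T = turn/strand from T/E/B, C = coil) becomes one vertex, placed at
the centroid of the run's C-alpha coordinates; two vertices are joined
when their centroid distance is no greater than **AVG**, the mean pairwise
centroid distance (Angstroms). The package then asks: is this edge set a
*stable* representation of the fold?

Stability is measured by entropy. The classic measure puts the degree
distribution on the vertices; the package's extended measure instead uses
k-distance neighborhoods. Writing $d(u,v)$ for hop distance and
$N_i(u) = \{v : d(u,v)=i\}$ for the $i$-sphere of $u$,

$$f(u) = \sum_{i=1}^{\mathrm{ecc}(u)} \frac{|N_i(u)|}{n-i+1}, \qquad
  q_i = \frac{f(v_i)}{\sum_v f(v)}, \qquad
  I'(G) = -\sum_i q_i \log_2 q_i .$$

Every vertex contributes to every other vertex's score, so $I'$ is
sensitive to global compactness where degree entropy sees only the first
sphere: among the 4-vertex fixtures, $I'(P_4) < I'(S_4)$ although both
have density $0.5$, reflecting that the star is the more compact object.
$I'$ is maximized at $\log_2 n$ exactly when $q$ is uniform
(vertex-transitive graphs such as $C_n$, $K_n$ attain it), and is
undefined on disconnected graphs — hop distances, and with them $f$,
diverge. The package treats that case as a typed condition carrying the
`NaC` ("not a connected graph") label rather than a numeric sentinel,
because 0 is a legitimate entropy value for degenerate inputs and tables
need to print `NaC` distinctly.

One subtlety deserves note: the per-vertex weight $1/(n-i+1)$ equals
$1/n$ at $i=1$ and *grows* with $i$, so a vertex in a distant sphere
contributes more than one in the first sphere. The "closer means more
impact" intuition is realized through the sphere sizes themselves — in
compact graphs nearly everything sits in the large early spheres — not
through the weights. The package implements the formula exactly as
stated and documents the weighting rather than silently redefining it.

## The edge-adjustment rule

With $x = I'(G)$, $y = I'(G-e)$ for the geometrically longest edge $e$,
and $z = I'(G+e)$ for the shortest non-edge:

| ordering | case | action |
|---|---|---|
| removal disconnects | case 1 | stop (`y` is `NaC`) |
| $z > x > y$ | case 2 | add the non-edge |
| $x > z > y$ | case 3 | keep the graph |
| $y > x > z$ | case 4 | remove the edge |
| anything else | uncovered | none |

The four cases do not exhaust the six orderings of three reals, and exact
ties are possible (e.g. the square-with-one-diagonal fixture has
$y = z = 2 > x$). Rather than guessing intent, the package classifies
such triples as `uncovered` with no action. A complete graph has no
non-edge; `z` is then unavailable (`NaN` in reports) and the graph is
reported stable — $x = \log_2 n$ is already maximal, so no removal can
beat it.

`adjust_graph()` iterates the rule, applying recommended moves until
case 1/3/uncovered or `max_steps` (default 10). Because case 2 and case 4
both require the applied move to strictly raise $I'$, any run consisting
of such moves is monotone in $I'$; the iteration policy itself (when to
stop, how many steps) is this package's own plumbing.

**The ±ke sweep** reports $I'$ and density while the $k$ longest edges
are removed ($-ke$) or the $k$ shortest non-edges added ($+ke$),
$k = 1..k_{\max}$ (default 3, matching the width of typical report
tables). Candidates are ranked *once* from the offset-0 graph and applied
cumulatively; the alternative (re-ranking after each step) would make
columns path-dependent, and the phrase "the $k$ longest edges" reads most
naturally against the original graph. Density at offset $+k$ is therefore
exactly $\mathrm{dens}(G) + 2k/(n(n-1))$ while candidates remain.
Removals can disconnect the graph — entropy cells turn `NaC` (density is
still well defined and kept numeric in the data frame; the table writer
prints a dash to make the sentinel prominent). Disconnection is monotone
under cumulative removal, so the `NaC` region is a contiguous left block.

## Spectral comparison

Graphs are compared by their Laplacian spectra ($L = D - A$; eigenvalues
sorted descending). When sizes differ, the shorter spectrum is padded
with *trailing* zeros — padding at the ascending end would displace the
structurally meaningful zero eigenvalue — and the Euclidean norm of the
difference is reported. This padded distance is a true metric on padded
vectors (non-negativity, symmetry, triangle inequality; verified
property-style in the tests), but it is a *pseudo*-metric on graphs:
cospectral non-isomorphic graphs exist and receive distance 0. That is a
known, accepted limitation of spectral comparison — it is used precisely
because isomorphism testing is hard.

The old-vs-new report writer marks a remodeling "+" when the adjusted
graphs' pairwise distance is smaller than the unadjusted ones', "−" when
larger, and "=" within a relative tolerance of 0.5% — chosen so that
distances that agree to roughly three significant figures count as "not
bad" rather than as wins or losses.

## Tunable parameters

| parameter | where | default | meaning |
|---|---|---|---|
| `threshold_multiplier` | `build_pgraph()` | 1 | scales the AVG contact threshold (Å); 1 is the plain mean pairwise centroid distance |
| `k_max` | `entropy_sweep()` | 3 | sweep half-width (columns $-k_{\max}..+k_{\max}$) |
| `max_steps` | `adjust_graph()` | 10 | cap on adjustment iterations |
| `tol` | `verdict()` | 0.005 | relative tolerance for the "=" verdict |
| `multiplier`, `seed` | `random_geometric_graph()` | 1, 1 | radius multiplier on the mean pairwise distance; RNG seed |

Segmentation choices: DSSP blank and `S` (bend) map to coil — coil is the
catch-all class of standard 3-state reductions; any other letter is an
error rather than a silent guess. Multi-chain inputs build one joint
graph over all supplied chains (segments never span a chain break); to
work per chain, filter the residue table first. The representative point
is the plain centroid of the segment's C-alpha coordinates — the simplest
convention consistent with "distance between secondary-structure
elements"; no length- or class-weighted variant is attempted.

## Numerical choices

* Entropies are reported in bits (base-2 logarithms throughout).
* The AVG edge rule is inclusive (distance $\le$ threshold) and applied
  with a guard of $10^{-9}(1+\mathrm{AVG})$ so that pairs sitting exactly
  on the threshold — e.g. all-equidistant representatives, which must
  yield a complete graph — are not lost to floating-point noise in the
  mean.
* Laplacian eigenvalues come from the symmetric eigensolver; zero/PSD
  checks use tolerance $10^{-8}$. Table cells print at 3 decimals.
* Candidate edges with equal geometric length are ordered by
  (length, smaller endpoint, larger endpoint) — deterministic across
  platforms.
* Case classification uses strict floating-point comparisons; exact ties
  fall into `uncovered` rather than being perturbed.
* Degenerate inputs: single-vertex graphs have Laplacian $[0]$ and no
  entropy; edgeless graphs have no degree entropy; graphs without
  geometry refuse the adjustment operations with a clear error.

## What the synthetic generators emulate

`random_geometric_graph(n, multiplier, seed)` scatters points uniformly
in the unit cube and applies the same mean-distance threshold rule as the
P-graph builder. This reproduces the *mechanism* that makes protein
contact graphs what they are — geometric edges from a global distance
threshold — and therefore exercises every code path (bridges, NaC
regions, complete graphs, tie-breaks). It does **not** emulate chain
connectivity (real P-graphs have a backbone path through consecutive
segments), secondary-structure class composition, or realistic segment
spacing (~5–25 Å); and uniform point clouds are more isotropic than
folded proteins, so their $q$-distributions sit closer to uniform and
their $I'$ closer to $\log_2 n$ than real sweep tables, whose entropy
rows move more. Passing property tests on these graphs shows the
*algorithms* are correct under the stated invariants — normalization,
bounds, case trichotomy, density arithmetic — not that any biological
conclusion holds for real structures. The bundled
`synthetic_miniprotein_sse.tsv` is likewise a labelled synthetic object:
a 96-residue, 21-segment curve with helix/strand/coil runs, useful for
demonstrating the build-score-adjust pipeline end to end, not a real
protein.

The exhaustive enumerator `all_connected_graphs(n)` (all connected
labeled graphs, $n \le 6$; 26,704 at $n=6$) is the oracle substrate: the
test suite checks the impact and entropy implementations against a
literal brute-force evaluator (matrix-power shortest paths, term-by-term
summation) on *every* such graph, and property tests run on 1,000 seeded
random connected graphs of 5–8 vertices. These sizes keep the full suite
in the minutes range on one core while still being exhaustive where
exhaustiveness matters.

## Known limitations

* Spectral distance is blind to cospectral mates (see above).
* The extended entropy is only defined on connected graphs; the package
  deliberately refuses rather than imputing a value for fragments.
* The adjustment rule moves one edge at a time and stops at the first
  stable state; it is a local criterion, not a global optimization of
  $I'$ over graphs with fixed $n$.
* The uncovered orderings ($z > y > x$ etc.) have no prescribed action;
  the package reports them and leaves the graph alone.
* Reference tables for real proteins depend on the particular contact
  construction used upstream; with a different vertex/edge construction
  the absolute entropy values will differ even for the same PDB entry,
  and no attempt is made to reproduce any particular published table.
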