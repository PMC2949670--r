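---
title: "Methods: k-connected decomposition for protein complex prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: k-connected decomposition for protein complex prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cfanet)
```

## Model and assumptions

`cfanet` treats a protein–protein interaction (PPI) network as an
unweighted, undirected simple graph and a protein complex as a vertex set
whose induced subgraph remains connected under vertex deletions — a
*k-connected* subgraph. The working assumptions are:

* interactions are binary and symmetric; confidence weights, direction and
  interaction type are ignored;
* complex membership expresses itself topologically as multi-path
  reachability (Menger: k-connectivity equals k vertex-disjoint paths
  between every pair), not necessarily as density;
* false-positive edges are common, so candidates are post-filtered by
  size, diameter and optionally cluster score rather than accepted as-is;
* complexes only form among co-localized proteins, so restricting the
  network to cellular-component localization groups before prediction
  removes biologically impossible edges.

The decomposition itself is exact, not heuristic: degree refinement keeps
precisely the k-core, the separator search uses max-flow vertex
connectivity, and every emitted subgraph is certifiably k-connected (the
test suite re-verifies this against exhaustive subset enumeration on
hundreds of small random graphs).

## Parameters

| parameter | default | meaning and rationale |
|---|---|---|
| `min_cluster_size` | 4 | complexes of ≤ 3 proteins are indistinguishable from spurious triangles in real networks (size-3 cliques outnumber known size-3 complexes by more than 200:1), so candidates below 4 members are dropped. |
| `diameter_limit_k1` | 4 | 1-connected candidates are only loosely constrained by connectivity; a diameter above 4 indicates a chain-like artifact rather than a compact machine. |
| level-k diameter limit | `k` | for `k ≥ 2` the accepted diameter shrinks as the connectivity requirement grows; both limits are inclusive (`diam ≤ 4`, `diam ≤ k`), reading "greater than the limit is removed" as the normative rule. |
| `use_cluster_score_filter` | off | keep level-k clusters only when cluster score `> k + 1`; at `k = 1` this removes exactly the trees (score 2), the least reliable shapes under two-hybrid noise. Off by default because it is a refinement experiment, not part of the core pipeline. |
| `separator_mode` | `"readd"` | see below. |
| `theta` (evaluation) | 0.5 | overlap `|S∩C|²/(|S||C|)` at or above 0.5 declares a match, the conventional threshold for whole-complex-level scoring. |
| `alpha` (redundancy) | 0.5 | two predictions overlapping at ≥ 0.5 are redundant; the larger is kept. The comparison is inclusive so that `alpha = 1` still removes exact duplicates. |
| informativeness threshold | 10 | a cellular-component term is informative when ≥ 10 proteins carry it while every descendant term has < 10; 10 is the customary choice for yeast-scale annotation. Counting uses ancestor-propagated annotations — annotation to a child implies annotation to the parent — the standard GO counting convention. |

## Separator handling: why re-adding is the default

When a graph is not yet k-connected, fragmentation removes a minimum
vertex cut and recurses. Two treatments of the cut vertices are possible.
Discarding them (`"literal"`, the classical pseudocode) is simple and
overlap-free, but it is lossy: a k-connected subgraph that contains a cut
vertex of the wider graph is truncated or destroyed. The smallest witness
is a bowtie (two triangles sharing a vertex): at `k = 2` the shared vertex
is the cut, and discarding it leaves two edges — both triangles are lost.
The effect is not a corner case: in the synthetic benchmark below, noise
edges entangle two planted `K_6` cores, the minimum cuts pass through core
members, and literal-mode recursion erodes both cores to nothing.

Re-adding the separator to each piece (`"readd"`, the default) recurses on
the induced subgraph over *component ∪ separator*. Any k-connected
subgraph `S` of the current graph survives each step: removing a cut of
size `< k` cannot disconnect `S`, so `S` minus the cut lies in one
component, and re-adding the cut restores `S` entirely — by induction every
maximal k-connected subgraph is eventually emitted. The cost is that
outputs may overlap in up to `k − 1` vertices, which is biologically
desirable (real complexes share subunits). The induced-subgraph closure
(including separator–separator edges) is essential to this guarantee; the
re-added variant would be incorrect without it.

A related consequence, exercised in the tests: under `"readd"` the levels
nest (every level-`k+1` cluster lies inside some level-`k` cluster), while
under `"literal"` nesting can fail — a `K_5` sharing one vertex with a
triangle yields a `K_4` at `k = 2` (the shared vertex was discarded as a
cut) but the full `K_5` at `k = 3` (refinement removes the triangle first).

## Determinism and numerical choices

* Among all minimum cuts the lexicographically smallest vertex set (under
  sorted identifier order) is chosen, making the whole decomposition — and
  the written cluster files — byte-deterministic.
* Duplicate vertex sets found at several levels are stored once, labeled
  with the *highest* level, i.e. the subgraph's actual connectivity
  number, the most informative annotation.
* Output ordering is descending size with lexicographic member-set
  tie-break; cluster names are assigned after sorting.
* Degenerate inputs: density and cluster score are errors (not 0) below 2
  vertices, so singleton artifacts cannot be scored silently; the diameter
  of a single vertex is 0 (subgraphs are examined before the size filter);
  an empty graph yields an empty prediction table, not an error; the
  evaluation of empty prediction or reference sets reports zeros, with
  `F(0, 0) = 0` as the harmonic-mean limit.
* Matching is many-to-many: one cluster may match several complexes and
  conversely; no assignment is computed.
* Reference complexes are preprocessed per network — members absent from
  the graph are removed, then complexes with ≤ 3 remaining members are
  dropped. Predicted clusters are not re-filtered at evaluation time
  (their size floor is the predictor's own parameter).
* `kscore` uses the unfiltered decomposition (no diameter or size rules):
  it characterizes how connected the *reference complexes* are inside a
  network, not how the predictor would report them.

## What the synthetic generator does and does not emulate

`generate_planted_graph()` plants vertex-disjoint cores — complete graphs,
circulant (ring-plus-nearest-neighbor) graphs, or rejection-sampled random
graphs certified k-connected — among background vertices, and adds uniform
noise edges to every vertex pair not inside a single core. Each
realization is reproducible from its seed, and generation never perturbs
the caller's RNG stream. The default conditions (five complete cores of
six proteins, 30 background vertices, noise probability 0.02, seed 13) are
the package's fixed end-to-end benchmark: small enough to decompose in
well under a second, noisy enough that cores become entangled with the
background and with each other.

The generator does *not* emulate several properties of real interaction
data: scale-free degree distributions, systematic false negatives
(missing-edge models beyond uniform noise), overlapping ground-truth
complexes (cores are disjoint so scoring is unambiguous), or
annotation noise in the ontology fixtures. Passing the planted-recovery
test therefore demonstrates algorithmic correctness under controlled
noise, not expected performance on experimental networks, where precision
and recall are far below 1.

`generate_toy_ontology()` builds a two-level ontology whose child terms
each annotate a fixed number of proteins, placing the informativeness
boundary by construction: at any threshold up to the per-group count the
children are exactly the informative terms; above it, informativeness
moves to the root.

## Problem sizes in the test suite

The exhaustive connectivity oracle enumerates all vertex subsets of size
`< k`, so oracle-based checks run on graphs of at most 10–14 vertices; the
decomposition-vs-oracle agreement suite uses 200 seeded Erdős–Rényi graphs
(n ≤ 10, edge probabilities 0.2/0.4/0.6, k = 1..4, both separator modes).
End-to-end fixtures use the 60-vertex planted benchmark above. These sizes
were chosen so that every claim the tests make is verified against
enumeration or hand-traced expectations rather than against the
implementation itself.

## Known limitations

* The separator search enumerates all minimum cuts to pick a canonical
  one; on graphs with very many minimum cuts this is the dominant cost.
  The intended scale (localization-segregated subnetworks, thousands of
  vertices after refinement fragments them) keeps this tractable, but the
  package is not tuned for dense million-edge graphs.
* `"readd"` mode can revisit overlapping regions; its worst case is
  exponential in pathological graphs, though refinement and the diameter
  filters keep practical inputs far from it.
* Informative-term selection depends on the annotation corpus and
  ontology release used; counts are not comparable across releases.
* Only `is_a` and `part_of` ontology relations are traversed; evidence
  codes are not filtered.
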