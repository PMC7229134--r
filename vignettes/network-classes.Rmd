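---
title: "Classifying unrooted phylogenetic networks by graph reductions"
author: "phynetclass"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying unrooted phylogenetic networks by graph reductions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phynetclass)
library(igraph)
```

## The problem

An unrooted phylogenetic network on a taxon set $X$ is a connected simple
graph with no degree-2 vertices whose degree-1 vertices (leaves) are
bijectively labeled by $X$.  Networks generalize phylogenetic trees to
non-treelike evolution (hybridization, horizontal gene transfer).  A network
is *tree-based* if it has a spanning tree — a *support tree* — whose leaf set
is exactly $X$: the network is then a tree with extra edges.  Deciding
tree-basedness is NP-complete in general, so the practical question is which
structural properties *guarantee* it, preferably properties that are cheap to
test.

This package implements three reductions of a network to simpler graphs and
the sufficient criteria they induce:

* **Leaf cutting** (`lcut`) deletes the labeled leaves and nothing else.
  New degree-1 or degree-2 vertices are kept.
* **Leaf shrinking** (`leafShrink`) exhaustively applies four *restriction
  operations* — delete a leaf, suppress a degree-2 vertex, delete one copy of
  a parallel edge, delete a loop — never dropping below two vertices.  The
  result is unique up to isomorphism whatever the order, so "the" leaf shrink
  graph is well defined.  A graph whose leaf shrink graph is a single edge is
  *edge-based*.
* **Leaf connecting** (`lcon`) pairs up leaves and joins their attachment
  points, inserting a two-vertex gadget whenever the joining edge would be
  parallel to an existing edge, with a special rule for the odd last leaf.
  Different pairing orders can give non-isomorphic results, so the output is
  a *set* of graphs, deduplicated up to isomorphism.

## Why edge-basedness matters

Edge-based networks coincide (for loopless graphs, hence for all networks)
with the classical *generalized series-parallel* (GSP) graphs, the graphs
reducible to $K_2$ without the loop-deletion move; equivalently, the
connected graphs all of whose blocks are series-parallel.  GSP membership is
decidable in linear time, and every proper edge-based network is tree-based —
so edge-basedness is the rare sufficient criterion that is also cheap.  The
package decides it by two independent routes (whole-graph reduction; blocks +
SP test) and insists they agree; the reduction trace is returned as a
machine-checkable certificate.

The support tree of an edge-based network is built constructively
(`supportTreeEdgeBased`): each cut-edge block contributes itself, and each
series-parallel block with at least three vertices contributes a spanning
tree whose leaves are all degree-2 vertices of the block (a *valid spanning
tree*, which always exists for such blocks).  Gluing these trees at cut
vertices yields a spanning tree whose leaves are exactly $X$; the
construction re-verifies this postcondition on every call.

```{r example}
net <- networkFixture("pendant-triangle")
net
as.logical(isEdgeBased(net))
st <- supportTreeEdgeBased(net)
baseTreeNewick(st)
```

## Hamiltonicity-based criteria

Four further sufficient criteria connect tree-basedness to Hamiltonian graph
theory (all are decided exactly, by backtracking search):

1. `criterionPath` — two leaves have adjacent attachment points joined by a
   path through all inner vertices;
2. `criterionHConnected` — the leaf cut graph is Hamilton connected (every
   vertex pair joined by a Hamiltonian path);
3. `criterionLconNewEdge` — some leaf-connect graph has a Hamiltonian cycle
   through an edge that is new (a pair-join or gadget edge, not one created
   by the last-leaf rule);
4. `criterionLconGadget` — some Hamiltonian leaf-connect graph needed the
   two-vertex gadget, which forces criterion 3.

`criterionToughChordal` covers the composite sufficient condition: the leaf
cut graph is not Hamiltonian, yet some leaf-connect graph is chordal with
toughness at least 10 (such graphs are always Hamiltonian, and the cycle must
then use a new edge).  Toughness is computed by brute force over separating
sets, returning `Inf` for complete graphs, where no separating set exists.

None of these criteria is necessary: `classifyNetwork` falls back on an exact
spanning-tree oracle (`isTreeBased`) that forces all leaf edges into the tree
and backtracks over inner edges.

## Structure theorems verified in the test suite

Rather than asserting isolated examples, the test suite and
`scripts/acceptance.R` verify the package's structural claims over exhaustive
enumerations and seeded random families:

* confluence of leaf shrinking (five random operation orders per graph);
* the GSP / edge-based / no-K4-topological-minor equivalence (the K4 oracle
  is an independent brute-force search, never the production procedure);
* every generated edge-based network yields a verified support tree;
* every proper binary chordal network is edge-based, certified by the
  triangle-collapse reduction (`chordalBinaryReduction`), which verifies the
  degree-2-vertex-in-a-triangle property at each step instead of assuming
  it;
* soundness of criteria 1–4 against the exact oracle over the exhaustive
  enumeration of small proper networks;
* the overlap bound: a network that is both edge-based and has a Hamilton
  connected leaf cut graph has a leaf cut graph with at most three vertices —
  a single vertex, a single edge, or a triangle.

## The synthetic generators

`genGspNetwork` composes single edges by random series, parallel and
generalized-series compositions, passes to the underlying simple graph
(which provably has the same leaf shrink graph), labels degree-1 core
vertices, attaches a leaf to every degree-2 core vertex, and repairs
properness by attaching extra leaves to leafless sides of cut elements —
leaf additions never change the leaf shrink graph, so edge-basedness is a
construction invariant, not an empirical observation.

`genTreePlusEdges` grows a random binary tree by leaf insertion, then adds
chords between fresh subdivision points of distinct tree edges; the
construction tree is returned and is a support tree by construction, making
the output tree-based with a verifiable witness.

`genBinaryChordal` deserves a note.  Working out the reverse of the
triangle-collapse reduction showed that expanding an edge into a triangle is
only legal while both endpoints have degree at most 2, which stalls after a
single step: the only non-trivial blobs a proper *binary* chordal network
can contain are triangles and diamonds ($K_4$ minus an edge).  (Sketch: a
chordal graph has a simplicial vertex; with maximum degree 3 inside a blob
this forces a degree-2 vertex in a triangle, or $K_4$ itself, which cannot
occur inside a binary network because its vertices would need degree 4 to
attach anything.)  The generator therefore samples random blob-trees over
triangle/diamond blobs, degree-3 branch vertices and leaves — which is the
entire family, not a convenience subset.

`enumerateNetworks` enumerates, up to isomorphism with exchangeable leaf
labels, all proper networks whose inner graph has at most `maxInner`
vertices (guarded at 7): inner cores are enumerated up to isomorphism by
minimizing edge-set bitmasks over all vertex permutations, leaves are
attached in every way that avoids degree-1 and degree-2 inner vertices, and
results are deduplicated by a canonical form.  The enumerator is
cross-checked at small sizes against an independent generate-all-then-filter
enumeration and against the known counts of connected graphs (1, 1, 2, 6,
21, 112 for 1–6 vertices).

What the generators do *not* emulate: real reconstructed networks have
branch lengths, non-uniform topology distributions, and far more taxa than
the desk-scale instances here.  Passing tests certify the combinatorial
machinery, not statistical behaviour on biological data.

## Numerical and design choices

* **Multigraph canonical forms.** Isomorphism of multigraphs is decided by
  encoding parallel-edge multiplicities and loop counts as colored auxiliary
  vertices and taking a BLISS canonical permutation of the colored simple
  encoding; simple graphs skip the encoding.  This is exact and adequate for
  the at-most-20-vertex graphs handled here.
* **Operation order.** The deterministic policy applies the
  lexicographically smallest operation under the rank delete-leaf <
  delete-parallel-copy < delete-loop < suppress-degree2.  Deleting parallel
  copies before suppressing means reductions restricted to the first three
  operations never create loops on loopless input, which makes the greedy
  run a complete GSP/SP decision procedure (confluence makes the choice
  irrelevant for full leaf shrinking, where all four operations are
  allowed).
* **Caps.** Every brute-force search (Hamiltonian paths, K4 minors,
  toughness, tree-basedness oracle, leaf-connect order enumeration) takes a
  cap and returns an explicit indeterminate (`NA`, recorded in
  `capsHit`) when it is hit.  Criteria never silently treat indeterminate
  as false.
* **Degenerate sizes.** Hamilton-connectedness of the one- and two-vertex
  graphs is defined `TRUE` so that leaf cut graphs consisting of a single
  vertex or single edge compose with the H-connected class; toughness of a
  complete graph is `Inf`; leaf cutting the two-taxon single edge yields the
  empty graph, flagged rather than rejected, because the degenerate case is
  needed when classifying trees with at most one inner edge.
* **Pair-order semantics of leaf connecting.** The order of *pair choices*
  (not merely the final matching) can change the result, so the full order
  tree is enumerated and deduplicated by a provenance-respecting canonical
  form; whether a two-vertex gadget was used is part of the deduplication
  key because the gadget criterion depends on it.  Pre-processing is always
  applied first.
* **Problem sizes.** The exhaustive suites use at most 6 inner vertices and
  6 leaves for the leaf-cut bound and at most 5/5 for the criteria sweep
  (the leaf-connect order tree grows factorially in the leaf count);
  randomized suites use 300 graphs on up to 10 vertices, 200 generated
  edge-based networks, and 100 binary chordal networks.

## Known limitations

* All exact searches are exponential; the package targets desk-scale
  networks (tens of vertices), not genome-scale instances.  Linear-time SP
  recognition via SPQR trees is out of scope.
* Rooted networks, directed variants and edge weights are out of scope, as
  is perfect-graph recognition (the natural generalization of the chordal
  criterion, left open here).
* `lcon` on many-leaf networks explores all pairing orders; beyond roughly
  eight reduced leaves the cap will be hit and results flagged incomplete.
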