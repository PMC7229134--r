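# phynetclass

Classification of unrooted phylogenetic networks by graph reductions.

Phylogenetic networks generalize phylogenetic trees to non-treelike
evolution (hybridization, horizontal gene transfer).  A network $N^u$ on a
taxon set $X$ is **tree-based** if it has a spanning tree whose leaf set is
exactly $X$ (a *support tree*): the network is then a tree with extra edges.
Deciding tree-basedness is NP-complete, so practitioners want structural
properties that guarantee it and are cheap to test.  This package implements
the reduction machinery that supplies such properties, for people studying
network classes and for pipelines that need a fast certified "tree-based"
verdict:

* the three reductions of a network to simpler graphs — **leaf cutting**
  (`lcut`), **leaf shrinking** (`leafShrink`, confluent rewriting by leaf
  deletion, degree-2 suppression, parallel-copy and loop deletion), and
  **leaf connecting** (`lcon`, with edge-provenance annotations);
* **edge-basedness** ($\mathcal{LS}(N^u) = K_2$) and its equivalence with
  generalized series-parallel (GSP) graphs, decided by two independent
  routes with reduction-trace certificates (`isEdgeBased`, `isGSP`, `isSP`,
  `edgeBasedByBlobs`, `reduceToEdge`);
* a constructive, re-verified **support tree** for edge-based networks from
  valid spanning trees of their series-parallel blocks
  (`supportTreeEdgeBased`, `validSpanningTree`);
* the **Hamiltonicity-based sufficient criteria** for tree-basedness
  (`criterionPath`, `criterionHConnected`, `criterionLconNewEdge`,
  `criterionLconGadget`, `criterionToughChordal`), exact Hamiltonian
  path/cycle/Hamilton-connectedness searches, graph toughness and
  chordality;
* an exact tree-basedness **oracle** (`isTreeBased`), a combined classifier
  (`classifyNetwork`), the chordal-binary reduction certificate
  (`chordalBinaryReduction`);
* **generators with ground truth** (`genGspNetwork`, `genTreePlusEdges`,
  `genBinaryChordal`) and an exhaustive isomorphism-free **enumerator** of
  small proper networks (`enumerateNetworks`), used to verify the package's
  structure theorems;
* GraphML/TSV input-output, Newick export of base trees, JSON reports, and
  a command-line tool (`inst/scripts/phynetclass`).

## Worked example

```r
library(phynetclass)

## triangle w,p,q with a pendant inner vertex s; leaves 1,2 on s, 3 on p, 4 on q
net <- networkFixture("pendant-triangle")
net
#> PhyloNetwork: 8 vertices, 8 edges, 4 taxa (1,2,3,4), binary

classifyNetwork(net)
#> ClassificationReport
#>   proper                   yes
#>   binary                   yes
#>   chordal                  yes
#>   simpleNetwork            no
#>   edgeBased                yes
#>   gsp                      yes
#>   hConnected               no
#>   criterionPath            no
#>   criterionLconNewEdge     yes
#>   criterionLconGadget      yes
#>   criterionToughChordal    yes
#>   treeBased                yes
#>   tree-based method: edge-based
```

The network shrinks to a single edge (delete leaves 1–4, delete the new
unlabeled leaf s, suppress a triangle vertex, delete the parallel copy), so
it is edge-based and hence tree-based — even though its leaf cut graph is
not Hamilton connected (`hConnected: no`).  The support tree and its base
tree come from the block construction:

```r
st <- supportTreeEdgeBased(net)
st
#> SupportTree: 8 vertices, leaves {1,2,3,4}
baseTreeNewick(st)
#> [1] "((1,2),3,4);"
```

The leaf shrink trace is a replayable certificate:

```r
leafShrink(net)
#> ReductionTrace: 7 step(s), 8/8 -> 2/1 vertices/edges
#>                   kind t1   t2
#> 1          delete-leaf  1 <NA>
#> ...
#> 7 delete-parallel-copy  q    w
```

From a shell:

```sh
Rscript inst/scripts/phynetclass classify mynet.graphml
Rscript inst/scripts/phynetclass reduce ls mynet.graphml
Rscript inst/scripts/phynetclass enumerate --max-inner 3 --max-leaves 4
```

Exit codes: 0 success, 1 error, 2 indeterminate (a brute-force cap was hit).

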