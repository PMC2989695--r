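# cladegraph

Graph models of phylogenies: node-based vs stem-based trees, their
equivalence, and what "monophyletic" means on each.

## The problem

Systematists draw the same phylogeny in two mathematically different ways.
In a **node-based tree** *T*, every taxon — sampled tip or inferred ancestor
— is a *vertex*, and an edge *x* → *y* is the hypothesis that taxon *x* is
the immediate ancestor of taxon *y*. In a **stem-based (branch-based) tree**
*U*, every taxon is an *edge* (a lineage persisting between speciation
events) and every vertex is an anonymous speciation event; such a tree is
always *planted* — its root vertex has exactly one child, the edge
representing the common ancestor of everything sampled.

The two models carry identical information. Relabeling converts one into
the other: plant a new root above *T*, label each edge *v* → *w* of the
augmented tree by *w*, and erase the vertex labels (the reverse procedure
recovers *T*). This is a bijection: rooted trees on *n* labeled vertices
and planted trees with *n* labeled edges correspond one-to-one, and both
families have exactly *n*^(*n*−1) members (Cayley's formula).

The correspondence is *not* innocent for substructures, which is where
biological meaning lives. Subtrees of *T* correspond to **planted** subtrees
of *U* only; a non-planted subtree of *U* has no subtree counterpart in *T*.
Consequently a monophyletic group — an ancestor plus all of its descendants,
ancestor included — is a proper subtree *rooted at a vertex* in *T* but a
proper subtree *planted at an edge* in *U*, and applying the node-style
definition to a stem tree (or vice versa) selects a group that is not
monophyletic at all. `cladegraph` implements both models, the conversion,
exhaustive certification of the bijection, and the
monophyletic/paraphyletic/polyphyletic classification that makes those
mistakes visible.

The package is for systematists, tree-thinking educators, and developers of
phylogenetic software who need clade semantics to be stated on — and checked
against — the right graphical model.

## Worked example

The nine-taxon fixture (`fig3_tree()`) has root `1`, with children `2`,`3`;
`2` has children `4`,`5`; `3` has `6`,`7`; `4` has `8`,`9`:

```r
library(cladegraph)

t <- fig3_tree("node")          # taxa as vertices
u <- fig3_tree("stem")          # the same phylogeny, taxa as edges
write_newick(t)
#> [1] "(((8,9)4,5)2,(6,7)3)1;"
write_newick(u)                 # identical string, other interpretation
#> [1] "(((8,9)4,5)2,(6,7)3)1;"

# {4,5,8,9} is a subtree of the stem tree, but not planted...
stem_is_subtree(u, c("4", "5", "8", "9"))
#> # A tibble: 1 × 2
#>   is_subtree planted
#>   <lgl>      <lgl>
#> 1 TRUE       FALSE

# ...so the same labels do NOT form a subtree of the node tree,
is_subtree(t, c("4", "5", "8", "9"))
#> [1] FALSE

# and the group is polyphyletic: it excludes its own common ancestor 2.
classify_clade(t, c("4", "5", "8", "9"))
#> [1] "polyphyletic"
yca(t, c("4", "5", "8", "9"))
#> [1] "2"

# Adding the ancestor makes a clade, identical under either model's naming:
classify_clade(t, c("2", "4", "5", "8", "9"))
#> [1] "monophyletic"
identical(clade(t, "2"), clade(u, "2"))
#> [1] TRUE

# The bijection between the two models, certified exhaustively:
glance(certify_bijection(4))
#> # A tibble: 1 × 9
#>       n expected n_node n_stem injective image_matches roundtrip_node roundtrip_stem pass
#>   <dbl>    <dbl>  <int>  <int> <lgl>     <lgl>         <lgl>          <lgl>          <lgl>
#> 1     4       64     64     64 TRUE      TRUE          TRUE           TRUE           TRUE
```

`64 = 4^3` rooted labeled node trees and exactly as many planted
edge-labeled stem trees, with the conversion a verified bijection and both
round trips identities.

A shell surface wraps the same operations
(`system.file("cli", "cladegraph", package = "cladegraph")`):

```sh
cladegraph classify --in fig3.nwk --model node --taxa 4,5,8,9
# polyphyletic (yca: 2)
cladegraph convert --in fig3.nwk --from node --to stem
cladegraph certify --n 4 --json
```

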