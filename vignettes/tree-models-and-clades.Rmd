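---
title: "Two graph models of phylogenies and the semantics of clades"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Two graph models of phylogenies and the semantics of clades}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cladegraph)
```

## The two models

A rooted tree can represent a phylogeny in two distinct ways, and the
difference is entirely in what the vertices and edges *mean*, not in the
mathematics of the graph.

In the **node-based** model, every taxon — sampled or inferred — is a
vertex, and an edge from parent vertex to child vertex asserts an ancestry
hypothesis. Internal vertices are ancestral taxa: not "hypothetical" in any
weaker sense than the tips, merely unsampled and inferred. Nothing in
nature corresponds to an edge; it is a relation.

In the **stem-based** model, every taxon is an edge — a lineage persisting
between two speciation events — and every vertex is a speciation event. The
vertices carry no identity at all: `cladegraph` calls them *junctions*,
gives them internal identifiers, and never serializes them. A stem-based
tree is always **planted**: the root junction has exactly one child, and
the single edge hanging from it is the common ancestor of everything
sampled.

`node_tree()` and `stem_tree()` construct validated objects; both are
tibbles underneath (one row per taxon: `label`/`parent` for the node model,
`tail`/`head`/`label` edge rows for the stem model), so they compose with
the usual data-frame tooling, and `tidy()`, `glance()` and `autoplot()`
methods expose per-taxon tables, structural summaries and model-faithful
drawings.

Both constructors enforce the defining invariants — unique non-empty
labels, a single root, acyclicity and connectedness, vertex count = edge
count + 1, and plantedness for stem trees. Polytomies are allowed
everywhere; no operation assumes binarity. Child order is semantically
meaningless; a canonical order (see *Serialization*) exists only so that
output and equality testing are deterministic. Empty trees are rejected:
the minimal objects are a single-vertex node tree and a single-edge stem
tree. Branch lengths, divergence times, unrooted trees and reticulate
networks are out of scope — a tree in this strict sense cannot model
reticulation, which is precisely why it supports unambiguous ancestry
queries.

## Conversion, and why it is a theorem rather than a convenience

`node_to_stem()` implements the relabeling that turns a node tree $T$ into
its stem counterpart $U$: create a fresh root junction, add an edge from it
to the old root, label every edge $v \to w$ of the augmented tree with $w$,
erase vertex labels. `stem_to_node()` reverses it. Three properties — all
tested exhaustively and by seeded sweeps — make this a bijection:

* both round trips are identities (`stem_to_node(node_to_stem(T)) = T` and
  conversely),
* the taxon label multiset is conserved,
* the output of `node_to_stem()` is always planted.

`certify_bijection(n)` certifies the correspondence by brute force: it
enumerates *all* rooted labeled node trees on $n$ labels and *all* planted
edge-labeled stem trees on the same labels, by two deliberately unrelated
methods, and checks the conversion is injective with image exactly the stem
enumeration. Both counts equal $n^{n-1}$: 1, 2, 9, 64, 625 for
$n = 1..5$.

A design point worth recording: the node-side enumerator decodes Prüfer
sequences (a bijective encoding of free labeled trees) and roots each tree
at each vertex, while the stem-side enumerator brute-forces acyclic parent
maps over the label set, using the fact that junctions can be canonically
named after the head of their unique parent edge — which makes the
enumeration duplicate-free without a deduplication pass. Neither enumerator
calls the conversion algorithms, so the certification is not circular. The
junction-relabel-then-deduplicate strategy (enumerate planted junction
structures, apply all $n!$ edge labelings, collapse by canonical
serialization) is retained in the test suite as an independent oracle at
$n \le 4$, where the two strategies are asserted to agree. Both enumerators
refuse $n > 7$ with a hard size-guard error rather than truncating
silently.

## The subtree correspondence

Subtrees of $T$ correspond to **planted** subtrees of $U$ with the same
label set — proper subtrees (a vertex plus all its descendants; exactly one
per vertex) to planted proper subtrees (an edge plus all edges below it).
The correspondence fails, by design of the models, for non-planted subtrees
of $U$: on the nine-taxon fixture, edges $\{4,5,8,9\}$ form a subtree of
$U$, but the same labels do not form a subtree of $T$.

`is_subtree()` decides the node side in $O(|S|)$: an induced subgraph of a
tree is automatically a forest, so it is connected exactly when the number
of induced edges is $|S| - 1$. `stem_is_subtree()` similarly counts
touched junctions ($|E| + 1$ for a connected edge set) and checks
plantedness by asking whether the shallowest touched junction has exactly
one member edge below it. The test suite cross-checks `is_subtree()`
exhaustively against an igraph connected-components oracle.
`certify_subtree_correspondence()` sweeps *all* $2^n - 1$ label subsets of
a tree (guarded at $n \le 12$) and verifies the equivalence
subset-is-subtree-of-$T$ $\iff$ edge-set-is-planted-subtree-of-$U$, plus
the proper-subtree count.

`corresponding_subtree()` maps a `subtree_ref` across models. For a
non-planted stem subtree it deliberately returns a diagnostic
`undefined_correspondence` value rather than raising: that case is the
conceptual payload of the whole package, and callers (the clade module and
the CLI) need to report it, not crash on it.

## Monophyly, paraphyly, polyphyly

A monophyletic group is a common ancestor together with all of its
descendants, the ancestor included. On its own model, each naming scheme
picks out exactly these groups: `clade(node_tree, v)` is the proper subtree
rooted at $v$; `clade(stem_tree, e)` is the proper subtree planted at $e$;
after conversion the two name the same sets, anchor by anchor — applied
each to its own model, the two naming schemes are synonymous.

`classify_clade()` decides the status of an arbitrary taxon set $S$ from
its youngest common ancestor $a =$ `yca(tree, S)` (the MRCA; it may itself
belong to $S$):

* **monophyletic** — $S = \{a\} \cup \text{descendants}(a)$;
* **paraphyletic** — $a \in S$ but some descendants of $a$ are missing;
* **polyphyletic** — $a \notin S$.

The literature exemplifies the para/poly split rather than defining it
sharply; the YCA-membership criterion used here is a documented package
choice. It reproduces both canonical verdicts on the fixture —
$\{4,5,8,9\}$ excludes its YCA $2$ and is polyphyletic; $\{1,3,6,7\}$
contains its YCA $1$ but omits $2$ and everything below it and is
paraphyletic — and it honors the convention that the ancestor belongs to
the group. Two consequences are deliberate and documented: a paraphyletic
set is *not* required to induce a connected subgraph, and a singleton
internal taxon classifies as paraphyletic (it is its own YCA but excludes
its descendants) while a singleton tip is monophyletic. Ancestral
(internal, unsampled-but-inferred) taxa are full-fledged members of taxon
sets throughout. Classification is model-independent: the stem method
delegates through `stem_to_node()`, and a property test confirms agreement
on random phylogenies and random subsets.

`diagnose_misapplication()` produces the structured demonstration of what
goes wrong cross-model. Because stem-tree junctions are unlabeled, a
node-based anchor on a stem tree is addressed as "the head junction of edge
$e$"; the report then shows the non-planted subtree it selects and its
(poly- or para-) classification. A stem-based anchor on a node tree is
addressed by the child endpoint of the intended "root edge"; the report
states that an edge without both endpoints is not a graph and exhibits the
well-defined monophyletic fallback obtained by omitting the root edge.

## Serialization

One Newick grammar, two interpretations, chosen by an explicit `mode`
argument — never guessed from content, because the same string legitimately
encodes both models and silent guessing would recreate the very confusion
the package exists to dispel. In node mode every token (tips, internal,
root) must be labeled. In stem mode each token's label names its parent
edge, and the implicit topmost junction is unlabeled; an explicitly
unlabeled outermost token with more than one child is a not-planted error.

The dialect is strict on purpose: branch lengths and support values are
rejected with a position-reporting error (a bare number in label position
is ambiguous between a label and a support value), as are bracket comments;
quoting follows standard Newick rules (single quotes, `''` escape); the
trailing semicolon is required. Writing is canonical — children are ordered
by the smallest label in their subtree under a locale-independent byte
order, so serialization is deterministic, `parse ∘ write` is the identity
bit-exactly, and the node and stem serializations of corresponding trees
are character-identical. Annotation tables (taxon, comma-separated
character identifiers, tab-separated) are parsed leniently as multisets
with duplicate rows merged, and validated against a tree only at attach
time; translation between models is the identity on labels, because the
model correspondence preserves them.

## Random trees and what the generator does and does not emulate

`random_tree(n, seed)` draws uniformly over all $n^{n-1}$ rooted labeled
trees (uniform Prüfer sequence $\times$ uniform root; a chi-squared check
over the nine three-taxon trees guards the claim), deterministically per
seed and without disturbing the caller's RNG state. Uniformity over
*labeled rooted trees* is the right reference measure for certifying
structural claims, which is what this package does; it is **not** a model
of real phylogenies — it produces unary chains (ancestor series with a
single descendant) and polytomies at rates no birth–death process would,
has no branch lengths, and carries no character evolution. Passing tests
therefore certify graph-theoretic correctness of the implementation on the
full space of tree shapes, not inferential performance on empirical data —
there is nothing statistical here to validate against real datasets.

## Problem sizes and numerical choices

Exhaustive certifications run at $n \le 5$ (1 + 2 + 9 + 64 + 625 = 701
trees per side), where the full bijection check completes in seconds;
random-tree sweeps use 500 trees up to 64 taxa for round trips, 200 trees
up to 10 taxa for the all-subsets subtree correspondence (at most
$2^{10} - 1$ subsets each), and 200 trees for clade-name synonymy. These
sizes exercise every code path — polytomies, unary chains, singletons,
64-taxon depth — while keeping the whole suite interactive. There is no
floating-point anywhere in the core: every computation is exact on discrete
structures, so no tolerances apply; determinism is obtained by canonical
child ordering (radix byte order), canonical junction naming in the stem
enumerator, and seed-scoped RNG.

## Known limitations

* No branch lengths, divergence times, or support values — by design, with
  hard errors rather than silent dropping.
* No reticulations or unrooted trees; the ancestry semantics require a
  rooted tree.
* Exhaustive operations are size-guarded ($n \le 7$ for enumeration,
  $n \le 12$ for subset sweeps); they are certification tools, not
  general-purpose counters.
* The figure fixtures are reconstructions constrained by their textual
  descriptions (the drawings themselves are not machine-readable); the
  shipped character table is likewise a documented synthetic
  reconstruction. All properties asserted about them in tests are the
  text-stated ones.
* Crown-clade machinery, apomorphy-based definitions and nomenclatural
  registration are out of scope; the package implements clade *semantics*
  on each model, not naming rules.
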