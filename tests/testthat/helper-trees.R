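# Shared fixtures and independent oracles for the test suite.

# caterpillar a -> b -> c -> ... (root first)
chain_tree <- function(labels) {
  node_tree(tibble::tibble(
    label = labels,
    parent = c(NA_character_, labels[-length(labels)])
  ))
}

star_tree <- function(root, leaves) {
  node_tree(tibble::tibble(
    label = c(root, leaves),
    parent = c(NA_character_, rep(root, length(leaves)))
  ))
}

# Independent connectivity oracle for is_subtree, via igraph components.
igraph_is_subtree <- function(tree, members) {
  if (length(members) == 1) return(TRUE)
  edges <- tree[!is.na(tree$parent), c("parent", "label")]
  keep <- edges$parent %in% members & edges$label %in% members
  g <- igraph::graph_from_data_frame(edges[keep, ], directed = FALSE,
                                     vertices = data.frame(name = members))
  igraph::count_components(g) == 1
}

# Brute-force YCA oracle: intersect full ancestor-or-self chains, pick the
# deepest common vertex.
brute_yca <- function(tree, members) {
  depth <- stats::setNames(
    vapply(tree$label, function(v) length(taxon_ancestors(tree, v)), integer(1)),
    tree$label
  )
  chains <- lapply(members, function(v) c(v, taxon_ancestors(tree, v)))
  common <- Reduce(intersect, chains)
  common[which.max(depth[common])]
}

# every non-empty subset of a label vector (for exhaustive sweeps)
all_subsets <- function(labels) {
  n <- length(labels)
  lapply(seq_len(2^n - 1), function(mask) {
    labels[bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L]
  })
}

expect_valid_tree <- function(tree) {
  if (is_node_tree(tree)) {
    expect_no_error(cladegraph:::validate_node_tree(tree))
    expect_identical(nrow(tree), sum(!is.na(tree$parent)) + 1L)
  } else {
    expect_no_error(cladegraph:::validate_stem_tree(tree))
    expect_identical(length(unique(c(tree$tail, tree$head))), nrow(tree) + 1L)
  }
}

is_node_tree <- function(x) inherits(x, "node_tree")
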