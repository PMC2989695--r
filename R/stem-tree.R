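#' Stem-based (branch-based) phylogenetic trees
#'
#' A stem-based tree models a phylogeny by representing every taxon as an
#' *edge* (a lineage persisting between two speciation events) and every
#' vertex as a speciation event. The vertices — called *junctions* here —
#' carry no biological identity: only the edge labels are taxa, and the
#' junction identifiers are internal bookkeeping that is never serialized.
#' Every stem-based tree is *planted*: its root junction has exactly one
#' child, and the single edge hanging from the root represents the common
#' ancestor of all sampled taxa.
#'
#' `stem_tree()` builds a validated tree from a data frame with one row per
#' edge: columns `tail` (parent junction), `head` (child junction) and
#' `label` (the taxon the edge represents). Junction identifiers may be any
#' strings; the root junction is inferred as the unique junction that is
#' never a head. Two stem trees are considered equal when they agree up to
#' junction renaming, which is what [write_newick()] canonicalizes over.
#'
#' @param x A data frame with columns `tail`, `head` and `label`.
#' @return A `stem_tree`: a tibble with columns `tail`, `head`, `label`.
#' @examples
#' u <- stem_tree(data.frame(
#'   tail  = c("j0", "j1", "j1", "j2", "j2"),
#'   head  = c("j1", "j2", "j3", "j4", "j5"),
#'   label = c("z", "y", "A", "B", "C")
#' ))
#' root_label(u)   # "z": the planted root edge
#' @seealso [node_tree()], [stem_to_node()], [planted_subtree()],
#'   [stem_is_subtree()].
#' @export
stem_tree <- function(x) {
  if (!is.data.frame(x) || !all(c("tail", "head", "label") %in% names(x))) {
    abort_cg("`x` must be a data frame with columns `tail`, `head`, `label`.",
             class = "cladegraph_error_bad_argument")
  }
  edges <- tibble::tibble(
    tail = as.character(x$tail),
    head = as.character(x$head),
    label = as.character(x$label)
  )
  validate_stem_tree(new_stem_tree(edges))
}

new_stem_tree <- function(edges) {
  tibble::new_tibble(edges, class = "stem_tree")
}

validate_stem_tree <- function(tree) {
  if (nrow(tree) == 0) {
    abort_cg("A stem tree must contain at least one taxon edge.",
             class = "cladegraph_error_empty_tree")
  }
  if (anyNA(tree$label) || any(!nzchar(tree$label))) {
    abort_cg("Edge (taxon) labels must be non-empty and non-missing.",
             class = "cladegraph_error_bad_label")
  }
  if (anyDuplicated(tree$label)) {
    abort_cg(
      sprintf("Duplicate taxon labels: %s",
              paste(unique(tree$label[duplicated(tree$label)]), collapse = ", ")),
      class = "cladegraph_error_duplicate_label"
    )
  }
  if (anyNA(tree$tail) || anyNA(tree$head)) {
    abort_cg("Junction identifiers must be non-missing.",
             class = "cladegraph_error_bad_label")
  }
  if (anyDuplicated(tree$head)) {
    abort_cg("Each junction can have at most one parent edge.",
             class = "cladegraph_error_not_a_tree")
  }
  junctions <- unique(c(tree$tail, tree$head))
  if (length(junctions) != nrow(tree) + 1L) {
    abort_cg(
      sprintf("Junction count (%d) must equal edge count + 1 (%d); the graph is not a tree.",
              length(junctions), nrow(tree) + 1L),
      class = "cladegraph_error_not_a_tree"
    )
  }
  roots <- setdiff(tree$tail, tree$head)
  if (length(roots) != 1) {
    abort_cg("The junction graph is not connected (no unique root junction).",
             class = "cladegraph_error_not_a_tree")
  }
  # connectivity from the root
  kids <- split(tree$head, factor(tree$tail, levels = junctions))
  seen <- character(0)
  frontier <- roots
  while (length(frontier) > 0) {
    seen <- c(seen, frontier)
    frontier <- unlist(kids[frontier], use.names = FALSE)
  }
  if (length(seen) != length(junctions)) {
    abort_cg("The junction graph is cyclic or disconnected.",
             class = "cladegraph_error_not_a_tree")
  }
  if (sum(tree$tail == roots) != 1) {
    abort_cg(
      "A stem-based tree must be planted: its root junction must have exactly one child edge.",
      class = "cladegraph_error_not_planted"
    )
  }
  tree
}

#' @export
print.stem_tree <- function(x, ...) {
  cat(sprintf("<stem_tree> %d taxa (edges), %d junctions, root edge '%s'\n",
              nrow(x), nrow(x) + 1L, root_label(x)))
  cat(write_newick(x), "\n")
  invisible(x)
}

is_stem_tree <- function(x) inherits(x, "stem_tree")

# root junction id
st_root <- function(tree) setdiff(tree$tail, tree$head)

# named by edge label: parent edge label (NA for the root edge)
st_edge_parents <- function(tree) {
  edge_at_head <- stats::setNames(tree$label, tree$head)  # head junction -> edge above it
  stats::setNames(unname(edge_at_head[tree$tail]), tree$label)
}

# named by edge label: child edge labels
st_edge_children <- function(tree) {
  ep <- st_edge_parents(tree)
  has_parent <- !is.na(ep)
  split(names(ep)[has_parent], factor(unname(ep[has_parent]), levels = tree$label))
}

# junction depths from the root junction (root = 0)
st_junction_depths <- function(tree) {
  junctions <- unique(c(tree$tail, tree$head))
  depth <- stats::setNames(rep(NA_integer_, length(junctions)), junctions)
  kids <- split(tree$head, factor(tree$tail, levels = junctions))
  frontier <- st_root(tree)
  d <- 0L
  while (length(frontier) > 0) {
    depth[frontier] <- d
    d <- d + 1L
    frontier <- unlist(kids[frontier], use.names = FALSE)
  }
  depth
}

#' Planted subtrees of a stem-based tree
#'
#' In a stem tree the analogue of a proper subtree is the *planted proper
#' subtree*: an edge together with every edge descended from it. Its local
#' root junction (the tail of the planting edge) has exactly one child edge
#' inside the subtree, so the subtree is itself a valid stem-based tree.
#' `planted_subtree()` returns the planted proper subtree hanging at edge
#' `taxon` as a [subtree_ref].
#'
#' `stem_is_subtree()` tests an arbitrary set of edge labels: the edges plus
#' their endpoint junctions form a subtree exactly when the number of
#' distinct junctions touched exceeds the edge count by one; the subtree is
#' additionally *planted* when its shallowest junction has exactly one member
#' edge hanging below it. A subtree of a stem tree that is not planted has no
#' counterpart among subtrees of the node-based model — see
#' [corresponding_subtree()].
#'
#' @param tree A `stem_tree`.
#' @param taxon An edge (taxon) label in `tree`.
#' @param taxa A character vector of edge labels in `tree`.
#' @return `planted_subtree()`: a `subtree_ref` with `planted = TRUE`;
#'   `stem_is_subtree()`: a one-row tibble with logical columns `is_subtree`
#'   and `planted`.
#' @examples
#' u3 <- fig3_tree("stem")
#' planted_subtree(u3, "2")                      # edges 2,4,5,8,9
#' stem_is_subtree(u3, c("4", "5", "8", "9"))    # subtree, but not planted
#' stem_is_subtree(u3, c("2", "4", "5", "8", "9"))
#' @export
planted_subtree <- function(tree, taxon) {
  check_string(taxon, "taxon")
  check_labels_exist(tree, taxon, "stem")
  kids <- st_edge_children(tree)
  out <- taxon
  frontier <- kids[[taxon]]
  while (length(frontier) > 0) {
    out <- c(out, frontier)
    frontier <- unlist(kids[frontier], use.names = FALSE)
  }
  subtree_ref(model = "stem", elements = out, planted = TRUE, host = tree)
}

#' @rdname planted_subtree
#' @export
stem_is_subtree <- function(tree, taxa) {
  taxa <- unique(as.character(taxa))
  check_labels_exist(tree, taxa, "stem")
  res <- st_is_subtree_impl(
    tails = stats::setNames(tree$tail, tree$label),
    heads = stats::setNames(tree$head, tree$label),
    jdepth = st_junction_depths(tree),
    members = taxa
  )
  tibble::tibble(is_subtree = res[[1]], planted = res[[2]])
}

# Returns c(is_subtree, planted). members: unique edge labels, validated.
st_is_subtree_impl <- function(tails, heads, jdepth, members) {
  t_m <- unname(tails[members])
  touched <- unique(c(t_m, unname(heads[members])))
  connected <- length(touched) == length(members) + 1L
  if (!connected) return(c(FALSE, FALSE))
  shallow <- touched[which.min(jdepth[touched])]
  c(TRUE, sum(t_m == shallow) == 1L)
}
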