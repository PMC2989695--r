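#' Node-based phylogenetic trees
#'
#' A node-based tree models a phylogeny by representing every taxon — sampled
#' or inferred ancestral — as a *vertex*; an edge from a parent vertex to a
#' child vertex is the hypothesis that the parent taxon is the immediate
#' ancestor of the child taxon. This is the reading most practitioners give a
#' phylogeny by default: tips are sampled taxa, internal vertices are inferred
#' common ancestors.
#'
#' `node_tree()` builds a validated tree from a data frame with one row per
#' taxon: a `label` column of unique, non-empty taxon names and a `parent`
#' column naming each taxon's parent (`NA` exactly once, for the root).
#' Alternatively a named character vector can be supplied (names = children,
#' values = parents, `NA` for the root). Polytomies (vertices with more than
#' two children) are fully supported; child order carries no meaning.
#'
#' The returned object is a tibble of class `node_tree`, so it prints,
#' filters and joins like any tibble, but the class contract is that the rows
#' describe a single connected rooted tree: every non-root vertex has exactly
#' one parent, following parents always terminates at the root, and the edge
#' count equals the vertex count minus one.
#'
#' @param x A data frame with columns `label` and `parent`, or a named
#'   character vector mapping each taxon to its parent (`NA` for the root).
#' @return A `node_tree`: a tibble with columns `label` and `parent`.
#' @examples
#' t1 <- node_tree(c(A = "z", B = "y", C = "y", y = "z", z = NA))
#' root_label(t1)
#' taxon_parent(t1, "B")
#' @seealso [stem_tree()] for the edge-labeled model, [node_to_stem()] for
#'   conversion, [clade()] and [classify_clade()] for monophyly queries.
#' @export
node_tree <- function(x) {
  if (!is.data.frame(x) && is.atomic(x)) {
    x <- as.character(x) |> stats::setNames(names(x))
  }
  if (is.character(x)) {
    if (is.null(names(x)) || any(names(x) == "")) {
      abort_cg("A character `x` must be a fully named parent map.",
               class = "cladegraph_error_bad_argument")
    }
    x <- tibble::tibble(label = names(x), parent = unname(x))
  }
  if (!is.data.frame(x) || !all(c("label", "parent") %in% names(x))) {
    abort_cg("`x` must be a data frame with columns `label` and `parent`.",
             class = "cladegraph_error_bad_argument")
  }
  nodes <- tibble::tibble(
    label = as.character(x$label),
    parent = as.character(x$parent)
  )
  validate_node_tree(new_node_tree(nodes))
}

# Low-level constructor: no validation, for internal use on known-good input.
new_node_tree <- function(nodes) {
  tibble::new_tibble(nodes, class = "node_tree")
}

validate_node_tree <- function(tree) {
  if (nrow(tree) == 0) {
    abort_cg("A node tree must contain at least one taxon.",
             class = "cladegraph_error_empty_tree")
  }
  if (anyNA(tree$label) || any(!nzchar(tree$label))) {
    abort_cg("Taxon labels must be non-empty and non-missing.",
             class = "cladegraph_error_bad_label")
  }
  if (anyDuplicated(tree$label)) {
    abort_cg(
      sprintf("Duplicate taxon labels: %s",
              paste(unique(tree$label[duplicated(tree$label)]), collapse = ", ")),
      class = "cladegraph_error_duplicate_label"
    )
  }
  is_root <- is.na(tree$parent)
  if (sum(is_root) != 1) {
    abort_cg(
      sprintf("A rooted tree needs exactly one root (parent = NA); found %d.",
              sum(is_root)),
      class = "cladegraph_error_bad_root"
    )
  }
  unknown <- setdiff(tree$parent[!is_root], tree$label)
  if (length(unknown) > 0) {
    abort_cg(
      sprintf("Parents not present as taxa: %s", paste(unknown, collapse = ", ")),
      class = "cladegraph_error_label_not_found"
    )
  }
  # Connectivity/acyclicity: breadth-first from the root must reach everything.
  kids <- nt_children(tree)
  seen <- character(0)
  frontier <- tree$label[is_root]
  while (length(frontier) > 0) {
    seen <- c(seen, frontier)
    frontier <- unlist(kids[frontier], use.names = FALSE)
  }
  if (length(seen) != nrow(tree)) {
    abort_cg(
      sprintf("Tree is cyclic or disconnected: %d of %d taxa unreachable from the root.",
              nrow(tree) - length(seen), nrow(tree)),
      class = "cladegraph_error_not_a_tree"
    )
  }
  tree
}

#' @export
print.node_tree <- function(x, ...) {
  cat(sprintf("<node_tree> %d taxa (vertices), %d edges, root '%s'\n",
              nrow(x), nrow(x) - 1L, root_label(x)))
  cat(write_newick(x), "\n")
  invisible(x)
}

is_node_tree <- function(x) inherits(x, "node_tree")

# parent lookup as a named character vector; NA at the root
nt_parents <- function(tree) {
  stats::setNames(tree$parent, tree$label)
}

nt_children <- function(tree) {
  has_parent <- !is.na(tree$parent)
  out <- split(tree$label[has_parent], factor(tree$parent[has_parent], levels = tree$label))
  out
}

nt_depths <- function(tree) {
  pm <- nt_parents(tree)
  depth <- stats::setNames(rep(NA_integer_, nrow(tree)), tree$label)
  root <- tree$label[is.na(tree$parent)]
  depth[root] <- 0L
  kids <- nt_children(tree)
  frontier <- root
  d <- 0L
  while (length(frontier) > 0) {
    d <- d + 1L
    frontier <- unlist(kids[frontier], use.names = FALSE)
    depth[frontier] <- d
  }
  depth
}

#' Taxa and structure accessors
#'
#' `taxa()` returns the taxon labels of either tree model (vertex labels of a
#' node tree, edge labels of a stem tree). `n_taxa()` counts them.
#' `root_label()` returns the root taxon of a node tree, or the planted root
#' edge's taxon for a stem tree.
#'
#' @param tree A `node_tree` or `stem_tree`.
#' @return `taxa()`: character vector; `n_taxa()`: integer; `root_label()`:
#'   a single taxon label.
#' @export
taxa <- function(tree) {
  UseMethod("taxa")
}

#' @export
taxa.node_tree <- function(tree) tree$label

#' @export
taxa.stem_tree <- function(tree) tree$label

#' @rdname taxa
#' @export
n_taxa <- function(tree) length(taxa(tree))

#' @rdname taxa
#' @export
root_label <- function(tree) {
  UseMethod("root_label")
}

#' @export
root_label.node_tree <- function(tree) tree$label[is.na(tree$parent)]

#' @export
root_label.stem_tree <- function(tree) tree$label[tree$tail == st_root(tree)]

#' Ancestry queries on a node-based tree
#'
#' `taxon_parent()` returns the parent taxon of `taxon` (or `NA` for the
#' root). `taxon_ancestors()` returns the chain of ancestors from the parent
#' up to and including the root (empty for the root itself; a taxon is never
#' its own ancestor). `taxon_lineage()` returns the part of that chain that
#' descends from — and includes — a designated ancestor `top`; with
#' `top = root_label(tree)` this is the *total lineage*. `taxon_descendants()`
#' returns every taxon having `taxon` on its ancestor chain (excluding
#' `taxon` itself).
#'
#' The queried taxon itself is excluded from lineages and ancestor lists, and
#' the bounding ancestor `top` is included; this endpoint convention is fixed
#' and documented here because "lineage" is used with both conventions in the
#' literature.
#'
#' @param tree A `node_tree`.
#' @param taxon,top Taxon labels present in `tree`.
#' @return `taxon_parent()`: a label or `NA`; `taxon_ancestors()` and
#'   `taxon_lineage()`: a character vector ordered from youngest to oldest;
#'   `taxon_descendants()`: an unordered character vector.
#' @examples
#' t3 <- fig3_tree("node")
#' taxon_parent(t3, "8")
#' taxon_ancestors(t3, "8")
#' taxon_lineage(t3, "8", top = "4")
#' taxon_descendants(t3, "2")
#' @export
taxon_parent <- function(tree, taxon) {
  check_string(taxon, "taxon")
  check_labels_exist(tree, taxon, "node")
  unname(nt_parents(tree)[taxon])
}

#' @rdname taxon_parent
#' @export
taxon_ancestors <- function(tree, taxon) {
  check_string(taxon, "taxon")
  check_labels_exist(tree, taxon, "node")
  pm <- nt_parents(tree)
  out <- character(0)
  v <- unname(pm[taxon])
  while (!is.na(v)) {
    out <- c(out, v)
    v <- unname(pm[v])
  }
  out
}

#' @rdname taxon_parent
#' @export
taxon_lineage <- function(tree, taxon, top = root_label(tree)) {
  check_string(top, "top")
  check_labels_exist(tree, top, "node")
  anc <- taxon_ancestors(tree, taxon)
  idx <- match(top, anc)
  if (is.na(idx)) {
    abort_cg(
      sprintf("'%s' is not an ancestor of '%s'.", top, taxon),
      class = "cladegraph_error_not_an_ancestor"
    )
  }
  anc[seq_len(idx)]
}

#' @rdname taxon_parent
#' @export
taxon_descendants <- function(tree, taxon) {
  check_string(taxon, "taxon")
  check_labels_exist(tree, taxon, "node")
  kids <- nt_children(tree)
  out <- character(0)
  frontier <- kids[[taxon]]
  while (length(frontier) > 0) {
    out <- c(out, frontier)
    frontier <- unlist(kids[frontier], use.names = FALSE)
  }
  out
}

#' Youngest common ancestor of a taxon set
#'
#' Returns the unique vertex that is an ancestor-or-self of every member of
#' `taxa` and is younger than any other such vertex — the youngest common
#' ancestor (often called the MRCA). The returned vertex may itself belong to
#' `taxa`; whether it does is exactly what separates paraphyly from polyphyly
#' in [classify_clade()].
#'
#' @param tree A `node_tree`.
#' @param taxa Non-empty character vector of taxon labels.
#' @return A single taxon label.
#' @examples
#' t3 <- fig3_tree("node")
#' yca(t3, c("8", "9"))
#' yca(t3, c("4", "5", "8", "9"))
#' @export
yca <- function(tree, taxa) {
  if (length(taxa) == 0) {
    abort_cg("Cannot take the common ancestor of an empty taxon set.",
             class = "cladegraph_error_empty_query")
  }
  taxa <- unique(as.character(taxa))
  check_labels_exist(tree, taxa, "node")
  pm <- nt_parents(tree)
  # ancestor-or-self chain of the first member, youngest first
  chain <- taxa[[1]]
  v <- unname(pm[taxa[[1]]])
  while (!is.na(v)) {
    chain <- c(chain, v)
    v <- unname(pm[v])
  }
  keep <- rep(TRUE, length(chain))
  for (x in taxa[-1]) {
    xs <- x
    v <- unname(pm[x])
    while (!is.na(v)) {
      xs <- c(xs, v)
      v <- unname(pm[v])
    }
    keep <- keep & (chain %in% xs)
  }
  chain[keep][[1]]
}

#' Subtrees of a node-based tree
#'
#' A *proper subtree* consists of one vertex together with all of its
#' descendants; it is uniquely determined by its root vertex, so a tree has
#' exactly as many proper subtrees as vertices. `proper_subtree()` returns
#' the proper subtree rooted at `taxon` as a [subtree_ref].
#'
#' `is_subtree()` tests whether an arbitrary taxon set induces a subtree: the
#' edges of the tree having both endpoints in the set must connect it. For a
#' subset of a tree the induced subgraph is automatically acyclic, so it is a
#' subtree exactly when the number of induced edges is one less than the
#' number of selected vertices.
#'
#' @param tree A `node_tree`.
#' @param taxon A taxon label in `tree`.
#' @param taxa A character vector of taxon labels in `tree`.
#' @return `proper_subtree()`: a `subtree_ref`; `is_subtree()`: `TRUE` or
#'   `FALSE`.
#' @examples
#' t3 <- fig3_tree("node")
#' proper_subtree(t3, "2")
#' is_subtree(t3, c("4", "5", "8", "9"))   # FALSE: their YCA 2 is missing
#' is_subtree(t3, c("2", "4", "5", "8", "9"))
#' @export
proper_subtree <- function(tree, taxon) {
  check_string(taxon, "taxon")
  check_labels_exist(tree, taxon, "node")
  subtree_ref(
    model = "node",
    elements = c(taxon, taxon_descendants(tree, taxon)),
    host = tree
  )
}

#' @rdname proper_subtree
#' @export
is_subtree <- function(tree, taxa) {
  taxa <- unique(as.character(taxa))
  check_labels_exist(tree, taxa, "node")
  nt_is_subtree_impl(nt_parents(tree), taxa)
}

# pm: named parent vector. members: unique labels, already validated.
nt_is_subtree_impl <- function(pm, members) {
  p <- pm[members]
  internal_edges <- sum(!is.na(p) & p %in% members)
  internal_edges == length(members) - 1L
}
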