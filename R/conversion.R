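#' Convert between the node-based and stem-based tree models
#'
#' The two models carry exactly the same information, encoded differently,
#' and these two relabeling algorithms realize the one-to-one correspondence
#' between them.
#'
#' `node_to_stem()` converts a node-based tree `T` into its stem-based
#' counterpart `U`: a fresh root junction is planted above the old root, a
#' new edge joins it to the old root, every edge `v -> w` of the augmented
#' tree is labeled by its child vertex `w`, and the vertex labels are erased
#' (junctions keep only internal identifiers). The result always has the
#' same taxon labels as `T`, one junction more than `T` has vertices, and is
#' always planted — the new root has exactly one child by construction.
#'
#' `stem_to_node()` reverses this: each non-root junction takes the label of
#' its parent edge, edge labels are erased, and the unlabeled root junction
#' and its single edge are deleted, leaving the head of the old root edge as
#' the new root vertex. The two algorithms are mutually inverse:
#' `stem_to_node(node_to_stem(T))` equals `T` and vice versa, for every tree
#' and whether or not polytomies are present.
#'
#' @param tree A `node_tree` (for `node_to_stem()`) or `stem_tree` (for
#'   `stem_to_node()`).
#' @return The corresponding tree of the other model.
#' @examples
#' t1 <- fig1_tree("node")
#' u1 <- node_to_stem(t1)
#' tree_equal(stem_to_node(u1), t1)
#' @export
node_to_stem <- function(tree) {
  if (!is_node_tree(tree)) {
    abort_cg("`tree` must be a node_tree.", class = "cladegraph_error_bad_argument")
  }
  # junction ids: "j0" is the new planted root; each vertex w keeps a
  # junction named after it internally (identifiers only, never serialized)
  jid <- function(v) paste0("j_", v)
  tail <- ifelse(is.na(tree$parent), "j0", jid(tree$parent))
  new_stem_tree(tibble::tibble(
    tail = tail,
    head = jid(tree$label),
    label = tree$label
  ))
}

#' @rdname node_to_stem
#' @export
stem_to_node <- function(tree) {
  if (!is_stem_tree(tree)) {
    abort_cg("`tree` must be a stem_tree.", class = "cladegraph_error_bad_argument")
  }
  if (sum(tree$tail == st_root(tree)) != 1) {
    # unreachable for validated stem_tree objects; kept as a guard for
    # hand-built structures passed around the class contract
    abort_cg("Input is not planted: the root junction has more than one child.",
             class = "cladegraph_error_not_planted")
  }
  ep <- st_edge_parents(tree)
  new_node_tree(tibble::tibble(label = names(ep), parent = unname(ep)))
}

#' The subtree correspondence between the two models
#'
#' Proper subtrees of a node tree `T` are in one-to-one correspondence with
#' *planted* proper subtrees of its stem counterpart `U`, and more generally
#' subtrees of `T` correspond to planted subtrees of `U` — always with the
#' same label set. The correspondence is not defined for non-planted
#' subtrees of `U`: the same labels, read as vertices of `T`, do not form a
#' subtree there. That failure is the crux of why a node-based clade
#' definition cannot be applied to a stem-based tree, so rather than raising
#' an error, `corresponding_subtree()` returns a diagnostic
#' `undefined_correspondence` object in that case.
#'
#' @param ref A [subtree_ref] into either model.
#' @return A `subtree_ref` into the other model (host attached), or an
#'   `undefined_correspondence` object when a non-planted stem subtree has no
#'   node-model counterpart.
#' @examples
#' t3 <- fig3_tree("node")
#' corresponding_subtree(proper_subtree(t3, "2"))
#' u3 <- fig3_tree("stem")
#' ref <- subtree_ref("stem", c("4", "5", "8", "9"), host = u3)
#' corresponding_subtree(ref)   # undefined: not planted
#' @export
corresponding_subtree <- function(ref) {
  if (!inherits(ref, "subtree_ref")) {
    abort_cg("`ref` must be a subtree_ref.", class = "cladegraph_error_bad_argument")
  }
  if (ref$model == "node") {
    subtree_ref("stem", ref$elements, host = node_to_stem(ref$host))
  } else {
    if (!isTRUE(ref$planted)) {
      return(structure(
        list(
          elements = ref$elements,
          reason = sprintf(
            paste0("The stem subtree {%s} is not planted, so the same labels, ",
                   "read as vertices of the node-based tree, do not form a subtree."),
            paste(ref$elements, collapse = ", "))
        ),
        class = "undefined_correspondence"
      ))
    }
    subtree_ref("node", ref$elements, host = stem_to_node(ref$host))
  }
}

#' Per-taxon character annotations
#'
#' An annotation map records, per taxon, a multiset of character identifiers
#' (apomorphies hypothesized to have become fixed in that taxon's lineage).
#' On a stem tree the characters decorate edges; on a node tree they
#' decorate vertices. No position along an edge is stored — placement within
#' an edge carries no temporal meaning.
#'
#' `annotation_map()` normalizes a data frame with columns `taxon` and
#' `character` (one row per character occurrence). `translate_annotations()`
#' carries a map from one model's tree to the other's: because the
#' model correspondence preserves taxon labels, translation is the identity
#' on the map — the work is validating the taxa against both trees.
#'
#' @param x A data frame with columns `taxon` and `character`.
#' @param ann An `annotation_map`.
#' @param from,to Trees (either model); every annotated taxon must exist in
#'   `from`, and in `to` after translation.
#' @return An `annotation_map`: a tibble with columns `taxon`, `character`.
#' @examples
#' ann <- fig1_annotations()
#' translate_annotations(ann, from = fig1_tree("stem"), to = fig1_tree("node"))
#' @export
annotation_map <- function(x = NULL) {
  if (is.null(x)) {
    x <- tibble::tibble(taxon = character(0), character = character(0))
  }
  if (!is.data.frame(x) || !all(c("taxon", "character") %in% names(x))) {
    abort_cg("`x` must be a data frame with columns `taxon` and `character`.",
             class = "cladegraph_error_bad_argument")
  }
  out <- tibble::tibble(
    taxon = as.character(x$taxon),
    character = as.character(x$character)
  )
  if (anyNA(out$taxon) || (nrow(out) > 0 && any(!nzchar(out$taxon)))) {
    abort_cg("Annotation taxa must be non-empty strings.",
             class = "cladegraph_error_bad_label")
  }
  tibble::new_tibble(out, class = "annotation_map")
}

#' @rdname annotation_map
#' @export
translate_annotations <- function(ann, from, to) {
  ann <- annotation_map(ann)
  check_labels_exist(from, unique(ann$taxon), "source")
  check_labels_exist(to, unique(ann$taxon), "target")
  ann
}
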