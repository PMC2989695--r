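#' Clade extraction on either tree model
#'
#' A monophyletic group is a common ancestor together with *all* of its
#' descendants — with the ancestral taxon itself a member of the group, per
#' Hennig's usage. On a node-based tree a clade originates with a vertex and
#' is the proper subtree rooted there; on a stem-based tree a clade
#' originates with an edge and is the proper subtree planted there. Applied
#' each to its own model, the two namings are synonymous: `clade()` on a
#' stem tree and `clade()` on its node-based counterpart return the same
#' taxon set for every anchor.
#'
#' @param tree A `node_tree` or `stem_tree`.
#' @param anchor A taxon label: a vertex of a node tree, an edge of a stem
#'   tree.
#' @return A sorted character vector: the clade's taxon set. It always
#'   classifies as monophyletic under [classify_clade()].
#' @examples
#' clade(fig3_tree("node"), "2")
#' clade(fig3_tree("stem"), "2")   # identical set
#' @export
clade <- function(tree, anchor) {
  UseMethod("clade")
}

#' @export
clade.node_tree <- function(tree, anchor) {
  sort(proper_subtree(tree, anchor)$elements, method = "radix")
}

#' @export
clade.stem_tree <- function(tree, anchor) {
  sort(planted_subtree(tree, anchor)$elements, method = "radix")
}

#' Classify a taxon set as mono-, para- or polyphyletic
#'
#' Let `a` be the youngest common ancestor ([yca()]) of the set `S`. The set
#' is **monophyletic** when it equals `a` plus all of `a`'s descendants;
#' otherwise it is **paraphyletic** when it contains `a` but omits some of
#' `a`'s descendants, and **polyphyletic** when it excludes its own youngest
#' common ancestor. This makes the para/poly split precise via ancestor
#' membership, reproducing both textbook verdicts on the figure fixture: the
#' set `{4,5,8,9}` excludes its YCA `2` and is polyphyletic, while
#' `{1,3,6,7}` contains its YCA `1` but omits descendants (`2` and the taxa
#' below it) and is paraphyletic. A paraphyletic set is *not* required to
#' induce a connected subgraph.
#'
#' Classification is model-independent: on a stem tree the query is answered
#' on the node-based counterpart (via [stem_to_node()]), and both routes
#' always agree. Ancestral (internal, unsampled-but-inferred) taxa are
#' first-class set members.
#'
#' @param tree A `node_tree` or `stem_tree`.
#' @param taxa Non-empty character vector of taxon labels.
#' @return A string: `"monophyletic"`, `"paraphyletic"` or `"polyphyletic"`.
#' @examples
#' t3 <- fig3_tree("node")
#' classify_clade(t3, c("4", "5", "8", "9"))       # polyphyletic
#' classify_clade(t3, c("1", "3", "6", "7"))       # paraphyletic
#' classify_clade(t3, c("2", "4", "5", "8", "9"))  # monophyletic
#' @export
classify_clade <- function(tree, taxa) {
  UseMethod("classify_clade")
}

#' @export
classify_clade.node_tree <- function(tree, taxa) {
  taxa <- unique(as.character(taxa))
  if (length(taxa) == 0) {
    abort_cg("Cannot classify an empty taxon set.",
             class = "cladegraph_error_empty_query")
  }
  check_labels_exist(tree, taxa, "node")
  a <- yca(tree, taxa)
  full <- c(a, taxon_descendants(tree, a))
  if (length(taxa) == length(full) && setequal(taxa, full)) {
    "monophyletic"
  } else if (a %in% taxa) {
    "paraphyletic"
  } else {
    "polyphyletic"
  }
}

#' @export
classify_clade.stem_tree <- function(tree, taxa) {
  classify_clade(stem_to_node(tree), taxa)
}

#' Diagnose a clade definition applied to the wrong tree model
#'
#' A node-based clade definition anchors a clade at a vertex; a stem-based
#' one anchors it at an edge. Each is only instantiable on its own model:
#' the vertices of a stem tree are anonymous speciation events, not taxa,
#' and a node tree has no "root edge" — an edge cannot exist without both
#' its endpoints. `diagnose_misapplication()` builds the structured report
#' of what goes wrong when the opposite model's definition is forced onto a
#' tree:
#'
#' * On a **stem tree** with a node-based anchor, the anchor must be
#'   addressed indirectly (junctions are unlabeled) as the head junction of
#'   edge `anchor`. The proper-but-not-planted subtree hanging below that
#'   junction is reported together with its classification — for any
#'   junction with two or more child edges the selected taxa exclude their
#'   own common ancestor and come out polyphyletic.
#' * On a **node tree** with a stem-based anchor, the intended "root edge"
#'   is the edge from `anchor`'s parent down to `anchor`. An edge without
#'   its parent vertex is not a graph; omitting the root edge yields a
#'   well-defined node-based clade at `anchor`, which is reported as the
#'   monophyletic fallback reading.
#'
#' @param tree A `node_tree` or `stem_tree`.
#' @param definition `"node"` or `"stem"`: the kind of clade definition
#'   being applied.
#' @param anchor The anchor taxon label (see above for how each case is
#'   addressed). Ignored when the definition matches the model.
#' @return A `misapplication_report` with fields `misapplied`, `model`,
#'   `definition`, `anchor`, `selected`, `classification`, `message`. When
#'   the definition matches the tree's model the report is empty
#'   (`misapplied = FALSE`).
#' @examples
#' diagnose_misapplication(fig3_tree("stem"), "node", anchor = "2")
#' diagnose_misapplication(fig3_tree("node"), "stem", anchor = "3")
#' @export
diagnose_misapplication <- function(tree, definition = c("node", "stem"),
                                    anchor = NULL) {
  definition <- rlang::arg_match(definition)
  model <- if (is_node_tree(tree)) {
    "node"
  } else if (is_stem_tree(tree)) {
    "stem"
  } else {
    abort_cg("`tree` must be a node_tree or stem_tree.",
             class = "cladegraph_error_bad_argument")
  }
  if (model == definition) {
    return(structure(
      list(misapplied = FALSE, model = model, definition = definition,
           anchor = NULL, selected = character(0), classification = NA_character_,
           message = sprintf(
             "A %s-based definition on a %s-based tree: no misapplication.",
             definition, model)),
      class = "misapplication_report"
    ))
  }
  check_string(anchor, "anchor")
  check_labels_exist(tree, anchor, model)
  if (model == "stem") {
    # node-based anchor on a stem tree: the anchored vertex is the head
    # junction of `anchor`; its proper subtree is the set of edges strictly
    # below it, which is never planted when the junction has >= 2 children.
    kids <- st_edge_children(tree)
    selected <- character(0)
    frontier <- kids[[anchor]]
    while (length(frontier) > 0) {
      selected <- c(selected, frontier)
      frontier <- unlist(kids[frontier], use.names = FALSE)
    }
    selected <- sort(selected, method = "radix")
    classification <- if (length(selected) > 0) {
      classify_clade(tree, selected)
    } else {
      NA_character_
    }
    msg <- if (length(selected) == 0) {
      sprintf(paste0(
        "A node-based definition cannot be instantiated on a stem-based tree: ",
        "its vertices are anonymous speciation events, not taxa. The head ",
        "junction of edge '%s' is terminal, so the anchored subtree selects ",
        "no taxa at all."), anchor)
    } else {
      sprintf(paste0(
        "A node-based definition cannot be instantiated on a stem-based tree: ",
        "its vertices are anonymous speciation events, not taxa. Anchoring at ",
        "the head junction of edge '%s' selects the non-planted subtree ",
        "{%s}, which is %s, not monophyletic: every selected taxon descends ",
        "from '%s', which the subtree excludes."),
        anchor, paste(selected, collapse = ", "), classification, anchor)
    }
    structure(
      list(misapplied = TRUE, model = model, definition = definition,
           anchor = anchor, selected = selected,
           classification = classification, message = msg),
      class = "misapplication_report"
    )
  } else {
    # stem-based anchor on a node tree: the intended "root edge" is
    # parent(anchor) -> anchor, but an edge without both endpoints is not a
    # graph. Omitting the root edge leaves the node clade at `anchor`.
    p <- taxon_parent(tree, anchor)
    selected <- clade(tree, anchor)
    msg <- if (is.na(p)) {
      sprintf(paste0(
        "A stem-based definition cannot be instantiated on a node-based tree: ",
        "'%s' is the root vertex, so there is no edge above it at all. The ",
        "node clade at '%s' ({%s}) carries the intended information."),
        anchor, anchor, paste(selected, collapse = ", "))
    } else {
      sprintf(paste0(
        "A stem-based definition cannot be instantiated on a node-based tree: ",
        "the intended 'root edge' %s->%s without its parent vertex '%s' is ",
        "not a graph (an edge needs both endpoints). Omitting the root edge ",
        "yields the well-defined node clade {%s}, which is monophyletic and ",
        "carries the same biological information."),
        p, anchor, p, paste(selected, collapse = ", "))
    }
    structure(
      list(misapplied = TRUE, model = model, definition = definition,
           anchor = anchor, selected = selected,
           classification = classify_clade(tree, selected), message = msg),
      class = "misapplication_report"
    )
  }
}

#' @export
print.misapplication_report <- function(x, ...) {
  if (!x$misapplied) {
    cat("<misapplication_report> none:", x$message, "\n")
    return(invisible(x))
  }
  cat(sprintf("<misapplication_report> %s-based definition on a %s-based tree\n",
              x$definition, x$model))
  cat(sprintf("  anchor: '%s'\n", x$anchor))
  if (length(x$selected) > 0) {
    cat(sprintf("  selected taxa: {%s} — %s\n",
                paste(x$selected, collapse = ", "), x$classification))
  }
  cat(strwrap(x$message, width = 76, prefix = "  "), sep = "\n")
  invisible(x)
}
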