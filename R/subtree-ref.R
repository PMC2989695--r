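#' Subtree references
#'
#' A `subtree_ref` names a subtree of a host tree by its element labels:
#' vertex labels for a node-based host (`model = "node"`) or edge labels for
#' a stem-based host (`model = "stem"`). Construction verifies that the
#' elements really do induce a subtree of the host; for a stem host the
#' `planted` flag records whether the subtree is planted (computed from the
#' host when not supplied).
#'
#' @param model `"node"` or `"stem"`.
#' @param elements Character vector of element labels.
#' @param host The host tree the reference points into.
#' @param planted For stem references, whether the subtree is planted;
#'   derived from the host when `NULL`. Always `NA` for node references.
#' @return An object of class `subtree_ref` with fields `model`, `elements`
#'   (sorted), `planted` and `host`.
#' @seealso [proper_subtree()], [planted_subtree()], [corresponding_subtree()].
#' @export
subtree_ref <- function(model = c("node", "stem"), elements, host, planted = NULL) {
  model <- rlang::arg_match(model)
  elements <- unique(as.character(elements))
  if (model == "node") {
    if (!is_node_tree(host)) {
      abort_cg("A node-model subtree_ref needs a node_tree host.",
               class = "cladegraph_error_bad_argument")
    }
    if (!is_subtree(host, elements)) {
      abort_cg(
        sprintf("Vertices {%s} do not induce a subtree of the host node tree.",
                paste(elements, collapse = ", ")),
        class = "cladegraph_error_invalid_ref"
      )
    }
    planted <- NA
  } else {
    if (!is_stem_tree(host)) {
      abort_cg("A stem-model subtree_ref needs a stem_tree host.",
               class = "cladegraph_error_bad_argument")
    }
    chk <- stem_is_subtree(host, elements)
    if (!chk$is_subtree) {
      abort_cg(
        sprintf("Edges {%s} do not induce a subtree of the host stem tree.",
                paste(elements, collapse = ", ")),
        class = "cladegraph_error_invalid_ref"
      )
    }
    planted <- planted %||% chk$planted
  }
  structure(
    list(model = model, elements = sort(elements), planted = planted, host = host),
    class = "subtree_ref"
  )
}

#' @export
print.subtree_ref <- function(x, ...) {
  kind <- if (x$model == "node") {
    "vertices"
  } else if (isTRUE(x$planted)) {
    "edges (planted)"
  } else {
    "edges (not planted)"
  }
  cat(sprintf("<subtree_ref:%s> %d %s: {%s}\n",
              x$model, length(x$elements), kind,
              paste(x$elements, collapse = ", ")))
  invisible(x)
}

#' @export
print.undefined_correspondence <- function(x, ...) {
  cat("<undefined correspondence>\n")
  cat(sprintf("  edges: {%s}\n", paste(x$elements, collapse = ", ")))
  cat(" ", x$reason, "\n")
  invisible(x)
}
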