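#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy summaries of trees and certificates
#'
#' `tidy()` on a tree returns one row per taxon with its parent (for a stem
#' tree: parent *edge*), depth and leaf status. `glance()` returns a one-row
#' structural summary; on a certificate it flattens the certification report
#' so results can be row-bound across runs.
#'
#' @param x A `node_tree`, `stem_tree`, `bijection_certificate` or
#'   `subtree_certificate`.
#' @param ... Unused; for generic consistency.
#' @return A tibble.
#' @examples
#' tidy(fig3_tree("node"))
#' glance(certify_bijection(3))
#' @method tidy node_tree
#' @export
tidy.node_tree <- function(x, ...) {
  depth <- nt_depths(x)
  kids <- nt_children(x)
  tibble::tibble(
    label = x$label,
    parent = x$parent,
    depth = unname(depth[x$label]),
    is_leaf = vapply(kids[x$label], length, integer(1)) == 0L
  )
}

#' @rdname tidy.node_tree
#' @method tidy stem_tree
#' @export
tidy.stem_tree <- function(x, ...) {
  ep <- st_edge_parents(x)
  kids <- st_edge_children(x)
  jdepth <- st_junction_depths(x)
  tibble::tibble(
    label = x$label,
    parent_edge = unname(ep[x$label]),
    depth = unname(jdepth[x$tail]),
    is_terminal = vapply(kids[x$label], length, integer(1)) == 0L
  )
}

#' @rdname tidy.node_tree
#' @method glance node_tree
#' @export
glance.node_tree <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    model = "node",
    n_taxa = nrow(x),
    n_edges = nrow(x) - 1L,
    root = root_label(x),
    n_leaves = sum(td$is_leaf),
    max_depth = max(td$depth)
  )
}

#' @rdname tidy.node_tree
#' @method glance stem_tree
#' @export
glance.stem_tree <- function(x, ...) {
  td <- tidy(x)
  tibble::tibble(
    model = "stem",
    n_taxa = nrow(x),
    n_junctions = nrow(x) + 1L,
    root = root_label(x),
    n_terminal = sum(td$is_terminal),
    max_depth = max(td$depth) + 1L
  )
}

#' @rdname tidy.node_tree
#' @method glance bijection_certificate
#' @export
glance.bijection_certificate <- function(x, ...) {
  tibble::tibble(
    n = x$n, expected = x$expected, n_node = x$n_node, n_stem = x$n_stem,
    injective = x$injective, image_matches = x$image_matches,
    roundtrip_node = x$roundtrip_node, roundtrip_stem = x$roundtrip_stem,
    pass = x$pass
  )
}

#' @rdname tidy.node_tree
#' @method glance subtree_certificate
#' @export
glance.subtree_certificate <- function(x, ...) {
  tibble::tibble(
    n_taxa = x$n_taxa, n_subsets = x$n_subsets,
    n_subtrees_node = x$n_subtrees_node, n_planted_stem = x$n_planted_stem,
    n_agree = x$n_agree, n_proper = x$n_proper, pass = x$pass
  )
}

# Shared layout: leaves get consecutive x positions in canonical (serialized)
# order; an internal element sits at the mean of its children; y is depth,
# drawn downward from the root.
tree_layout <- function(labels, root, kids, depth) {
  x <- stats::setNames(rep(NA_real_, length(labels)), labels)
  counter <- 0
  assign_x <- function(v) {
    children <- kids[[v]]
    if (is.null(children) || length(children) == 0) {
      counter <<- counter + 1
      x[v] <<- counter
    } else {
      mins <- vapply(children, function(ch) newick_render(ch, kids)$min, character(1))
      for (ch in children[order(mins, method = "radix")]) assign_x(ch)
      x[v] <<- mean(x[kids[[v]]])
    }
  }
  assign_x(root)
  tibble::tibble(label = labels, x = unname(x[labels]), y = -unname(depth[labels]))
}

#' Plot trees with ggplot2
#'
#' `autoplot()` draws the tree the way its model means it: for a node tree
#' taxa sit *at the vertices* and edges are unadorned relation lines; for a
#' stem tree taxa label the *edges* (at their midpoints, displaced from the
#' tips) and vertices are anonymous speciation-event dots, with the planted
#' root edge hanging from the unlabeled top junction.
#'
#' @param object A `node_tree` or `stem_tree`.
#' @param ... Unused.
#' @return A ggplot object.
#' @examples
#' library(ggplot2)
#' autoplot(fig1_tree("node"))
#' autoplot(fig1_tree("stem"))
#' @method autoplot node_tree
#' @export
autoplot.node_tree <- function(object, ...) {
  kids <- nt_children(object)
  lay <- tree_layout(object$label, root_label(object), kids, nt_depths(object))
  pos <- stats::setNames(seq_len(nrow(lay)), lay$label)
  seg <- dplyr::filter(object, !is.na(.data$parent))
  seg <- tibble::tibble(
    x = lay$x[match(seg$parent, lay$label)],
    y = lay$y[match(seg$parent, lay$label)],
    xend = lay$x[match(seg$label, lay$label)],
    yend = lay$y[match(seg$label, lay$label)]
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      colour = "grey40"
    ) +
    ggplot2::geom_point(data = lay, ggplot2::aes(x = .data$x, y = .data$y), size = 2) +
    ggplot2::geom_text(
      data = lay,
      ggplot2::aes(x = .data$x, y = .data$y, label = .data$label),
      vjust = -0.8
    ) +
    ggplot2::labs(title = "Node-based tree: taxa are vertices",
                  x = NULL, y = "depth below root") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' @rdname autoplot.node_tree
#' @method autoplot stem_tree
#' @export
autoplot.stem_tree <- function(object, ...) {
  kids <- st_edge_children(object)
  jdepth <- st_junction_depths(object)
  # depth of the head junction of each edge
  depth <- stats::setNames(unname(jdepth[object$head]), object$label)
  lay <- tree_layout(object$label, root_label(object), kids, depth)
  # each edge runs from its parent junction (parent edge's head) to its head
  ep <- st_edge_parents(object)
  parent_y <- ifelse(is.na(ep[lay$label]), -min(jdepth), lay$y[match(ep[lay$label], lay$label)])
  parent_x <- ifelse(is.na(ep[lay$label]), lay$x, lay$x[match(ep[lay$label], lay$label)])
  seg <- tibble::tibble(
    x = unname(parent_x), y = unname(parent_y),
    xend = lay$x, yend = lay$y, label = lay$label
  )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y, xend = .data$xend, yend = .data$yend),
      colour = "grey30", linewidth = 0.8
    ) +
    ggplot2::geom_point(data = lay, ggplot2::aes(x = .data$x, y = .data$y),
                        size = 1.5, colour = "grey50") +
    ggplot2::geom_text(
      data = seg,
      ggplot2::aes(x = (.data$x + .data$xend) / 2, y = (.data$y + .data$yend) / 2,
                   label = .data$label),
      hjust = -0.4
    ) +
    ggplot2::labs(title = "Stem-based tree: taxa are edges, vertices are speciation events",
                  x = NULL, y = "depth below planted root") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_blank(),
                   panel.grid = ggplot2::element_blank())
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @importFrom rlang .data
NULL
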