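#' Exhaustive enumeration of small labeled trees
#'
#' These enumerators are the brute-force oracle behind the model-equivalence
#' certificates. `enumerate_node_trees()` generates every rooted tree whose
#' vertices carry the given labels, exactly once: free labeled trees are
#' produced bijectively from Prüfer sequences (so there are `n^(n-2)` of
#' them for `n >= 2`), and each is rooted at each vertex in turn, giving
#' Cayley's `n^(n-1)` rooted trees.
#'
#' `enumerate_stem_trees()` generates every planted tree whose `n` edges
#' carry the given labels, exactly once up to junction renaming — by a
#' deliberately different route, so that certifying the two enumerations
#' against each other is not circular. Junctions are canonically identified
#' with the head of their unique parent edge, under which planted
#' edge-labeled trees correspond exactly to acyclic parent maps over the
#' label set; those maps are enumerated by brute force (every root choice
#' times every parent function, filtered for acyclicity). No Prüfer code and
#' no conversion algorithm is involved.
#'
#' Both enumerators refuse `n > 7` — the counts grow as `n^(n-1)` and
#' exhaustive generation beyond that is not meaningfully interactive.
#'
#' @param labels Character vector of 1 to 7 unique labels.
#' @return A list of `node_tree` (respectively `stem_tree`) objects.
#' @examples
#' length(enumerate_node_trees(c("a", "b", "c")))  # 9 = 3^2
#' length(enumerate_stem_trees(c("a", "b", "c")))  # 9: the models agree
#' @export
enumerate_node_trees <- function(labels) {
  labels <- check_enum_labels(labels)
  n <- length(labels)
  if (n == 1) {
    return(list(new_node_tree(tibble::tibble(label = labels, parent = NA_character_))))
  }
  out <- vector("list", n^(n - 1))
  k <- 0L
  for (seq_idx in prufer_sequences(n)) {
    adj <- prufer_decode(seq_idx, n)
    for (root in seq_len(n)) {
      parent_idx <- orient_edges(adj, n, root)
      k <- k + 1L
      out[[k]] <- new_node_tree(tibble::tibble(
        label = labels,
        parent = c(NA_character_, labels)[parent_idx + 1L]
      ))
    }
  }
  out
}

check_enum_labels <- function(labels) {
  labels <- as.character(labels)
  if (length(labels) < 1 || length(labels) > 7) {
    abort_cg(
      sprintf("Exhaustive enumeration supports 1 to 7 labels, got %d.",
              length(labels)),
      class = "cladegraph_error_size_guard"
    )
  }
  if (anyDuplicated(labels) || anyNA(labels) || any(!nzchar(labels))) {
    abort_cg("Labels must be unique, non-empty and non-missing.",
             class = "cladegraph_error_bad_label")
  }
  labels
}

# All Prüfer sequences of length n-2 over 1..n, as a list of integer vectors.
prufer_sequences <- function(n) {
  if (n == 2) return(list(integer(0)))
  grid <- do.call(expand.grid, rep(list(seq_len(n)), n - 2))
  lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
}

# Standard Prüfer decoding: sequence over 1..n -> adjacency list of the free
# labeled tree on vertices 1..n.
prufer_decode <- function(seq, n) {
  degree <- rep(1L, n)
  for (v in seq) degree[v] <- degree[v] + 1L
  adj <- vector("list", n)
  for (v in seq) {
    leaf <- which(degree == 1L)[1]
    adj[[leaf]] <- c(adj[[leaf]], v)
    adj[[v]] <- c(adj[[v]], leaf)
    degree[leaf] <- degree[leaf] - 1L
    degree[v] <- degree[v] - 1L
  }
  last <- which(degree == 1L)
  adj[[last[1]]] <- c(adj[[last[1]]], last[2])
  adj[[last[2]]] <- c(adj[[last[2]]], last[1])
  adj
}

# Orient a free tree's edges away from `root`; returns parent indices (0 at root).
orient_edges <- function(adj, n, root) {
  parent <- integer(n)
  visited <- logical(n)
  frontier <- root
  visited[root] <- TRUE
  while (length(frontier) > 0) {
    nxt <- integer(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (!visited[w]) {
          visited[w] <- TRUE
          parent[w] <- v
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  parent
}

#' @rdname enumerate_node_trees
#' @export
enumerate_stem_trees <- function(labels) {
  labels <- check_enum_labels(labels)
  n <- length(labels)
  if (n == 1) {
    return(list(new_stem_tree(tibble::tibble(tail = "j0", head = "j1", label = labels))))
  }
  out <- vector("list", n^(n - 1))
  k <- 0L
  jid <- paste0("j", seq_len(n))
  for (root in seq_len(n)) {
    rest <- setdiff(seq_len(n), root)
    grid <- do.call(expand.grid, rep(list(seq_len(n)), n - 1))
    for (i in seq_len(nrow(grid))) {
      p <- as.integer(grid[i, ])  # parent label index of each non-root label
      full <- integer(n)
      full[rest] <- p
      full[root] <- 0L
      if (!parent_map_acyclic(full, root)) next
      k <- k + 1L
      out[[k]] <- new_stem_tree(tibble::tibble(
        tail = c("j0", jid)[full + 1L],
        head = jid,
        label = labels
      ))
    }
  }
  out[seq_len(k)]
}

# full: parent index per vertex, 0 at root; TRUE iff every chain reaches root.
parent_map_acyclic <- function(full, root) {
  n <- length(full)
  for (v in seq_len(n)) {
    u <- v
    steps <- 0L
    while (u != root) {
      u <- full[u]
      steps <- steps + 1L
      if (steps > n) return(FALSE)
    }
  }
  TRUE
}

#' Certify the one-to-one correspondence between the two tree models
#'
#' The central structural fact about the two models is that rooted trees on
#' `n` labeled vertices and planted trees with `n` labeled edges are in
#' one-to-one correspondence, realized by [node_to_stem()] and
#' [stem_to_node()]. `certify_bijection()` verifies this exhaustively for a
#' given label set: both enumerations are generated independently, the
#' conversion is checked to be injective, its image is checked to be exactly
#' the stem enumeration, and both round trips are checked to be identities.
#' Both counts must equal Cayley's closed form `n^(n-1)`.
#'
#' @param n Number of labels (1 to 7); labels used are `"1"..as.character(n)`.
#' @return A `bijection_certificate`: list with fields `n`, `expected`
#'   (`n^(n-1)`), `n_node`, `n_stem`, `injective`, `image_matches`,
#'   `roundtrip_node`, `roundtrip_stem`, `pass`, and `offender` (a Newick
#'   string, only on failure). See [glance.bijection_certificate()].
#' @examples
#' certify_bijection(3)
#' @export
certify_bijection <- function(n) {
  labels <- as.character(seq_len(n))
  node_trees <- enumerate_node_trees(labels)
  stem_trees <- enumerate_stem_trees(labels)
  node_keys <- vapply(node_trees, write_newick, character(1))
  stem_keys <- vapply(stem_trees, write_newick, character(1))
  image <- vapply(node_trees, function(t) write_newick(node_to_stem(t)), character(1))

  offender <- NULL
  injective <- !anyDuplicated(image) && !anyDuplicated(node_keys)
  image_matches <- setequal(image, stem_keys) && !anyDuplicated(stem_keys)

  rt_node <- vapply(seq_along(node_trees), function(i) {
    write_newick(stem_to_node(node_to_stem(node_trees[[i]]))) == node_keys[i]
  }, logical(1))
  roundtrip_node <- all(rt_node)
  if (!roundtrip_node && is.null(offender)) offender <- node_keys[which(!rt_node)[1]]

  rt_stem <- vapply(seq_along(stem_trees), function(i) {
    write_newick(node_to_stem(stem_to_node(stem_trees[[i]]))) == stem_keys[i]
  }, logical(1))
  roundtrip_stem <- all(rt_stem)
  if (!roundtrip_stem && is.null(offender)) offender <- stem_keys[which(!rt_stem)[1]]

  expected <- length(labels)^(length(labels) - 1)
  pass <- injective && image_matches && roundtrip_node && roundtrip_stem &&
    length(node_trees) == expected && length(stem_trees) == expected

  structure(
    list(
      n = n, expected = expected,
      n_node = length(node_trees), n_stem = length(stem_trees),
      injective = injective, image_matches = image_matches,
      roundtrip_node = roundtrip_node, roundtrip_stem = roundtrip_stem,
      pass = pass, offender = offender
    ),
    class = "bijection_certificate"
  )
}

#' @export
print.bijection_certificate <- function(x, ...) {
  cat(sprintf("<bijection_certificate> n = %d: %s\n",
              x$n, if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  rooted node trees: %d | planted stem trees: %d | expected n^(n-1): %d\n",
              x$n_node, x$n_stem, x$expected))
  cat(sprintf("  injective: %s | image matches: %s | round trips: %s/%s\n",
              x$injective, x$image_matches, x$roundtrip_node, x$roundtrip_stem))
  if (!is.null(x$offender)) cat("  offender:", x$offender, "\n")
  invisible(x)
}

#' Certify the subtree correspondence on one tree
#'
#' Over *all* non-empty label subsets of a node tree `T` (host of at most 12
#' taxa), checks that a subset induces a subtree of `T` exactly when the
#' same labels, read as edges of the converted stem tree `U`, induce a
#' *planted* subtree of `U`; and that the proper subtrees of `T` (one per
#' vertex) correspond exactly to the planted proper subtrees of `U`.
#'
#' @param tree A `node_tree` with at most 12 taxa.
#' @return A `subtree_certificate`: list with fields `n_taxa`,
#'   `n_subsets`, `n_subtrees_node` (subsets inducing subtrees of `T`),
#'   `n_planted_stem` (subsets inducing planted subtrees of `U`),
#'   `n_agree`, `n_proper` (count of proper subtrees, which must equal
#'   `n_taxa`), `pass`.
#' @examples
#' certify_subtree_correspondence(fig3_tree("node"))
#' @export
certify_subtree_correspondence <- function(tree) {
  if (!is_node_tree(tree)) {
    abort_cg("`tree` must be a node_tree.", class = "cladegraph_error_bad_argument")
  }
  n <- nrow(tree)
  if (n > 12) {
    abort_cg(
      sprintf("Subset enumeration supports at most 12 taxa, got %d.", n),
      class = "cladegraph_error_size_guard"
    )
  }
  labels <- tree$label
  stem <- node_to_stem(tree)
  pm <- nt_parents(tree)
  tails <- stats::setNames(stem$tail, stem$label)
  heads <- stats::setNames(stem$head, stem$label)
  jdepth <- st_junction_depths(stem)

  proper_sets <- lapply(labels, function(v) sort(c(v, taxon_descendants(tree, v)),
                                                 method = "radix"))
  proper_keys <- vapply(proper_sets, paste, character(1), collapse = "\x1f")

  n_subsets <- as.integer(2^n - 1)
  n_node_sub <- 0L; n_planted <- 0L; n_agree <- 0L; n_proper_planted <- 0L
  for (mask in seq_len(n_subsets)) {
    members <- labels[bitwAnd(mask, bitwShiftL(1L, seq_len(n) - 1L)) != 0L]
    node_ok <- nt_is_subtree_impl(pm, members)
    st <- st_is_subtree_impl(tails, heads, jdepth, members)
    planted_ok <- st[1] && st[2]
    if (node_ok) n_node_sub <- n_node_sub + 1L
    if (planted_ok) n_planted <- n_planted + 1L
    if (node_ok == planted_ok) n_agree <- n_agree + 1L
    if (planted_ok &&
        paste(sort(members, method = "radix"), collapse = "\x1f") %in% proper_keys) {
      n_proper_planted <- n_proper_planted + 1L
    }
  }
  # proper subtrees of T are planted proper subtrees of U, and there are
  # exactly as many of them as vertices
  n_proper <- length(unique(proper_keys))
  pass <- (n_agree == n_subsets) && (n_node_sub == n_planted) &&
    (n_proper == n) && (n_proper_planted == n)
  structure(
    list(
      n_taxa = n, n_subsets = n_subsets,
      n_subtrees_node = n_node_sub, n_planted_stem = n_planted,
      n_agree = n_agree, n_proper = n_proper, pass = pass
    ),
    class = "subtree_certificate"
  )
}

#' @export
print.subtree_certificate <- function(x, ...) {
  cat(sprintf("<subtree_certificate> %d taxa, %d subsets: %s\n",
              x$n_taxa, x$n_subsets, if (x$pass) "PASS" else "FAIL"))
  cat(sprintf("  subtrees of T: %d | planted subtrees of U: %d | agreement: %d/%d\n",
              x$n_subtrees_node, x$n_planted_stem, x$n_agree, x$n_subsets))
  cat(sprintf("  proper subtrees: %d (= taxa: %s)\n",
              x$n_proper, x$n_proper == x$n_taxa))
  invisible(x)
}
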