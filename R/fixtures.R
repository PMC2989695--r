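#' Built-in example trees
#'
#' Two small phylogenies used throughout the documentation and tests, each
#' available in both models (the stem form is the exact conversion image of
#' the node form). Copies are also shipped as Newick files under
#' `inst/extdata/`.
#'
#' `fig1_tree()` is the five-taxon introductory example: sampled taxa `A`,
#' `B`, `C` and their unsampled-but-inferred ancestors `y` (of `B` and `C`)
#' and `z` (of everything). `fig1_annotations()` attaches seven apomorphy
#' marks to it; the per-taxon placements other than `B:{3,4,5}` and
#' `y:{1,2}` are a synthetic reconstruction chosen to be consistent with the
#' worked character discussion, not copied from any dataset.
#'
#' `fig3_tree()` is the nine-taxon tree on labels `1`..`9` (root `1`;
#' children of `1` are `2`,`3`; of `2` are `4`,`5`; of `3` are `6`,`7`; of
#' `4` are `8`,`9`) on which every classical subtree and monophyly contrast
#' can be exhibited: `{4,5,8,9}` is a subtree of the stem form but not of
#' the node form and is polyphyletic; `{2,4,5,8,9}` is a subtree of both
#' (planted in the stem form) and monophyletic; `{1,3,6,7}` is paraphyletic.
#'
#' @param model `"node"` or `"stem"`.
#' @return A `node_tree` or `stem_tree`; `fig1_annotations()` returns an
#'   [annotation_map].
#' @export
fig1_tree <- function(model = c("node", "stem")) {
  model <- rlang::arg_match(model)
  t <- node_tree(c(A = "z", B = "y", C = "y", y = "z", z = NA))
  if (model == "node") t else node_to_stem(t)
}

#' @rdname fig1_tree
#' @export
fig3_tree <- function(model = c("node", "stem")) {
  model <- rlang::arg_match(model)
  t <- node_tree(c(
    "1" = NA, "2" = "1", "3" = "1", "4" = "2", "5" = "2",
    "6" = "3", "7" = "3", "8" = "4", "9" = "4"
  ))
  if (model == "node") t else node_to_stem(t)
}

#' @rdname fig1_tree
#' @export
fig1_annotations <- function() {
  annotation_map(tibble::tibble(
    taxon = c("B", "B", "B", "y", "y", "A", "C"),
    character = c("3", "4", "5", "1", "2", "6", "7")
  ))
}

#' Seeded random rooted labeled trees
#'
#' Draws a rooted labeled tree uniformly at random: a uniform Prüfer
#' sequence determines the free labeled tree (the Prüfer code is a bijection,
#' so free trees are uniform) and an independently uniform vertex becomes the
#' root, making all `n^(n-1)` rooted labeled trees equally likely. With
#' `model = "stem"` the draw is converted, under which uniformity is
#' preserved because the conversion is a bijection.
#'
#' @param n Number of taxa (`n >= 1`).
#' @param seed Optional integer; when supplied the draw is deterministic and
#'   the caller's RNG state is left untouched.
#' @param model `"node"` or `"stem"`.
#' @param labels Optional character vector of `n` unique labels; defaults to
#'   `"t1".."tn"`.
#' @return A `node_tree` or `stem_tree` with `n` taxa.
#' @examples
#' random_tree(6, seed = 1)
#' tree_equal(random_tree(6, seed = 1), random_tree(6, seed = 1))
#' @export
random_tree <- function(n, seed = NULL, model = c("node", "stem"), labels = NULL) {
  model <- rlang::arg_match(model)
  if (!rlang::is_scalar_integerish(n) || n < 1) {
    abort_cg("`n` must be a positive integer.",
             class = "cladegraph_error_bad_argument")
  }
  n <- as.integer(n)
  labels <- labels %||% paste0("t", seq_len(n))
  labels <- as.character(labels)
  if (length(labels) != n || anyDuplicated(labels)) {
    abort_cg("`labels` must supply `n` unique labels.",
             class = "cladegraph_error_bad_label")
  }
  draw <- function() {
    if (n == 1) {
      new_node_tree(tibble::tibble(label = labels, parent = NA_character_))
    } else {
      code <- if (n == 2) integer(0) else sample.int(n, n - 2, replace = TRUE)
      adj <- prufer_decode(code, n)
      root <- sample.int(n, 1)
      parent_idx <- orient_edges(adj, n, root)
      new_node_tree(tibble::tibble(
        label = labels,
        parent = c(NA_character_, labels)[parent_idx + 1L]
      ))
    }
  }
  t <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())
  if (model == "node") t else node_to_stem(t)
}
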