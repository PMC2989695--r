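test_that("construction validates the rooted-tree invariants", {
  expect_s3_class(node_tree(c(a = NA)), "node_tree")
  expect_error(node_tree(tibble::tibble(label = character(), parent = character())),
               class = "cladegraph_error_empty_tree")
  expect_error(node_tree(c(a = NA, b = NA)), class = "cladegraph_error_bad_root")
  expect_error(node_tree(c(a = "b", b = "a")), class = "cladegraph_error_bad_root")
  expect_error(node_tree(tibble::tibble(label = c("a", "a"), parent = c(NA, "a"))),
               class = "cladegraph_error_duplicate_label")
  expect_error(node_tree(c(a = NA, b = "zz")),
               class = "cladegraph_error_label_not_found")
  # cycle hanging off a rooted component
  expect_error(node_tree(c(a = NA, b = "c", c = "b")),
               class = "cladegraph_error_not_a_tree")
})

test_that("vertex count exceeds edge count by one on assorted trees", {
  trees <- list(
    fig1_tree("node"), fig3_tree("node"),
    chain_tree(letters[1:6]), star_tree("r", c("a", "b", "c")),
    node_tree(c(only = NA))
  )
  for (t in trees) expect_valid_tree(t)
})

test_that("parent, ancestors and lineage follow the ancestry chain", {
  t3 <- fig3_tree("node")
  expect_identical(taxon_parent(t3, "8"), "4")
  expect_identical(taxon_parent(t3, "1"), NA_character_)
  expect_identical(taxon_ancestors(t3, "8"), c("4", "2", "1"))
  expect_identical(taxon_ancestors(t3, "1"), character(0))
  expect_identical(taxon_lineage(t3, "8", top = "1"), c("4", "2", "1"))
  expect_identical(taxon_lineage(t3, "8", top = "4"), "4")
  expect_identical(taxon_lineage(t3, "2"), "1")  # child of root, default top
  expect_error(taxon_lineage(t3, "8", top = "3"),
               class = "cladegraph_error_not_an_ancestor")
  expect_error(taxon_parent(t3, "99"), class = "cladegraph_error_label_not_found")

  t1 <- fig1_tree("node")
  expect_identical(taxon_parent(t1, "B"), "y")
  expect_identical(taxon_ancestors(t1, "C"), c("y", "z"))
})

test_that("a taxon is never its own ancestor", {
  for (seed in 1:25) {
    t <- random_tree(12, seed = seed)
    for (v in taxa(t)) expect_false(v %in% taxon_ancestors(t, v))
  }
})

test_that("youngest common ancestor matches examples and the brute-force oracle", {
  t3 <- fig3_tree("node")
  expect_identical(yca(t3, c("8", "9")), "4")
  expect_identical(yca(t3, "5"), "5")  # a vertex is its own YCA
  expect_identical(yca(t3, c("4", "5", "8", "9")), "2")
  expect_error(yca(t3, character(0)), class = "cladegraph_error_empty_query")

  for (seed in 1:10) {
    t <- random_tree(9, seed = seed)
    withr::with_seed(seed + 100, {
      for (k in 1:5) {
        s <- sample(taxa(t), sample(1:4, 1))
        expect_identical(yca(t, s), brute_yca(t, s))
      }
    })
  }
})

test_that("yca is on every member's ancestor-or-self chain", {
  for (seed in 1:10) {
    t <- random_tree(10, seed = seed)
    pair <- withr::with_seed(seed, sample(taxa(t), 2))
    a <- yca(t, pair)
    for (v in pair) expect_true(a %in% c(v, taxon_ancestors(t, v)))
  }
})

test_that("descendants inverts the ancestor relation", {
  t3 <- fig3_tree("node")
  expect_setequal(taxon_descendants(t3, "2"), c("4", "5", "8", "9"))
  expect_identical(taxon_descendants(t3, "9"), character(0))
  expect_setequal(taxon_descendants(t3, "1"), setdiff(taxa(t3), "1"))
  t <- random_tree(15, seed = 3)
  for (v in taxa(t)) {
    for (d in taxon_descendants(t, v)) {
      expect_true(v %in% taxon_ancestors(t, d))
    }
  }
})

test_that("proper subtrees are vertex-plus-descendants and one exists per vertex", {
  t3 <- fig3_tree("node")
  ref <- proper_subtree(t3, "2")
  expect_s3_class(ref, "subtree_ref")
  expect_setequal(ref$elements, c("2", "4", "5", "8", "9"))
  expect_identical(proper_subtree(t3, "9")$elements, "9")
  expect_setequal(proper_subtree(t3, "1")$elements, taxa(t3))

  # count sweep: exactly as many distinct proper subtrees as vertices
  for (seed in 1:100) {
    t <- random_tree((seed * 7L) %% 12L + 1L, seed = seed)
    keys <- vapply(taxa(t), function(v)
      paste(sort(proper_subtree(t, v)$elements), collapse = "|"), character(1))
    expect_identical(length(unique(keys)), n_taxa(t))
  }
})

test_that("is_subtree matches the figure claims and an independent connectivity oracle", {
  t3 <- fig3_tree("node")
  expect_false(is_subtree(t3, c("4", "5", "8", "9")))
  expect_true(is_subtree(t3, c("2", "4", "5", "8", "9")))
  expect_true(is_subtree(t3, "6"))

  # exhaustive agreement with igraph connectivity on all subsets, several trees
  trees <- c(list(t3, chain_tree(letters[1:5]), star_tree("r", c("a", "b", "c"))),
             lapply(1:5, function(s) random_tree(7, seed = s)))
  for (t in trees) {
    for (s in all_subsets(taxa(t))) {
      expect_identical(is_subtree(t, s), igraph_is_subtree(t, s))
    }
  }
})
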