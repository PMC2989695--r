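test_that("one string, two readings: node and stem modes of the same Newick", {
  t <- parse_newick("(A,(B,C)y)z;", mode = "node")
  expect_s3_class(t, "node_tree")
  expect_identical(root_label(t), "z")
  expect_identical(taxon_parent(t, "C"), "y")

  u <- parse_newick("(A,(B,C)y)z;", mode = "stem")
  expect_s3_class(u, "stem_tree")
  expect_identical(root_label(u), "z")
  # the stem reading equals the conversion image of the node reading
  expect_true(tree_equal(u, node_to_stem(t)))

  expect_identical(n_taxa(parse_newick("A;", mode = "node")), 1L)
  expect_identical(n_taxa(parse_newick("A;", mode = "stem")), 1L)
})

test_that("serialization is canonical, deterministic and mode-symmetric", {
  expect_identical(write_newick(fig1_tree("node")), "(A,(B,C)y)z;")
  # child order input does not matter
  t_rev <- parse_newick("((C,B)y,A)z;", mode = "node")
  expect_identical(write_newick(t_rev), "(A,(B,C)y)z;")
  expect_identical(
    write_newick(node_tree(c("1" = NA))), "1;"
  )
  single_stem <- stem_tree(tibble::tibble(tail = "r", head = "s", label = "1"))
  expect_identical(write_newick(single_stem), "1;")

  # write(node_to_stem(T), stem) == write(T, node), character-identical
  for (seed in 1:25) {
    t <- random_tree((seed %% 16) + 1, seed = seed)
    expect_identical(write_newick(t), write_newick(node_to_stem(t)))
  }
})

test_that("read-write round trips are bit-exact", {
  for (seed in 1:100) {
    t <- random_tree((seed %% 32) + 1, seed = seed)
    nwk <- write_newick(t)
    expect_identical(write_newick(parse_newick(nwk, mode = "node")), nwk)
    expect_identical(write_newick(parse_newick(nwk, mode = "stem")), nwk)
  }
})

test_that("quoted labels survive a round trip", {
  t <- node_tree(c("Homo sapiens" = "anc (x)", "Pan'y" = "anc (x)",
                   "anc (x)" = NA))
  nwk <- write_newick(t)
  expect_true(tree_equal(parse_newick(nwk, mode = "node"), t))
})

test_that("syntax errors report a position; lengths and supports are rejected", {
  err <- expect_error(parse_newick("(A,B;", mode = "node"),
                      class = "cladegraph_error_parse")
  expect_match(conditionMessage(err), "position")
  expect_error(parse_newick("(A:0.1,B)r;", mode = "node"),
               class = "cladegraph_error_parse")
  expect_error(parse_newick("(A,B)r:12;", mode = "node"),
               class = "cladegraph_error_parse")
  expect_error(parse_newick("(A,B)r[comment];", mode = "node"),
               class = "cladegraph_error_parse")
  expect_error(parse_newick("(A,B)r", mode = "node"),
               class = "cladegraph_error_parse")
  expect_error(parse_newick("", mode = "node"),
               class = "cladegraph_error_parse")
  # missing internal label in node mode
  expect_error(parse_newick("(A,B);", mode = "node"),
               class = "cladegraph_error_parse")
  # unlabeled top with two children cannot be planted in stem mode
  expect_error(parse_newick("(A,B);", mode = "stem"),
               class = "cladegraph_error_not_planted")
  # but a single unlabeled wrap is just the implicit root junction
  expect_true(tree_equal(parse_newick("((B,C)A);", mode = "stem"),
                         parse_newick("(B,C)A;", mode = "stem")))
  # duplicate labels
  expect_error(parse_newick("(A,A)r;", mode = "node"),
               class = "cladegraph_error_duplicate_label")
})

test_that("the parser agrees with ape on standard multi-tip trees", {
  for (seed in 1:10) {
    t <- random_tree(9, seed = seed)
    nwk <- write_newick(t)
    at <- ape::read.tree(text = nwk)
    # same leaf set
    td <- tidy(t)
    expect_setequal(at$tip.label, td$label[td$is_leaf])
    # same parent relation on leaves: ape parent node label vs ours
    all_lab <- c(at$tip.label, at$node.label)
    for (tip in at$tip.label) {
      tip_idx <- match(tip, at$tip.label)
      par_idx <- at$edge[at$edge[, 2] == tip_idx, 1]
      expect_identical(all_lab[par_idx], taxon_parent(t, tip))
    }
  }
})

test_that("file I/O reproduces the shipped fixtures", {
  fig3_path <- system.file("extdata", "fig3.nwk", package = "cladegraph")
  t <- read_newick(fig3_path, mode = "node")
  expect_true(tree_equal(t, fig3_tree("node")))
  u <- read_newick(fig3_path, mode = "stem")
  expect_true(tree_equal(u, fig3_tree("stem")))

  tmp <- withr::local_tempfile(fileext = ".nwk")
  write_newick_file(t, tmp)
  expect_identical(readLines(tmp), write_newick(t))
  expect_error(read_newick(file.path(tempdir(), "no-such-file.nwk"), "node"),
               class = "cladegraph_error_file_not_found")
})
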