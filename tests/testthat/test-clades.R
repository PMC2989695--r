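test_that("clades anchored on either model give the same taxon sets", {
  t3 <- fig3_tree("node")
  u3 <- fig3_tree("stem")
  expect_identical(clade(t3, "2"), c("2", "4", "5", "8", "9"))
  expect_identical(clade(u3, "2"), c("2", "4", "5", "8", "9"))
  expect_identical(clade(t3, "9"), "9")
  expect_identical(clade(t3, "1"), sort(taxa(t3)))

  # synonymy across all anchors on random phylogenies
  for (seed in 1:50) {
    t <- random_tree(10, seed = seed)
    u <- node_to_stem(t)
    for (v in taxa(t)) expect_identical(clade(t, v), clade(u, v))
  }
})

test_that("every clade classifies as monophyletic", {
  for (seed in 1:20) {
    t <- random_tree(9, seed = seed)
    u <- node_to_stem(t)
    for (v in taxa(t)) {
      expect_identical(classify_clade(t, clade(t, v)), "monophyletic")
      expect_identical(classify_clade(u, clade(u, v)), "monophyletic")
    }
  }
})

test_that("classification reproduces the figure verdicts", {
  t3 <- fig3_tree("node")
  expect_identical(classify_clade(t3, c("4", "5", "8", "9")), "polyphyletic")
  expect_identical(classify_clade(t3, c("1", "3", "6", "7")), "paraphyletic")
  expect_identical(classify_clade(t3, c("2", "4", "5", "8", "9")), "monophyletic")
  # same verdicts straight from the stem model
  u3 <- fig3_tree("stem")
  expect_identical(classify_clade(u3, c("4", "5", "8", "9")), "polyphyletic")
  expect_identical(classify_clade(u3, c("1", "3", "6", "7")), "paraphyletic")
  expect_identical(classify_clade(u3, sort(taxa(u3))), "monophyletic")
})

test_that("single taxa: terminal is monophyletic, internal is paraphyletic", {
  t3 <- fig3_tree("node")
  expect_identical(classify_clade(t3, "9"), "monophyletic")
  expect_identical(classify_clade(t3, "4"), "paraphyletic")
  expect_error(classify_clade(t3, character(0)),
               class = "cladegraph_error_empty_query")
  expect_error(classify_clade(t3, "nope"),
               class = "cladegraph_error_label_not_found")
})

test_that("classification is model-independent on random phylogenies", {
  for (seed in 1:50) {
    t <- random_tree(12, seed = seed)
    u <- node_to_stem(t)
    subsets <- withr::with_seed(seed, {
      lapply(1:10, function(i) sample(taxa(t), sample(1:6, 1)))
    })
    for (s in subsets) {
      expect_identical(classify_clade(t, s), classify_clade(u, s))
    }
  }
})

test_that("polyphyly is exactly exclusion of the set's own YCA", {
  t3 <- fig3_tree("node")
  for (s in all_subsets(taxa(t3))) {
    cls <- classify_clade(t3, s)
    a <- yca(t3, s)
    expect_identical(cls == "polyphyletic", !(a %in% s))
    if (cls == "monophyletic") {
      expect_setequal(s, c(a, taxon_descendants(t3, a)))
    }
    if (cls == "paraphyletic") {
      expect_true(a %in% s)
      expect_gt(length(setdiff(c(a, taxon_descendants(t3, a)), s)), 0)
    }
  }
})

test_that("clade-name sets are in bijection across models for small trees", {
  for (n in 2:5) {
    for (t in enumerate_node_trees(as.character(seq_len(n)))) {
      u <- node_to_stem(t)
      node_names <- sort(vapply(taxa(t), function(v)
        paste(clade(t, v), collapse = "|"), character(1)))
      stem_names <- sort(vapply(taxa(u), function(e)
        paste(clade(u, e), collapse = "|"), character(1)))
      expect_identical(unname(node_names), unname(stem_names))
    }
  }
})

test_that("misapplied definitions are diagnosed with the demonstration", {
  u3 <- fig3_tree("stem")
  rep1 <- diagnose_misapplication(u3, "node", anchor = "2")
  expect_true(rep1$misapplied)
  expect_identical(rep1$selected, c("4", "5", "8", "9"))
  expect_identical(rep1$classification, "polyphyletic")

  t3 <- fig3_tree("node")
  rep2 <- diagnose_misapplication(t3, "stem", anchor = "3")
  expect_true(rep2$misapplied)
  expect_match(rep2$message, "both endpoints")
  expect_identical(rep2$selected, c("3", "6", "7"))
  expect_identical(rep2$classification, "monophyletic")

  # matching model: empty report
  rep3 <- diagnose_misapplication(t3, "node")
  expect_false(rep3$misapplied)
  expect_identical(rep3$selected, character(0))

  # terminal-edge anchor on a stem tree selects nothing
  rep4 <- diagnose_misapplication(u3, "node", anchor = "9")
  expect_true(rep4$misapplied)
  expect_identical(rep4$selected, character(0))
})
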