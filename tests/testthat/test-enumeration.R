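# Independent count oracle: rooted labeled trees by brute force over parent
# maps (every root choice x every parent function, acyclicity-filtered).
brute_count_rooted <- function(n) {
  if (n == 1) return(1L)
  count <- 0L
  for (root in seq_len(n)) {
    rest <- setdiff(seq_len(n), root)
    grid <- do.call(expand.grid, rep(list(seq_len(n)), n - 1))
    for (i in seq_len(nrow(grid))) {
      p <- as.integer(grid[i, ])
      full <- integer(n); full[rest] <- p; full[root] <- 0L
      ok <- TRUE
      for (v in seq_len(n)) {
        u <- v; steps <- 0L
        while (u != root) {
          u <- full[u]; steps <- steps + 1L
          if (steps > n) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (ok) count <- count + 1L
    }
  }
  count
}

# The dedup-style stem enumeration: all planted junction structures on n+1
# junctions x all edge labelings, deduplicated by canonical serialization.
dedup_stem_count <- function(labels) {
  n <- length(labels)
  if (n == 1) return(1L)
  junctions <- paste0("J", seq_len(n))
  keys <- character(0)
  for (root in seq_len(n)) {
    rest <- setdiff(seq_len(n), root)
    grid <- do.call(expand.grid, rep(list(seq_len(n)), n - 1))
    for (i in seq_len(nrow(grid))) {
      p <- as.integer(grid[i, ])
      full <- integer(n); full[rest] <- p; full[root] <- 0L
      ok <- TRUE
      for (v in seq_len(n)) {
        u <- v; steps <- 0L
        while (u != root) {
          u <- full[u]; steps <- steps + 1L
          if (steps > n) { ok <- FALSE; break }
        }
        if (!ok) break
      }
      if (!ok) next
      perms <- permute_all(seq_len(n))
      for (perm in perms) {
        u <- stem_tree(tibble::tibble(
          tail = c("J0", junctions)[full + 1L],
          head = junctions,
          label = labels[perm]
        ))
        keys <- c(keys, write_newick(u))
      }
    }
  }
  length(unique(keys))
}

permute_all <- function(x) {
  if (length(x) == 1) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permute_all(x[-i])) out[[length(out) + 1L]] <- c(x[i], rest)
  }
  out
}

test_that("node-tree enumeration matches Cayley's closed form and brute force", {
  for (n in 1:4) {
    trees <- enumerate_node_trees(as.character(seq_len(n)))
    expect_identical(length(trees), as.integer(n^(n - 1)))
    keys <- vapply(trees, write_newick, character(1))
    expect_identical(anyDuplicated(keys), 0L)
    expect_identical(length(trees), brute_count_rooted(n))
  }
})

test_that("stem-tree enumeration agrees with the junction-relabeling dedup oracle", {
  for (n in 1:4) {
    labels <- letters[seq_len(n)]
    trees <- enumerate_stem_trees(labels)
    keys <- vapply(trees, write_newick, character(1))
    expect_identical(anyDuplicated(keys), 0L)
    expect_identical(length(trees), dedup_stem_count(labels))
    for (u in trees) expect_valid_tree(u)
  }
})

test_that("size guards reject out-of-range enumeration requests", {
  expect_error(enumerate_node_trees(as.character(1:8)),
               class = "cladegraph_error_size_guard")
  expect_error(enumerate_node_trees(character(0)),
               class = "cladegraph_error_size_guard")
  expect_error(enumerate_stem_trees(as.character(1:8)),
               class = "cladegraph_error_size_guard")
  expect_error(certify_subtree_correspondence(random_tree(13, seed = 1)),
               class = "cladegraph_error_size_guard")
})

test_that("the model bijection certifies on small label sets", {
  c1 <- certify_bijection(1)
  expect_true(c1$pass)
  expect_identical(c1$n_node, 1L)

  c3 <- certify_bijection(3)
  expect_true(c3$pass)
  expect_identical(c3$n_node, 9L)
  expect_identical(c3$n_stem, 9L)
  expect_true(c3$injective)
  expect_true(c3$image_matches)

  g <- glance(c3)
  expect_s3_class(g, "tbl_df")
  expect_true(g$pass)
})

test_that("subtree correspondence certifies on the figure fixture and random trees", {
  cert <- certify_subtree_correspondence(fig3_tree("node"))
  expect_true(cert$pass)
  expect_identical(cert$n_agree, cert$n_subsets)
  expect_identical(cert$n_proper, 9L)  # as many proper subtrees as vertices

  single <- certify_subtree_correspondence(node_tree(c(a = NA)))
  expect_true(single$pass)

  for (seed in 1:25) {
    cert <- certify_subtree_correspondence(random_tree((seed %% 10) + 1, seed = seed))
    expect_true(cert$pass)
  }
})
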