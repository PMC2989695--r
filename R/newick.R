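#' Read and write Newick, under an explicit model interpretation
#'
#' The same Newick string can encode either tree model; which one is meant is
#' never guessable from the text, so the interpretation `mode` is always an
#' explicit argument. In **node** mode every parenthesized group and every
#' leaf token names a *vertex* (a taxon), so every token — internal and root
#' included — must carry a label. In **stem** mode every token's label names
#' the *edge above it* (its parent edge), the implicit topmost junction is
#' unlabeled, and the outermost label becomes the planted root edge. One
#' grammar, two readings: `"(A,(B,C)y)z;"` is a five-vertex node tree or a
#' five-edge stem tree, and the two are exactly each other's image under
#' [node_to_stem()] / [stem_to_node()].
#'
#' The dialect is deliberately strict: labels are mandatory, branch lengths
#' and support values are rejected (a bare number in label position is
#' ambiguous between a label and a support value, so `:` and bracket
#' comments are hard errors with a reported position), labels containing
#' special characters must be single-quoted with `''` escaping doubled
#' quotes, and the trailing semicolon is required.
#'
#' `write_newick()` emits a canonical serialization: children are ordered by
#' the lexicographically smallest label in their subtree (a deterministic,
#' locale-independent byte order), so `parse_newick(write_newick(x), mode)`
#' reproduces `x` exactly, and the node and stem serializations of
#' corresponding trees are character-identical.
#'
#' @param text A Newick string (trailing `;` required).
#' @param file Path to a file containing one Newick string.
#' @param mode `"node"` or `"stem"`: how to interpret the labels.
#' @param tree A `node_tree` or `stem_tree`.
#' @return `parse_newick()`/`read_newick()`: a `node_tree` or `stem_tree`;
#'   `write_newick()`: a single string; `write_newick_file()`: the input
#'   tree, invisibly.
#' @examples
#' parse_newick("(A,(B,C)y)z;", mode = "node")
#' parse_newick("(A,(B,C)y)z;", mode = "stem")
#' write_newick(fig3_tree("node"))
#' @export
parse_newick <- function(text, mode = c("node", "stem")) {
  mode <- rlang::arg_match(mode)
  check_string(text, "text")
  ast <- newick_ast(text)
  if (mode == "node") newick_to_node(ast) else newick_to_stem(ast)
}

#' @rdname parse_newick
#' @export
read_newick <- function(file, mode = c("node", "stem")) {
  mode <- rlang::arg_match(mode)
  check_string(file, "file")
  if (!file.exists(file)) {
    abort_cg(sprintf("File not found: '%s'", file),
             class = "cladegraph_error_file_not_found")
  }
  text <- paste(readLines(file, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  parse_newick(text, mode = mode)
}

newick_syntax_error <- function(msg, pos) {
  abort_cg(sprintf("Newick syntax error at position %d: %s", pos, msg),
           class = "cladegraph_error_parse", position = pos)
}

# Recursive-descent parse into an AST of list(label, pos, children).
newick_ast <- function(text) {
  chars <- strsplit(text, "", fixed = TRUE)[[1]]
  n <- length(chars)
  i <- 1L

  peek <- function() if (i <= n) chars[[i]] else ""
  skip_ws <- function() {
    while (i <= n && chars[[i]] %in% c(" ", "\t", "\n", "\r")) i <<- i + 1L
  }
  specials <- c("(", ")", ",", ";", ":", "'", "[", "]",
                " ", "\t", "\n", "\r")

  parse_label <- function() {
    skip_ws()
    start <- i
    if (peek() == "'") {
      i <<- i + 1L
      out <- character(0)
      repeat {
        if (i > n) newick_syntax_error("unterminated quoted label", start)
        ch <- chars[[i]]
        if (ch == "'") {
          if (i + 1L <= n && chars[[i + 1L]] == "'") {
            out <- c(out, "'"); i <<- i + 2L
          } else {
            i <<- i + 1L; break
          }
        } else {
          out <- c(out, ch); i <<- i + 1L
        }
      }
      label <- paste(out, collapse = "")
      if (!nzchar(label)) newick_syntax_error("empty quoted label", start)
    } else {
      out <- character(0)
      while (i <= n && !(chars[[i]] %in% specials)) {
        out <- c(out, chars[[i]]); i <<- i + 1L
      }
      label <- paste(out, collapse = "")
    }
    skip_ws()
    if (peek() == ":") {
      newick_syntax_error(
        "branch lengths / support values are not supported in this dialect", i)
    }
    if (peek() == "[") {
      newick_syntax_error("bracket comments are not supported", i)
    }
    list(label = label, pos = start)
  }

  parse_subtree <- function() {
    skip_ws()
    start <- i
    if (peek() == "(") {
      i <<- i + 1L
      children <- list(parse_subtree())
      skip_ws()
      while (peek() == ",") {
        i <<- i + 1L
        children[[length(children) + 1L]] <- parse_subtree()
        skip_ws()
      }
      if (peek() != ")") newick_syntax_error("expected ',' or ')'", i)
      i <<- i + 1L
      lab <- parse_label()
      list(label = lab$label, pos = lab$pos, children = children)
    } else {
      lab <- parse_label()
      if (!nzchar(lab$label)) newick_syntax_error("expected a label or '('", start)
      list(label = lab$label, pos = lab$pos, children = list())
    }
  }

  skip_ws()
  if (i > n) newick_syntax_error("empty input", 1L)
  root <- parse_subtree()
  skip_ws()
  if (peek() != ";") newick_syntax_error("expected terminating ';'", i)
  i <- i + 1L
  skip_ws()
  if (i <= n) newick_syntax_error("trailing content after ';'", i)
  root
}

newick_to_node <- function(ast) {
  labels <- character(0)
  parents <- character(0)
  walk <- function(node, parent) {
    if (!nzchar(node$label)) {
      newick_syntax_error(
        "node-mode input requires a label on every vertex (internal and root included)",
        node$pos)
    }
    labels <<- c(labels, node$label)
    parents <<- c(parents, parent)
    for (ch in node$children) walk(ch, node$label)
  }
  walk(ast, NA_character_)
  node_tree(tibble::tibble(label = labels, parent = parents))
}

newick_to_stem <- function(ast) {
  # The implicit topmost junction is unlabeled. An unlabeled outermost token
  # exposes that junction: with one child we unwrap; with several the tree
  # would not be planted.
  if (!nzchar(ast$label)) {
    if (length(ast$children) == 1L) {
      ast <- ast$children[[1L]]
    } else {
      abort_cg(
        "Not a planted stem tree: the topmost junction has more than one child edge.",
        class = "cladegraph_error_not_planted"
      )
    }
  }
  counter <- 0L
  new_junction <- function() {
    counter <<- counter + 1L
    sprintf("j%d", counter)
  }
  tails <- character(0); heads <- character(0); labs <- character(0)
  walk <- function(node, tail_junction) {
    if (!nzchar(node$label)) {
      newick_syntax_error(
        "stem-mode input requires a label (the parent-edge taxon) on every token",
        node$pos)
    }
    head_junction <- new_junction()
    tails <<- c(tails, tail_junction)
    heads <<- c(heads, head_junction)
    labs <<- c(labs, node$label)
    for (ch in node$children) walk(ch, head_junction)
  }
  root_junction <- "j0"
  walk(ast, root_junction)
  stem_tree(tibble::tibble(tail = tails, head = heads, label = labs))
}

#' @rdname parse_newick
#' @export
write_newick <- function(tree) {
  UseMethod("write_newick")
}

#' @export
write_newick.node_tree <- function(tree) {
  kids <- nt_children(tree)
  paste0(newick_render(root_label(tree), kids)$str, ";")
}

#' @export
write_newick.stem_tree <- function(tree) {
  kids <- st_edge_children(tree)
  paste0(newick_render(root_label(tree), kids)$str, ";")
}

# Shared canonical renderer over a label + children-map view of either model.
# Children are ordered by the smallest label in their subtree (byte order),
# which totally orders disjoint sibling subtrees.
newick_render <- function(label, kids) {
  children <- kids[[label]]
  if (is.null(children) || length(children) == 0) {
    return(list(str = escape_newick_label(label), min = label))
  }
  rendered <- lapply(children, newick_render, kids = kids)
  mins <- vapply(rendered, function(r) r$min, character(1))
  ord <- order(mins, method = "radix")
  strs <- vapply(rendered[ord], function(r) r$str, character(1))
  list(
    str = paste0("(", paste(strs, collapse = ","), ")", escape_newick_label(label)),
    min = sort(c(label, mins), method = "radix")[1]
  )
}

escape_newick_label <- function(label) {
  if (grepl("^[A-Za-z0-9_.+|-]+$", label)) {
    label
  } else {
    paste0("'", gsub("'", "''", label, fixed = TRUE), "'")
  }
}

#' @rdname parse_newick
#' @export
write_newick_file <- function(tree, file) {
  writeLines(write_newick(tree), file, useBytes = TRUE)
  invisible(tree)
}

#' Tree equality up to canonical form
#'
#' Two trees of the same model are equal when their canonical Newick
#' serializations coincide; for stem trees this compares structure up to
#' junction renaming, which is the right notion of equality because junction
#' identifiers carry no biological meaning.
#'
#' @param a,b Two trees of the same model.
#' @return `TRUE` or `FALSE`.
#' @export
tree_equal <- function(a, b) {
  if (is_node_tree(a) != is_node_tree(b) || is_stem_tree(a) != is_stem_tree(b)) {
    return(FALSE)
  }
  identical(write_newick(a), write_newick(b))
}
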