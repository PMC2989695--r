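# Internal error helpers. All conditions carry a "cladegraph_error" class plus
# a specific subclass so callers (and tests) can distinguish failure modes.

abort_cg <- function(message, class, ...) {
  rlang::abort(message, class = c(class, "cladegraph_error"), ...)
}

stop_label_not_found <- function(labels, tree_kind) {
  abort_cg(
    sprintf(
      "Label%s not found in %s tree: %s",
      if (length(labels) > 1) "s" else "", tree_kind,
      paste0("'", labels, "'", collapse = ", ")
    ),
    class = "cladegraph_error_label_not_found",
    labels = labels
  )
}

check_labels_exist <- function(tree, labels, tree_kind) {
  missing <- setdiff(labels, tree$label)
  if (length(missing) > 0) stop_label_not_found(missing, tree_kind)
  invisible(labels)
}

check_string <- function(x, arg) {
  if (!rlang::is_string(x)) {
    abort_cg(sprintf("`%s` must be a single string.", arg),
             class = "cladegraph_error_bad_argument")
  }
  x
}

`%||%` <- rlang::`%||%`
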