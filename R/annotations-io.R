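#' Read and write character-annotation tables
#'
#' Annotation files are two-column, tab-separated text: the taxon label,
#' then a comma-separated list of character identifiers fixed in that
#' taxon's lineage. A taxon may appear on several lines; its character
#' multisets are merged. An empty file is a valid empty map. Malformed lines
#' are reported with their line number. Validation against a tree happens at
#' attach time via [translate_annotations()] (or any function receiving the
#' map together with a tree), not at read time.
#'
#' @param file Path to a TSV file.
#' @param ann An [annotation_map].
#' @return `read_annotations()`: an `annotation_map`;
#'   `write_annotations()`: `ann`, invisibly.
#' @examples
#' tsv <- tempfile(fileext = ".tsv")
#' write_annotations(fig1_annotations(), tsv)
#' read_annotations(tsv)
#' @export
read_annotations <- function(file) {
  check_string(file, "file")
  if (!file.exists(file)) {
    abort_cg(sprintf("File not found: '%s'", file),
             class = "cladegraph_error_file_not_found")
  }
  lines <- readLines(file, warn = FALSE, encoding = "UTF-8")
  taxa <- character(0)
  chars <- character(0)
  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) next
    fields <- strsplit(line, "\t", fixed = TRUE)[[1]]
    if (length(fields) != 2 || !nzchar(trimws(fields[[1]]))) {
      abort_cg(
        sprintf("Malformed annotation line %d: expected 'taxon<TAB>char1,char2,...'", i),
        class = "cladegraph_error_parse", line = i
      )
    }
    ids <- trimws(strsplit(fields[[2]], ",", fixed = TRUE)[[1]])
    ids <- ids[nzchar(ids)]
    if (length(ids) == 0) {
      abort_cg(
        sprintf("Malformed annotation line %d: no character identifiers.", i),
        class = "cladegraph_error_parse", line = i
      )
    }
    taxa <- c(taxa, rep(trimws(fields[[1]]), length(ids)))
    chars <- c(chars, ids)
  }
  annotation_map(tibble::tibble(taxon = taxa, character = chars))
}

#' @rdname read_annotations
#' @export
write_annotations <- function(ann, file) {
  ann <- annotation_map(ann)
  by_taxon <- split(ann$character, factor(ann$taxon, levels = unique(ann$taxon)))
  lines <- vapply(
    names(by_taxon),
    function(tx) paste0(tx, "\t", paste(by_taxon[[tx]], collapse = ",")),
    character(1)
  )
  writeLines(lines, file, useBytes = TRUE)
  invisible(ann)
}
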