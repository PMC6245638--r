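#' Read a protein-to-GO annotation table
#'
#' Two-column TSV, one `protein_id<TAB>GO_id` pair per line, no header.
#' Repeated pairs collapse (set semantics).  GO identifiers must match
#' `GO:` followed by exactly seven digits; a malformed id is reported with
#' its line number.
#'
#' @param source Path to a TSV file, or a character vector of lines.
#' @return A tibble of class `annotation_table` with columns `protein_id`,
#'   `go_id` (unique pairs).  Use [go_terms()] for lookups; unknown proteins
#'   yield an empty set.
#' @examples
#' anns <- read_annotations(c("P1\tGO:0007420", "P1\tGO:0007420"))
#' go_terms(anns, "P1")
#' @export
read_annotations <- function(source) {
  lines <- if (length(source) == 1 && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    as.character(source)
  }
  lines <- sub("\r$", "", lines)
  keep <- nzchar(trimws(lines))
  idx <- which(keep)
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  bad_cols <- which(lengths(parts) < 2)
  if (length(bad_cols)) {
    abort(sprintf("Line %d: expected 'protein_id<TAB>GO_id'.", idx[bad_cols[[1]]]),
          class = "orthopath_annotation_error")
  }
  pid <- map_chr(parts, 1)
  gid <- map_chr(parts, 2)
  ok <- grepl("^GO:[0-9]{7}$", gid)
  if (any(!ok)) {
    abort(sprintf("Line %d: malformed GO identifier '%s'.",
                  idx[which(!ok)[[1]]], gid[which(!ok)[[1]]]),
          class = "orthopath_annotation_error")
  }
  out <- distinct(tibble(protein_id = pid, go_id = gid))
  class(out) <- c("annotation_table", class(out))
  out
}

#' GO terms annotated to one protein
#'
#' @param annotations An `annotation_table` from [read_annotations()].
#' @param protein_id Protein identifier.
#' @return Character vector of GO ids (possibly empty).
#' @export
go_terms <- function(annotations, protein_id) {
  annotations$go_id[annotations$protein_id == protein_id]
}

#' Proteins annotated with one GO term
#' @param annotations An `annotation_table`.
#' @param go_id GO term identifier.
#' @return Character vector of protein ids (possibly empty).
#' @export
term_proteins <- function(annotations, go_id) {
  unique(annotations$protein_id[annotations$go_id == go_id])
}
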