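#' Read protein sequences from a FASTA file
#'
#' Parses FASTA text into a tibble of protein records, one row per entry.
#' The record id is the first whitespace-delimited token of the header; the
#' remainder of the header becomes the description.  Sequence lines are
#' concatenated and upper-cased.  Non-standard residues U, B, Z and O are
#' mapped to X with a warning so that downstream alignment stays total over
#' real proteome content; any other character outside the 20 standard amino
#' acids plus X is an error.
#'
#' Malformed input (text before the first `>`, an empty sequence, a duplicate
#' id within the file) is reported with the offending line number.
#'
#' @param source Path to a FASTA file, or a character vector of FASTA lines.
#' @param proteome_id Optional proteome identifier stamped on every record.
#'
#' @return A tibble with columns `id`, `description`, `sequence`,
#'   `proteome_id`.
#' @examples
#' read_fasta(c(">P1 my protein", "MKV", "LLT"))
#' @export
read_fasta <- function(source, proteome_id = NA_character_) {
  lines <- if (length(source) == 1 && !startsWith(source[1], ">") && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    unlist(strsplit(source, "\n", fixed = TRUE))
  }
  lines <- sub("\r$", "", lines)

  ids <- character()
  descs <- character()
  seqs <- character()
  header_line <- integer()
  cur <- NULL # index of current record

  for (i in seq_along(lines)) {
    line <- lines[[i]]
    if (!nzchar(trimws(line))) next
    if (startsWith(line, ">")) {
      header <- trimws(substring(line, 2))
      if (!nzchar(header)) {
        abort(sprintf("Line %d: FASTA header has no identifier.", i),
              class = "orthopath_fasta_error")
      }
      tok <- strsplit(header, "\\s+")[[1]]
      id <- tok[[1]]
      if (id %in% ids) {
        abort(sprintf("Line %d: duplicate record id '%s'.", i, id),
              class = "orthopath_fasta_error")
      }
      ids <- c(ids, id)
      descs <- c(descs, if (length(tok) > 1) paste(tok[-1], collapse = " ") else "")
      seqs <- c(seqs, "")
      header_line <- c(header_line, i)
      cur <- length(ids)
    } else {
      if (is.null(cur)) {
        abort(sprintf("Line %d: sequence data before any '>' header.", i),
              class = "orthopath_fasta_error")
      }
      chunk <- toupper(gsub("\\s", "", line))
      bad <- setdiff(strsplit(chunk, "")[[1]], c(AA_ALLOWED, AA_REMAP, "*"))
      if (length(bad)) {
        abort(sprintf("Line %d: invalid residue(s) %s in record '%s'.",
                      i, paste(unique(bad), collapse = ","), ids[[cur]]),
              class = "orthopath_fasta_error")
      }
      seqs[[cur]] <- paste0(seqs[[cur]], chunk)
    }
  }

  if (!length(ids)) {
    return(tibble(id = character(), description = character(),
                  sequence = character(), proteome_id = character()))
  }
  empty <- !nzchar(gsub("\\*", "", seqs))
  if (any(empty)) {
    k <- which(empty)[[1]]
    abort(sprintf("Line %d: record '%s' has an empty sequence.",
                  header_line[[k]], ids[[k]]),
          class = "orthopath_fasta_error")
  }
  seqs <- gsub("\\*", "", seqs) # tolerate trailing stop codons
  if (any(grepl("[UBZO]", seqs))) {
    warn("Non-standard residues U/B/Z/O mapped to X.")
    seqs <- chartr("UBZO", "XXXX", seqs)
  }
  tibble(id = ids, description = descs, sequence = seqs,
         proteome_id = proteome_id)
}

#' Write protein records to a FASTA file
#'
#' Inverse of [read_fasta()] on the (`id`, `sequence`) pair: reading the
#' written file reproduces ids and sequences exactly.
#'
#' @param records Tibble with at least `id` and `sequence` columns
#'   (`description` used when present).
#' @param path Output file path.
#' @param width Line-wrap width for sequences.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(records, path, width = 60L) {
  stopifnot(all(c("id", "sequence") %in% names(records)))
  desc <- if ("description" %in% names(records)) records$description else ""
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (i in seq_len(nrow(records))) {
    hdr <- if (nzchar(desc[[min(i, length(desc))]] %||% "")) {
      paste0(">", records$id[[i]], " ", desc[[i]])
    } else {
      paste0(">", records$id[[i]])
    }
    writeLines(hdr, con)
    s <- records$sequence[[i]]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}
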