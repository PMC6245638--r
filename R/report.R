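#' Write a chain report to TSV and JSON
#'
#' The TSV is the human-readable summary (one row per taxon, fixed header:
#' taxon_index, taxon_name, species, search_query_id, hit_id, relation,
#' bit_score, evalue, query_coords, subject_coords; missing values rendered
#' as `NA`).  The JSON mirror carries the full alignments and parameters and
#' round-trips through [read_chain_report()] without loss.
#'
#' @param result A `chain_result` from [trace_chain()].
#' @param prefix Output path prefix; writes `<prefix>.chain.tsv` and
#'   `<prefix>.chain.json`.
#' @return Named character vector of the two paths, invisibly.
#' @export
write_chain_report <- function(result, prefix) {
  steps <- result$steps
  coords <- function(a, b) ifelse(is.na(a), NA_character_, paste0(a, "-", b))
  tsv <- tibble(
    taxon_index = steps$taxon_index,
    taxon_name = steps$taxon_name,
    species = steps$species_name,
    search_query_id = steps$search_query_id,
    hit_id = steps$hit_id,
    relation = steps$relation,
    bit_score = steps$bit_score,
    evalue = steps$evalue,
    query_coords = coords(steps$query_start, steps$query_end),
    subject_coords = coords(steps$subject_start, steps$subject_end)
  )
  tsv_path <- paste0(prefix, ".chain.tsv")
  json_path <- paste0(prefix, ".chain.json")
  utils::write.table(tsv, tsv_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  payload <- list(
    format = "orthopath.chain/1",
    query = as.list(result$query),
    entry_taxon = result$entry_taxon,
    path_name = result$path_name,
    backend = result$backend,
    params = unclass(result$params),
    steps = as.data.frame(steps)
  )
  jsonlite::write_json(payload, json_path, auto_unbox = TRUE, digits = NA,
                       na = "null", pretty = TRUE)
  invisible(c(tsv = tsv_path, json = json_path))
}

#' Read a chain report back from JSON
#'
#' @param json_path Path to a `<prefix>.chain.json` written by
#'   [write_chain_report()].
#' @return The reconstructed `chain_result`.
#' @export
read_chain_report <- function(json_path) {
  payload <- jsonlite::fromJSON(json_path, simplifyDataFrame = TRUE)
  if (!identical(payload$format, "orthopath.chain/1")) {
    abort("Not an orthopath chain report.", class = "orthopath_report_error")
  }
  steps <- as_tibble(payload$steps)
  for (col in c("hit_id", "query_aligned", "subject_aligned", "hit_sequence")) {
    steps[[col]] <- as.character(steps[[col]])
  }
  for (col in c("query_start", "query_end", "subject_start", "subject_end")) {
    steps[[col]] <- as.integer(steps[[col]])
  }
  for (col in c("raw_score", "bit_score", "evalue")) {
    steps[[col]] <- as.numeric(steps[[col]])
  }
  params <- payload$params
  result <- structure(
    list(
      query = tibble(id = payload$query$id, sequence = payload$query$sequence),
      entry_taxon = as.integer(payload$entry_taxon),
      steps = arrange(steps, .data$taxon_index),
      params = search_params(
        evalue_cutoff = params$evalue_cutoff,
        gap_open = params$gap_open,
        gap_extend = params$gap_extend,
        substitution_matrix = params$substitution_matrix,
        karlin_lambda = params$karlin_lambda,
        karlin_k = params$karlin_k
      ),
      path_name = payload$path_name,
      backend = payload$backend %||% "builtin"
    ),
    class = "chain_result"
  )
  validate_chain(result)
  result
}
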