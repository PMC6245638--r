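#' Best hit of a query in one proteome
#'
#' Aligns the query against every record of the target proteome and returns
#' the best-scoring hit whose e-value passes the cutoff.  Ranking is total
#' and deterministic: bit score descending, then subject id ascending
#' (lexicographic) on ties.
#'
#' @param query One-row record tibble (`id`, `sequence`).
#' @param target Proteome tibble of records (columns `id`, `sequence`,
#'   `proteome_id`).
#' @param params A [search_params()] object.
#'
#' @return A one-row tibble: the alignment columns of [local_align()] plus
#'   `subject_sequence`, `subject_proteome` and `rank` (always 1), or `NULL`
#'   when no hit passes
#'   the e-value cutoff.  An empty result is a valid outcome, not an error.
#' @export
best_hit <- function(query, target, params = search_params()) {
  stopifnot(nrow(target) >= 1)
  scores <- batch_scores(query$sequence[[1]], target$sequence, params)
  ev <- evalue(scores, nchar(query$sequence[[1]]), nchar(target$sequence), params)
  pass <- which(ev <= params$evalue_cutoff)
  if (!length(pass)) return(NULL)
  # bit score is monotone in raw score, so rank on raw; ties on id.
  ord <- pass[order(-scores[pass], target$id[pass])]
  top <- ord[[1]]
  aln <- local_align(query, target[top, ], params)
  mutate(aln,
         subject_sequence = target$sequence[[top]],
         subject_proteome = target$proteome_id[[top]] %||% NA_character_,
         rank = 1L)
}

#' Reciprocal-best-hit orthology assessment
#'
#' Given a forward best hit of `query` in some proteome, runs the reciprocal
#' search of the hit against the query's home proteome.  The relation is
#' `"ortholog"` iff the reciprocal rank-1 hit is the query itself, compared
#' by record id (all records of the home proteome participate, including the
#' query).  A reciprocal search that returns nothing, or a rank-1 hit other
#' than the query, yields `"homolog"`.
#'
#' @param query One-row record tibble used in the forward search.
#' @param hit Forward hit from [best_hit()].
#' @param query_home Proteome tibble containing `query`.
#' @param params A [search_params()] object.
#' @return `"ortholog"` or `"homolog"`.
#' @export
reciprocal_check <- function(query, hit, query_home, params = search_params()) {
  stopifnot(query$id[[1]] %in% query_home$id)
  subj <- tibble(id = hit$subject_id, sequence = hit_subject_sequence(hit))
  back <- best_hit(subj, query_home, params)
  if (is.null(back)) return("homolog")
  if (identical(back$subject_id, query$id[[1]])) "ortholog" else "homolog"
}

# Recover the full subject sequence when carried on the hit row, else
# reconstruct is impossible -> require the caller to supply it.
hit_subject_sequence <- function(hit) {
  if (!is.null(hit$subject_sequence)) return(hit$subject_sequence[[1]])
  abort("Hit does not carry `subject_sequence`.", class = "orthopath_search_error")
}
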