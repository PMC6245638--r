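#' Optimal local alignment of two protein sequences
#'
#' Exact Smith-Waterman local alignment under a substitution matrix and
#' affine gap penalties (a gap of length L costs `gap_open + L * gap_extend`,
#' the BLAST convention).  The raw score is converted to a bit score,
#' `(lambda * S - ln K) / ln 2`, and an e-value, `K * m * n * exp(-lambda * S)`
#' with `m`, `n` the full lengths of the two sequences.  The backend is fully
#' deterministic: identical inputs give identical alignments.
#'
#' @param a,b Protein sequences: plain strings or one-row record tibbles
#'   (columns `id`, `sequence`).
#' @param params A [search_params()] object.
#' @param query_id,subject_id Ids stamped on the result when `a`/`b` are
#'   plain strings.
#'
#' @return A one-row tibble with columns `query_id`, `subject_id`,
#'   `query_aligned`, `subject_aligned` (gap character `-`), 1-based
#'   inclusive `query_start`, `query_end`, `subject_start`, `subject_end`,
#'   `raw_score`, `bit_score`, `evalue`.
#' @examples
#' local_align("AAA", "AAA")$raw_score  # 3 * BLOSUM62 A<->A
#' @export
local_align <- function(a, b, params = search_params(),
                        query_id = "query", subject_id = "subject") {
  qa <- as_record(a, query_id)
  sb <- as_record(b, subject_id)
  if (!nzchar(qa$sequence) || !nzchar(sb$sequence)) {
    abort("Cannot align an empty sequence.", class = "orthopath_align_error")
  }
  note_backend_call()
  mat <- scoring_matrix(params)
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(qa$sequence), Biostrings::AAString(sb$sequence),
    type = "local", substitutionMatrix = mat,
    gapOpening = params$gap_open, gapExtension = params$gap_extend
  )
  s <- as.numeric(Biostrings::score(pa))
  m <- nchar(qa$sequence)
  n <- nchar(sb$sequence)
  tibble(
    query_id = qa$id,
    subject_id = sb$id,
    query_aligned = as.character(Biostrings::alignedPattern(pa)),
    subject_aligned = as.character(Biostrings::alignedSubject(pa)),
    query_start = Biostrings::start(Biostrings::pattern(pa)),
    query_end = Biostrings::end(Biostrings::pattern(pa)),
    subject_start = Biostrings::start(Biostrings::subject(pa)),
    subject_end = Biostrings::end(Biostrings::subject(pa)),
    raw_score = s,
    bit_score = bit_score(s, params),
    evalue = evalue(s, m, n, params)
  )
}

as_record <- function(x, fallback_id) {
  if (is.character(x) && length(x) == 1) {
    return(list(id = fallback_id, sequence = toupper(x)))
  }
  if (is.data.frame(x) && nrow(x) == 1) {
    return(list(id = x$id[[1]], sequence = x$sequence[[1]]))
  }
  abort("Expected a sequence string or a one-row record tibble.",
        class = "orthopath_align_error")
}

bit_score <- function(raw, params) {
  (params$karlin_lambda * raw - log(params$karlin_k)) / log(2)
}

evalue <- function(raw, m, n, params) {
  params$karlin_k * m * n * exp(-params$karlin_lambda * raw)
}

# Re-score an aligned pair under the matrix + affine penalties; used to
# enforce the raw-score invariant in tests.
rescore_alignment <- function(aln, params = search_params()) {
  mat <- scoring_matrix(params)
  q <- strsplit(aln$query_aligned, "")[[1]]
  s <- strsplit(aln$subject_aligned, "")[[1]]
  stopifnot(length(q) == length(s))
  score <- 0
  in_gap <- FALSE
  for (i in seq_along(q)) {
    if (q[[i]] == "-" || s[[i]] == "-") {
      score <- score - params$gap_extend - (if (in_gap) 0 else params$gap_open)
      in_gap <- TRUE
    } else {
      score <- score + mat[q[[i]], s[[i]]]
      in_gap <- FALSE
    }
  }
  score
}

# Vectorised raw scores of one query against many subjects (score only).
batch_scores <- function(query_seq, subject_seqs, params) {
  note_backend_call(length(subject_seqs))
  mat <- scoring_matrix(params)
  as.numeric(Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(subject_seqs), Biostrings::AAString(query_seq),
    type = "local", substitutionMatrix = mat,
    gapOpening = params$gap_open, gapExtension = params$gap_extend,
    scoreOnly = TRUE
  ))
}
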