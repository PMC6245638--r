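#' Search parameters for the homology search backend
#'
#' Bundles the scoring model used by [local_align()], [best_hit()] and the
#' chain tracer.  Defaults mirror protein BLAST defaults: BLOSUM62, affine
#' gap penalties 11 (open) / 1 (extend), and a permissive e-value cutoff of
#' 10.  Bit scores and e-values use Karlin-Altschul statistics with the
#' standard gapped constants lambda = 0.267 and K = 0.041; the e-value search
#' space is the pairwise product `m * n` of the two sequence lengths, not a
#' database-wide space, so real analyses wanting BLAST-like stringency should
#' lower `evalue_cutoff`.
#'
#' @param evalue_cutoff Maximum e-value for a hit to be reported. Must be > 0.
#' @param gap_open Positive integer gap-opening penalty.
#' @param gap_extend Positive integer per-residue gap-extension penalty.
#' @param substitution_matrix Name of a substitution matrix shipped with
#'   Biostrings (default `"BLOSUM62"`).
#' @param karlin_lambda,karlin_k Karlin-Altschul parameters used for
#'   `bit_score = (lambda * raw_score - ln K) / ln 2` and
#'   `evalue = K * m * n * exp(-lambda * raw_score)`.
#'
#' @return An object of class `search_params` (a named list).
#' @examples
#' search_params(evalue_cutoff = 1e-6)
#' @export
search_params <- function(evalue_cutoff = 10,
                          gap_open = 11L,
                          gap_extend = 1L,
                          substitution_matrix = "BLOSUM62",
                          karlin_lambda = 0.267,
                          karlin_k = 0.041) {
  if (!is.numeric(evalue_cutoff) || length(evalue_cutoff) != 1 || evalue_cutoff <= 0) {
    abort("`evalue_cutoff` must be a single positive number.", class = "orthopath_param_error")
  }
  if (gap_open <= 0 || gap_extend <= 0) {
    abort("Gap penalties must be positive.", class = "orthopath_param_error")
  }
  structure(
    list(
      evalue_cutoff = as.numeric(evalue_cutoff),
      gap_open = as.integer(gap_open),
      gap_extend = as.integer(gap_extend),
      substitution_matrix = substitution_matrix,
      karlin_lambda = karlin_lambda,
      karlin_k = karlin_k
    ),
    class = "search_params"
  )
}

#' @export
print.search_params <- function(x, ...) {
  cat("<search_params>\n")
  cat("  matrix:", x$substitution_matrix,
      " gap open/extend:", x$gap_open, "/", x$gap_extend, "\n")
  cat("  evalue cutoff:", format(x$evalue_cutoff),
      " lambda:", x$karlin_lambda, " K:", x$karlin_k, "\n")
  invisible(x)
}

# Resolve the substitution matrix by name from Biostrings' data sets.
scoring_matrix <- function(params) {
  name <- params$substitution_matrix
  env <- new.env()
  ok <- tryCatch(
    {
      utils::data(list = name, package = "Biostrings", envir = env)
      TRUE
    },
    warning = function(w) FALSE,
    error = function(e) FALSE
  )
  if (!ok || !exists(name, envir = env)) {
    abort(paste0("Unknown substitution matrix: ", name), class = "orthopath_param_error")
  }
  get(name, envir = env)
}
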