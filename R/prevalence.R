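#' Presence matrix of chains across path taxa
#'
#' For a set of chains traced on the same path, builds the boolean matrix
#' whose cell (query, taxon) is `TRUE` iff the chain found an ortholog or a
#' homolog at that taxon.  Steps with relation `none` are `FALSE`; the
#' query's own step (relation `query`) is `NA` - it is excluded from any
#' ratio, since the query trivially "hits" itself.
#'
#' @param chains List of `chain_result` objects traced on one path.
#' @return A logical matrix of class `presence_matrix` (rows = query ids,
#'   columns = taxon indices as character `0..T-1`).
#' @export
build_presence <- function(chains) {
  if (!length(chains)) {
    abort("Need at least one chain.", class = "orthopath_prevalence_error")
  }
  paths <- unique(map_chr(chains, function(ch) ch$path_name))
  ts <- unique(map_int(chains, function(ch) nrow(ch$steps)))
  if (length(paths) > 1 || length(ts) > 1) {
    abort("All chains must be traced on the same path.",
          class = "orthopath_prevalence_error")
  }
  qids <- map_chr(chains, function(ch) ch$query$id)
  if (anyDuplicated(qids)) {
    abort("Duplicate query ids across chains.", class = "orthopath_prevalence_error")
  }
  m <- matrix(NA, nrow = length(chains), ncol = ts,
              dimnames = list(qids, as.character(seq_len(ts) - 1L)))
  for (i in seq_along(chains)) {
    st <- arrange(chains[[i]]$steps, .data$taxon_index)
    v <- st$relation %in% c("ortholog", "homolog")
    v[st$relation == "query"] <- NA
    m[i, ] <- v
  }
  structure(m, class = c("presence_matrix", "matrix", "array"))
}

#' Per-taxon prevalence of one GO term
#'
#' The ratio at taxon t is the fraction of queries annotated with the term
#' whose chain has an ortholog or homolog at taxon t.  The denominator is
#' the number of queries annotated with the term (`denominator =
#' "annotated"`, the default) or all queries in the presence matrix
#' (`"all"`).  Taxa where every annotated query sits itself (relation
#' `query`) are reported as `NA`.
#'
#' @param term GO term identifier.
#' @param presence A `presence_matrix` from [build_presence()].
#' @param annotations An `annotation_table`; only query-side annotations are
#'   used (annotations are never transferred to hits).
#' @param denominator `"annotated"` or `"all"`.
#' @return A tibble of class `term_prevalence`: `term`, `taxon_index`,
#'   `ratio`, `n_queries`.  A term annotating no query raises a condition of
#'   class `orthopath_empty_term` rather than returning 0/0 ratios.
#' @export
term_ratio <- function(term, presence, annotations,
                       denominator = c("annotated", "all")) {
  denominator <- match.arg(denominator)
  annotated <- intersect(rownames(presence), term_proteins(annotations, term))
  if (!length(annotated)) {
    abort(paste0("Term ", term, " annotates no query in the presence matrix."),
          class = "orthopath_empty_term")
  }
  sub <- presence[annotated, , drop = FALSE]
  denom <- if (denominator == "annotated") length(annotated) else nrow(presence)
  ratio <- apply(sub, 2, function(col) {
    obs <- col[!is.na(col)]
    if (!length(obs)) return(NA_real_)
    sum(obs) / denom
  })
  out <- tibble(term = term,
                taxon_index = as.integer(colnames(presence)),
                ratio = as.numeric(ratio),
                n_queries = length(annotated))
  class(out) <- c("term_prevalence", class(out))
  out
}

#' Prevalence report over several GO terms
#'
#' One row per (term, taxon), ordered by term then taxon; `NA` at taxa
#' excluded as the query's own.
#'
#' @param terms Character vector of GO term ids.
#' @param presence A `presence_matrix`.
#' @param annotations An `annotation_table`.
#' @param file Optional path; when given the table is written as TSV
#'   (missing values rendered `NA`).
#' @inheritParams term_ratio
#' @return A `term_prevalence` tibble covering all terms.
#' @export
prevalence_report <- function(terms, presence, annotations, file = NULL,
                              denominator = c("annotated", "all")) {
  denominator <- match.arg(denominator)
  out <- bind_rows(map(sort(unique(terms)), function(tm) {
    term_ratio(tm, presence, annotations, denominator)
  }))
  out <- arrange(out, .data$term, .data$taxon_index)
  class(out) <- c("term_prevalence", class(out))
  if (!is.null(file)) {
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, na = "NA")
  }
  out
}

#' Read a prevalence report back from TSV
#' @param file Path written by [prevalence_report()].
#' @return A `term_prevalence` tibble.
#' @export
read_prevalence <- function(file) {
  out <- as_tibble(utils::read.delim(file, sep = "\t", na.strings = "NA",
                                     stringsAsFactors = FALSE))
  class(out) <- c("term_prevalence", class(out))
  out
}

#' @rdname prevalence_report
#' @param object A `term_prevalence` tibble.
#' @param ... Unused.
#' @export
autoplot.term_prevalence <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$taxon_index, y = .data$ratio,
                                       colour = .data$term)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "taxon", y = "presence ratio") +
    ggplot2::theme_minimal()
}
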