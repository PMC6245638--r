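#' Find the entry point of a query into an evolutionary path
#'
#' Searches the query against the union of all path proteomes and returns
#' the taxon whose proteome holds the overall best hit.  Ranking matches
#' [best_hit()] (bit score descending) with ties broken first by taxon index
#' descending (the proteome closest to the terminal node wins), then by
#' subject id ascending.  The entry relation is `"query"` when the hit is
#' id- and sequence-identical to the query; otherwise the entry hit is the
#' protein used to get into the path and is labelled `"ortholog"` without a
#' reciprocal check (a query from outside the path has no home proteome to
#' reciprocate against).
#'
#' @param query One-row record tibble (`id`, `sequence`).
#' @param path An [evo_path()].
#' @param params A [search_params()] object.
#' @return List with `entry_taxon` (integer), `hit` (a [best_hit()] row) and
#'   `relation` (`"query"` or `"ortholog"`).
#' @export
find_entry <- function(query, path, params = search_params()) {
  best <- NULL
  for (t in seq_len(n_taxa(path)) - 1L) {
    prot <- proteome(path, t)
    scores <- batch_scores(query$sequence[[1]], prot$sequence, params)
    ev <- evalue(scores, nchar(query$sequence[[1]]), nchar(prot$sequence), params)
    pass <- which(ev <= params$evalue_cutoff)
    if (!length(pass)) next
    ord <- pass[order(-scores[pass], prot$id[pass])]
    top <- ord[[1]]
    cand <- list(taxon = t, score = scores[[top]], id = prot$id[[top]])
    if (is.null(best) ||
        cand$score > best$score ||
        (cand$score == best$score && cand$taxon > best$taxon) ||
        (cand$score == best$score && cand$taxon == best$taxon && cand$id < best$id)) {
      best <- cand
    }
  }
  if (is.null(best)) {
    abort("Query has no hit in any path proteome: nothing to trace.",
          class = "orthopath_empty_chain")
  }
  prot <- proteome(path, best$taxon)
  hit <- best_hit(query, prot, params)
  relation <- if (identical(hit$subject_id, query$id[[1]]) &&
                  identical(hit$subject_sequence, query$sequence[[1]])) {
    "query"
  } else {
    "ortholog"
  }
  list(entry_taxon = best$taxon, hit = hit, relation = relation)
}

#' Trace a step-wise homolog chain along an evolutionary path
#'
#' The core traversal: after [find_entry()] places the query at its entry
#' taxon X, the entry hit seeds a descending sweep (X-1, X-2, ..., 0) and an
#' ascending sweep (X+1, ..., T-1).  At every step the current search query
#' - the most recent ortholog in that sweep, initialised to the entry hit -
#' is searched against the step's proteome with [best_hit()], and the hit is
#' assessed with [reciprocal_check()] against the search query's home
#' proteome.  An ortholog replaces the search query for subsequent steps; a
#' homolog is recorded but never used to search (last-ortholog fallback); a
#' step with no passing hit is recorded as `"none"` and skipped.  The
#' procedure stops only when every proteome of the path has been visited.
#'
#' @param query One-row record tibble (`id`, `sequence`).
#' @param path An [evo_path()].
#' @param params A [search_params()] object.
#' @param backend `"builtin"` for the exact Smith-Waterman backend, or
#'   `"blast"` to shell out to BLAST+ (requires `db_dir` and a path loaded
#'   from a config whose `taxa` carry the `fasta` column; alignment strings
#'   are then unavailable).
#' @param db_dir Directory of formatted BLAST databases (blast backend only).
#'
#' @return An object of class `chain_result`: the per-taxon steps are in
#'   `$steps` (one row per taxon, ordered by `taxon_index`), with the entry
#'   taxon in `$entry_taxon` and the query echoed in `$query`.  Use
#'   [tidy()] / [glance()] / [autoplot()] on it.
#' @export
trace_chain <- function(query, path, params = search_params(),
                        backend = c("builtin", "blast"), db_dir = NULL) {
  backend <- match.arg(backend)
  fwd <- make_forward_search(path, params, backend, db_dir)

  entry <- find_entry(query, path, params)
  x <- entry$entry_taxon
  steps <- vector("list", n_taxa(path))

  entry_hit <- entry$hit
  steps[[x + 1L]] <- step_row(x, query$id[[1]], entry_hit, entry$relation, 1L)

  seed <- tibble(id = entry_hit$subject_id, sequence = entry_hit$subject_sequence)
  order_counter <- 1L
  for (direction in c(-1L, 1L)) {
    sq <- seed
    sq_home <- x
    taxa <- if (direction < 0) rev(seq_len(x)) - 1L else seq(x + 1L, length.out = n_taxa(path) - x - 1L)
    for (t in taxa) {
      order_counter <- order_counter + 1L
      hit <- fwd(sq, t)
      if (is.null(hit)) {
        steps[[t + 1L]] <- step_row(t, sq$id[[1]], NULL, "none", order_counter)
        next
      }
      if (is.na(hit$subject_sequence)) {
        hit$subject_sequence <- lookup_sequence(path, t, hit$subject_id)
      }
      rel <- reciprocal_search(sq, hit, sq_home, path, params, backend, db_dir)
      steps[[t + 1L]] <- step_row(t, sq$id[[1]], hit, rel, order_counter)
      if (rel == "ortholog") {
        sq <- tibble(id = hit$subject_id, sequence = hit$subject_sequence)
        sq_home <- t
      }
    }
  }

  steps <- bind_rows(steps)
  steps <- left_join(path$taxa, steps, by = "taxon_index")
  steps <- mutate(steps, proteome_id = map_chr(
    .data$taxon_index, function(t) proteome(path, t)$proteome_id[[1]] %||% NA_character_))
  steps <- relocate(steps, "taxon_index", "taxon_name", "species_name",
                    "proteome_id", "step_order")

  result <- structure(
    list(
      query = tibble(id = query$id[[1]], sequence = query$sequence[[1]]),
      entry_taxon = x,
      steps = steps,
      params = params,
      path_name = path$name,
      backend = backend
    ),
    class = "chain_result"
  )
  validate_chain(result)
  result
}

step_row <- function(taxon, search_query_id, hit, relation, order) {
  if (is.null(hit)) {
    return(tibble(
      taxon_index = taxon, step_order = order,
      search_query_id = search_query_id,
      hit_id = NA_character_, relation = relation,
      raw_score = NA_real_, bit_score = NA_real_, evalue = NA_real_,
      query_start = NA_integer_, query_end = NA_integer_,
      subject_start = NA_integer_, subject_end = NA_integer_,
      query_aligned = NA_character_, subject_aligned = NA_character_,
      hit_sequence = NA_character_
    ))
  }
  tibble(
    taxon_index = taxon, step_order = order,
    search_query_id = search_query_id,
    hit_id = hit$subject_id, relation = relation,
    raw_score = hit$raw_score, bit_score = hit$bit_score, evalue = hit$evalue,
    query_start = hit$query_start, query_end = hit$query_end,
    subject_start = hit$subject_start, subject_end = hit$subject_end,
    query_aligned = hit$query_aligned, subject_aligned = hit$subject_aligned,
    hit_sequence = hit$subject_sequence
  )
}

make_forward_search <- function(path, params, backend, db_dir) {
  if (backend == "builtin") {
    function(sq, taxon) best_hit(sq, proteome(path, taxon), params)
  } else {
    if (is.null(db_dir) || !"fasta" %in% names(path$taxa)) {
      abort("blast backend needs `db_dir` and a path config with a `fasta` column.",
            class = "orthopath_blast_error")
    }
    bk <- blast_backend(db_dir, params)
    function(sq, taxon) bk(sq, path$taxa$fasta[[taxon + 1L]])
  }
}

reciprocal_search <- function(sq, hit, sq_home, path, params, backend, db_dir) {
  subj <- tibble(id = hit$subject_id, sequence = hit$subject_sequence)
  if (backend == "builtin") {
    back <- best_hit(subj, proteome(path, sq_home), params)
  } else {
    bk <- blast_backend(db_dir, params)
    back <- bk(subj, path$taxa$fasta[[sq_home + 1L]])
  }
  if (!is.null(back) && identical(back$subject_id, sq$id[[1]])) "ortholog" else "homolog"
}

lookup_sequence <- function(path, taxon, id) {
  prot <- proteome(path, taxon)
  i <- match(id, prot$id)
  if (is.na(i)) {
    abort(paste0("Hit id not found in proteome: ", id), class = "orthopath_search_error")
  }
  prot$sequence[[i]]
}

#' Check the structural invariants of a traced chain
#'
#' Asserts, for every non-entry step in traversal order, that the protein
#' used as search query is the hit of the nearest preceding step (in that
#' sweep) whose relation is `"ortholog"` or `"query"` - i.e. that homologs
#' are recorded but never seed a search - and that exactly one step exists
#' per path taxon.  Called automatically at the end of [trace_chain()].
#'
#' @param result A `chain_result`.
#' @return `result`, invisibly; errors if an invariant is violated.
#' @export
validate_chain <- function(result) {
  steps <- result$steps
  if (anyDuplicated(steps$taxon_index)) {
    abort("Chain has more than one step for a taxon.", class = "orthopath_chain_error")
  }
  x <- result$entry_taxon
  entry <- steps[steps$taxon_index == x, ]
  for (direction in c(-1L, 1L)) {
    expect_sq <- entry$hit_id
    taxa <- if (direction < 0) rev(seq_len(x)) - 1L else
      seq(x + 1L, length.out = nrow(steps) - x - 1L)
    for (t in taxa) {
      st <- steps[steps$taxon_index == t, ]
      if (!identical(st$search_query_id, expect_sq)) {
        abort(sprintf(
          "Chain invariant violated at taxon %d: search query '%s', expected '%s'.",
          t, st$search_query_id, expect_sq), class = "orthopath_chain_error")
      }
      if ((st$relation == "none") != is.na(st$hit_id)) {
        abort(sprintf("Relation/hit mismatch at taxon %d.", t),
              class = "orthopath_chain_error")
      }
      if (st$relation == "ortholog") expect_sq <- st$hit_id
    }
  }
  invisible(result)
}

#' @export
print.chain_result <- function(x, ...) {
  cat("<chain_result> query '", x$query$id, "' on path '", x$path_name,
      "' (entry taxon ", x$entry_taxon, ")\n", sep = "")
  print(select(x$steps, "taxon_index", "taxon_name", "search_query_id",
               "hit_id", "relation", "bit_score", "evalue"))
  invisible(x)
}

#' @rdname trace_chain
#' @param x A `chain_result`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.chain_result <- function(x, ...) {
  select(x$steps, -"query_aligned", -"subject_aligned", -"hit_sequence")
}

#' @rdname trace_chain
#' @exportS3Method generics::glance
glance.chain_result <- function(x, ...) {
  rel <- x$steps$relation
  tibble(
    query_id = x$query$id,
    path = x$path_name,
    n_taxa = nrow(x$steps),
    entry_taxon = x$entry_taxon,
    n_ortholog = sum(rel == "ortholog"),
    n_homolog = sum(rel == "homolog"),
    n_none = sum(rel == "none")
  )
}

#' @rdname trace_chain
#' @param object A `chain_result`.
#' @export
autoplot.chain_result <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$taxon_index, y = .data$bit_score,
                                  colour = .data$relation)) +
    ggplot2::geom_point(size = 2, na.rm = TRUE) +
    ggplot2::geom_line(ggplot2::aes(group = 1), colour = "grey60",
                       linewidth = 0.3, na.rm = TRUE) +
    ggplot2::scale_x_continuous(breaks = d$taxon_index,
                                labels = paste0(d$taxon_index, "\n", d$taxon_name)) +
    ggplot2::labs(x = "taxon", y = "bit score",
                  title = paste0("Homolog chain of ", object$query$id)) +
    ggplot2::theme_minimal()
}
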