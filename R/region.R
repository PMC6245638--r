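#' Lock a region of a protein for tracking
#'
#' A locked region is a subsequence of interest, given by 1-based inclusive
#' coordinates in its owner's sequence, whose conservation is followed
#' through a chain's alignments.
#'
#' @param owner_id Id of the protein whose coordinate system the region
#'   lives in (usually the chain's query).
#' @param start,end 1-based inclusive coordinates, `start <= end`.
#' @return An object of class `locked_region`.
#' @export
locked_region <- function(owner_id, start, end) {
  start <- as.integer(start)
  end <- as.integer(end)
  if (is.na(start) || is.na(end) || start < 1 || end < start) {
    abort("Region needs 1 <= start <= end.", class = "orthopath_region_bounds")
  }
  structure(list(owner_id = owner_id, start = start, end = end,
                 length = end - start + 1L),
            class = "locked_region")
}

#' @export
print.locked_region <- function(x, ...) {
  cat("<locked_region> ", x$owner_id, " ", x$start, "-", x$end,
      " (", x$length, " aa)\n", sep = "")
  invisible(x)
}

#' Validate a locked region against its owner sequence
#'
#' Region length must lie in the interval 10-100 amino acids and the
#' coordinates must fall inside the owner sequence.  Violations raise
#' distinct condition classes: `orthopath_region_length` for the length
#' bounds, `orthopath_region_bounds` for out-of-sequence coordinates.
#'
#' @param region A [locked_region()].
#' @param owner One-row record tibble (`id`, `sequence`) the coordinates
#'   refer to.
#' @return `region`, invisibly, when valid.
#' @export
validate_region <- function(region, owner) {
  if (region$length < 10L) {
    abort(sprintf("Locked region is %d aa; minimum length is 10.", region$length),
          class = "orthopath_region_length")
  }
  if (region$length > 100L) {
    abort(sprintf("Locked region is %d aa; maximum length is 100.", region$length),
          class = "orthopath_region_length")
  }
  if (region$end > nchar(owner$sequence[[1]])) {
    abort(sprintf("Region %d-%d exceeds the owner sequence (length %d).",
                  region$start, region$end, nchar(owner$sequence[[1]])),
          class = "orthopath_region_bounds")
  }
  invisible(region)
}

#' Project region coordinates through one pairwise alignment
#'
#' Coverage is the fraction of region positions (in the alignment's query
#' coordinate system) that fall inside the aligned query range and face a
#' residue - not a gap - on the subject side.  The region maps when at least
#' one position is covered and coverage reaches the threshold; mapped
#' coordinates are the subject positions aligned to the first and last
#' covered region positions.
#'
#' @param region_start,region_end 1-based inclusive coordinates in the
#'   alignment's query sequence.
#' @param alignment A one-row alignment tibble from [local_align()] (or a
#'   chain step carrying the same columns).
#' @param threshold Minimum coverage fraction in `[0, 1]`.
#' @return One-row tibble: `mapped`, `mapped_start`, `mapped_end`,
#'   `coverage`, `subsequence` (subject residues between the mapped
#'   coordinates), and `column_residues` (per region position, the subject
#'   residue aligned to it, `-` where uncovered; feeds [build_logo()]).
#' @export
map_region <- function(region_start, region_end, alignment, threshold = 0.75) {
  stopifnot(threshold >= 0, threshold <= 1, region_start <= region_end)
  len <- region_end - region_start + 1L
  q <- strsplit(alignment$query_aligned, "")[[1]]
  s <- strsplit(alignment$subject_aligned, "")[[1]]
  if (!length(q) || anyNA(alignment$query_aligned)) {
    abort("Alignment carries no aligned strings (external backend?).",
          class = "orthopath_region_error")
  }
  qpos <- cumsum(q != "-") + alignment$query_start - 1L
  qpos[q == "-"] <- NA_integer_
  spos <- cumsum(s != "-") + alignment$subject_start - 1L
  spos[s == "-"] <- NA_integer_

  col_res <- rep("-", len)
  cov_spos <- rep(NA_integer_, len)
  for (k in seq_len(len)) {
    r <- region_start + k - 1L
    i <- which(!is.na(qpos) & qpos == r)
    if (length(i) == 1 && s[[i]] != "-") {
      col_res[[k]] <- s[[i]]
      cov_spos[[k]] <- spos[[i]]
    }
  }
  covered <- which(!is.na(cov_spos))
  coverage <- length(covered) / len
  mapped <- length(covered) >= 1 && coverage >= threshold
  if (!length(covered)) {
    return(tibble(mapped = FALSE, mapped_start = NA_integer_,
                  mapped_end = NA_integer_, coverage = 0,
                  subsequence = NA_character_,
                  column_residues = paste(col_res, collapse = "")))
  }
  ms <- cov_spos[[covered[[1]]]]
  me <- cov_spos[[covered[[length(covered)]]]]
  sub <- paste(s[!is.na(spos) & spos >= ms & spos <= me], collapse = "")
  tibble(mapped = mapped, mapped_start = ms, mapped_end = me,
         coverage = coverage,
         subsequence = if (mapped) sub else NA_character_,
         column_residues = paste(col_res, collapse = ""))
}

#' Propagate a locked region through a traced chain
#'
#' Walks the chain's steps in traversal order (entry first, then the
#' descending and ascending sweeps, each restarting from the entry state)
#' and projects the region from protein to protein through the stored
#' alignments - no new searches or alignments are run.  At each step with a
#' hit, the current reference coordinates are projected through the step's
#' alignment; when the step's hit seeds later searches (relation `query` or
#' `ortholog`) and the projection succeeds, the reference moves to the hit.
#' A failed projection (e.g. the hit is a fragment lacking the region)
#' leaves the reference unchanged; when the chain's search query has moved
#' on past such a failure, the surviving reference coordinates are carried
#' over positionally onto later hits (rescue, flagged in the output) until
#' an alignment projection can re-synchronise.  Steps with relation `none`
#' yield no mapping.
#'
#' Re-locking: `region$owner_id` may name an ortholog inside the chain
#' instead of the query; mappings are then recomputed from the stored
#' alignments outward from that protein (reversed alignments carry the
#' coordinates back towards the entry), still without any new searches.
#'
#' @param chain A `chain_result` traced with the builtin backend.
#' @param region A [locked_region()] owned by the chain's query or by a
#'   chain ortholog.
#' @param threshold Minimum coverage fraction (default 0.75).
#' @return A tibble of class `region_mappings`, one row per step with a
#'   hit: `taxon_index`, `protein_id`, `relation`, `mapped`, `mapped_start`,
#'   `mapped_end`, `coverage`, `subsequence`, `column_residues`, `rescued`.
#' @export
propagate_region <- function(chain, region, threshold = 0.75) {
  steps <- arrange(chain$steps, .data$step_order)
  owner <- region$owner_id
  if (owner == chain$query$id) {
    validate_region(region, chain$query)
    return(propagate_from_query(chain, region, threshold))
  }
  k <- match(owner, steps$hit_id)
  if (is.na(k)) {
    abort(paste0("Region owner not in chain: ", owner),
          class = "orthopath_region_error")
  }
  validate_region(region, tibble(id = owner, sequence = steps$hit_sequence[[k]]))
  propagate_from_member(chain, region, threshold, steps, k)
}

propagate_from_query <- function(chain, region, threshold) {
  steps <- arrange(chain$steps, .data$step_order)
  x <- chain$entry_taxon
  entry <- steps[steps$taxon_index == x, ]
  entry_aln <- as.list(entry)
  m_entry <- map_region(region$start, region$end, entry_aln, threshold)
  rows <- list(mapping_row(entry, m_entry, rescued = FALSE))
  entry_ref <- if (m_entry$mapped) {
    list(id = entry$hit_id, start = m_entry$mapped_start, end = m_entry$mapped_end)
  } else {
    list(id = chain$query$id, start = region$start, end = region$end)
  }
  for (direction in c(-1L, 1L)) {
    sweep <- steps[if (direction < 0) steps$taxon_index < x else steps$taxon_index > x, ]
    sweep <- arrange(sweep, .data$step_order)
    rows <- c(rows, sweep_mappings(sweep, entry_ref, region, threshold))
  }
  finish_mappings(rows, region, threshold)
}

# Project along one sweep, starting from the entry reference state.
sweep_mappings <- function(sweep, ref, region, threshold) {
  rows <- list()
  for (i in seq_len(nrow(sweep))) {
    st <- sweep[i, ]
    if (st$relation == "none") next
    if (identical(ref$id, st$search_query_id)) {
      m <- map_region(ref$start, ref$end, as.list(st), threshold)
      rows <- c(rows, list(mapping_row(st, m, rescued = FALSE)))
      if (m$mapped && st$relation %in% c("ortholog", "query")) {
        ref <- list(id = st$hit_id, start = m$mapped_start, end = m$mapped_end)
      }
    } else {
      # Reference desynchronised from the search query (earlier failure):
      # carry the owner-frame coordinates over positionally onto the hit.
      m <- carry_over(ref, st, region, threshold)
      rows <- c(rows, list(mapping_row(st, m, rescued = TRUE)))
      if (m$mapped && st$relation %in% c("ortholog", "query")) {
        ref <- list(id = st$hit_id, start = m$mapped_start, end = m$mapped_end)
      }
    }
  }
  rows
}

carry_over <- function(ref, st, region, threshold) {
  hit_len <- nchar(st$hit_sequence)
  s <- min(ref$start, hit_len)
  e <- min(ref$end, hit_len)
  n_cov <- if (ref$start > hit_len) 0L else e - s + 1L
  coverage <- n_cov / region$length
  mapped <- n_cov >= 1 && coverage >= threshold
  sub <- if (n_cov >= 1) substr(st$hit_sequence, s, e) else NA_character_
  col_res <- rep("-", region$length)
  if (n_cov >= 1) col_res[seq_len(n_cov)] <- strsplit(sub, "")[[1]]
  tibble(mapped = mapped,
         mapped_start = if (n_cov >= 1) s else NA_integer_,
         mapped_end = if (n_cov >= 1) e else NA_integer_,
         coverage = coverage,
         subsequence = if (mapped) sub else NA_character_,
         column_residues = paste(col_res, collapse = ""))
}

propagate_from_member <- function(chain, region, threshold, steps, k) {
  x <- chain$entry_taxon
  owner_step <- steps[k, ]
  if (!owner_step$relation %in% c("ortholog", "query")) {
    abort("Re-locking requires the owner to be an ortholog in the chain.",
          class = "orthopath_region_error")
  }
  owner_side <- sign(owner_step$taxon_index - x)
  rows <- list(mapping_row(owner_step, tibble(
    mapped = TRUE, mapped_start = region$start, mapped_end = region$end,
    coverage = 1,
    subsequence = substr(owner_step$hit_sequence, region$start, region$end),
    column_residues = substr(owner_step$hit_sequence, region$start, region$end)
  ), rescued = FALSE))

  # Walk back towards the entry: reversing each step's stored alignment
  # carries the coordinates from its hit into its search query.
  back <- steps[steps$step_order <= owner_step$step_order &
                  sign(steps$taxon_index - x) == owner_side, ]
  back <- arrange(back, desc(.data$step_order))
  ref <- list(id = owner_step$hit_id, start = region$start, end = region$end)
  for (i in seq_len(nrow(back))) {
    st <- back[i, ]
    if (!st$relation %in% c("ortholog", "query") || !identical(ref$id, st$hit_id)) {
      abort("Re-locking across homolog/none steps is not supported.",
            class = "orthopath_region_error")
    }
    m <- map_region(ref$start, ref$end, reverse_alignment(st), threshold)
    if (!m$mapped) {
      abort("Region does not project back to the entry protein.",
            class = "orthopath_region_error")
    }
    new_id <- st$search_query_id
    src <- steps[!is.na(steps$hit_id) & steps$hit_id == new_id, ]
    if (nrow(src) == 1) {
      rows <- c(rows, list(mapping_row(src[1, ], m, rescued = FALSE)))
    }
    ref <- list(id = new_id, start = m$mapped_start, end = m$mapped_end)
  }
  # `ref` is now in the entry hit; continue outward over the remaining
  # steps of both sweeps.
  entry_ref <- ref
  out_rows <- list()
  for (direction in c(-1L, 1L)) {
    sweep <- steps[if (direction < 0) steps$taxon_index < x else steps$taxon_index > x, ]
    sweep <- arrange(sweep, .data$step_order)
    if (owner_side == direction) {
      sweep <- sweep[sweep$step_order > owner_step$step_order, ]
      out_rows <- c(out_rows, sweep_mappings(
        sweep, list(id = owner_step$hit_id, start = region$start, end = region$end),
        region, threshold))
    } else {
      out_rows <- c(out_rows, sweep_mappings(sweep, entry_ref, region, threshold))
    }
  }
  finish_mappings(c(rows, out_rows), region, threshold)
}

reverse_alignment <- function(st) {
  list(query_aligned = st$subject_aligned, subject_aligned = st$query_aligned,
       query_start = st$subject_start, subject_start = st$query_start)
}

mapping_row <- function(st, m, rescued) {
  bind_cols(tibble(taxon_index = st$taxon_index, protein_id = st$hit_id,
                   relation = st$relation),
            m, tibble(rescued = rescued))
}

finish_mappings <- function(rows, region, threshold) {
  out <- bind_rows(rows)
  out <- out[!duplicated(out$protein_id), ]
  out <- arrange(out, .data$taxon_index)
  attr(out, "region") <- region
  attr(out, "threshold") <- threshold
  class(out) <- c("region_mappings", class(out))
  out
}

#' @export
print.region_mappings <- function(x, ...) {
  r <- attr(x, "region")
  cat("<region_mappings> region ", r$owner_id, " ", r$start, "-", r$end,
      ", coverage threshold ", attr(x, "threshold"), "\n", sep = "")
  NextMethod()
}
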