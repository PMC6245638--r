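#' Position-frequency / information-content logo of mapped subsequences
#'
#' Stacks subsequences column-wise over the width of the locked region and
#' computes, per column, residue frequencies over the contributing
#' sequences and the information content in bits,
#' `IC = log2(20) - H` with `H` the Shannon entropy of the column's residue
#' distribution.  Strings may contain `-` for positions that contribute
#' nothing (unmapped region positions; subject insertions are already
#' dropped by [map_region()]'s per-position residues), so the per-column
#' sample size varies.  Sequences longer than `width` are truncated, shorter
#' ones are padded (the pad contributes nothing).
#'
#' @param subsequences Character vector of subsequences (or the
#'   `column_residues` strings from [propagate_region()]).
#' @param width Logo width; defaults to the longest input.
#' @param small_sample_correction Subtract the standard small-sample
#'   correction `e_n = 19 / (2 ln 2 n)` from each column's IC (clamped at
#'   0).  Off by default: the closed-form IC values are then exact.
#' @return An object of class `position_logo`: list with `freq` (20 x width
#'   matrix, columns sum to 1 where any residue contributes), `ic` (bits,
#'   in `[0, log2(20)]`), `n` (contributing sequences per column).
#' @examples
#' logo <- build_logo(rep("GAVLI", 10))
#' logo$ic  # each column: log2(20), fully conserved
#' @export
build_logo <- function(subsequences, width = NULL,
                       small_sample_correction = FALSE) {
  subsequences <- subsequences[!is.na(subsequences)]
  if (!length(subsequences)) {
    abort("Need at least one subsequence to build a logo.",
          class = "orthopath_logo_error")
  }
  width <- as.integer(width %||% max(nchar(subsequences)))
  freq <- matrix(0, nrow = length(AA_ALPHABET), ncol = width,
                 dimnames = list(AA_ALPHABET, NULL))
  counts <- freq
  for (s in subsequences) {
    chars <- strsplit(toupper(s), "")[[1]]
    for (j in seq_len(min(length(chars), width))) {
      ch <- chars[[j]]
      if (ch %in% AA_ALPHABET) counts[ch, j] <- counts[ch, j] + 1
    }
  }
  n <- colSums(counts)
  ic <- numeric(width)
  for (j in seq_len(width)) {
    if (n[[j]] > 0) {
      p <- counts[, j] / n[[j]]
      freq[, j] <- p
      nz <- p[p > 0]
      h <- -sum(nz * log2(nz))
      ic[[j]] <- log2(length(AA_ALPHABET)) - h
      if (small_sample_correction) {
        ic[[j]] <- max(0, ic[[j]] - (length(AA_ALPHABET) - 1) / (2 * log(2) * n[[j]]))
      }
    } else {
      ic[[j]] <- NA_real_
    }
  }
  structure(list(freq = freq, ic = ic, n = as.integer(n)),
            class = "position_logo")
}

#' @export
print.position_logo <- function(x, ...) {
  cat("<position_logo> width ", length(x$ic), ", IC range [",
      round(min(x$ic, na.rm = TRUE), 3), ", ",
      round(max(x$ic, na.rm = TRUE), 3), "] bits\n", sep = "")
  invisible(x)
}

#' @rdname build_logo
#' @param x,object A `position_logo`.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.position_logo <- function(x, ...) {
  wide <- as_tibble(t(x$freq))
  bind_cols(tibble(position = seq_along(x$ic)), wide,
            tibble(n = x$n, ic_bits = x$ic))
}

#' @rdname build_logo
#' @export
autoplot.position_logo <- function(object, ...) {
  d <- tidy(object)
  long <- tidyr::pivot_longer(d, cols = dplyr::all_of(AA_ALPHABET),
                              names_to = "residue", values_to = "freq")
  long <- filter(long, .data$freq > 0)
  long <- mutate(long, height = .data$freq * .data$ic_bits)
  long <- arrange(long, .data$position, .data$height)
  long <- mutate(group_by(long, .data$position),
                 ymax = cumsum(.data$height), ymin = .data$ymax - .data$height)
  ggplot2::ggplot(long) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$position - 0.45,
                                    xmax = .data$position + 0.45,
                                    ymin = .data$ymin, ymax = .data$ymax),
                       fill = "grey92", colour = "grey70", linewidth = 0.2) +
    ggplot2::geom_text(ggplot2::aes(x = .data$position,
                                    y = (.data$ymin + .data$ymax) / 2,
                                    label = .data$residue,
                                    size = .data$height),
                       show.legend = FALSE) +
    ggplot2::scale_size(range = c(1, 4)) +
    ggplot2::labs(x = "region position", y = "information content (bits)") +
    ggplot2::theme_minimal()
}

#' Write region mappings and their logo to TSV files
#'
#' @param mappings A `region_mappings` tibble from [propagate_region()].
#' @param prefix Output prefix; writes `<prefix>.regions.tsv` and
#'   `<prefix>.logo.tsv` (per column: the 20 residue frequencies, n, IC in
#'   bits).
#' @return Named character vector of paths, invisibly.
#' @export
write_region_report <- function(mappings, prefix) {
  region <- attr(mappings, "region")
  reg_path <- paste0(prefix, ".regions.tsv")
  logo_path <- paste0(prefix, ".logo.tsv")
  utils::write.table(
    select(as_tibble(mappings), -"column_residues"),
    reg_path, sep = "\t", quote = FALSE, row.names = FALSE, na = "NA")
  logo <- build_logo(mappings$column_residues[mappings$mapped],
                     width = region$length)
  utils::write.table(tidy(logo), logo_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, na = "NA")
  invisible(c(regions = reg_path, logo = logo_path))
}
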