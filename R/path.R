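#' Assemble an evolutionary path from loaded proteomes
#'
#' An evolutionary path is an ordered series of taxa, indexed 0..T-1, each
#' bound to exactly one proteome.  By convention each proteome is placed in
#' the last taxon it shares with the terminal node of the path, so the
#' terminal taxon carries the highest index.  Paths need at least two taxa.
#'
#' @param taxa Tibble with columns `taxon_index` (0-based, contiguous),
#'   `taxon_name`, `species_name`.
#' @param proteomes List of record tibbles (as from [read_fasta()]), one per
#'   taxon, in `taxon_index` order.
#' @param name Label for the path.
#' @return An object of class `evo_path`.
#' @export
evo_path <- function(taxa, proteomes, name = "path") {
  taxa <- as_tibble(taxa)
  stopifnot(all(c("taxon_index", "taxon_name", "species_name") %in% names(taxa)))
  taxa <- arrange(taxa, .data$taxon_index)
  idx <- taxa$taxon_index
  if (anyDuplicated(idx)) {
    abort("Duplicate taxon index in path definition.", class = "orthopath_path_error")
  }
  if (!identical(as.integer(idx), seq_len(nrow(taxa)) - 1L)) {
    abort("Taxon indices must be contiguous 0..T-1.", class = "orthopath_path_error")
  }
  if (nrow(taxa) < 2) {
    abort("An evolutionary path needs at least two taxa.", class = "orthopath_path_error")
  }
  if (length(proteomes) != nrow(taxa)) {
    abort("Need exactly one proteome per taxon.", class = "orthopath_path_error")
  }
  proteomes <- map(seq_along(proteomes), function(i) {
    p <- as_tibble(proteomes[[i]])
    if (!nrow(p)) {
      abort(sprintf("Proteome for taxon %d is empty.", i - 1L),
            class = "orthopath_path_error")
    }
    if (anyDuplicated(p$id)) {
      abort(sprintf("Duplicate record id in proteome for taxon %d.", i - 1L),
            class = "orthopath_path_error")
    }
    p
  })
  structure(
    list(name = name, taxa = taxa, proteomes = proteomes),
    class = "evo_path"
  )
}

#' @export
print.evo_path <- function(x, ...) {
  cat("<evo_path> '", x$name, "': ", n_taxa(x), " taxa, ",
      sum(map_int(x$proteomes, nrow)), " proteins\n", sep = "")
  print(mutate(x$taxa, n_proteins = map_int(x$proteomes, nrow)))
  invisible(x)
}

#' Number of taxa in a path
#' @param path An `evo_path`.
#' @return Integer T.
#' @export
n_taxa <- function(path) nrow(path$taxa)

#' Proteome bound to one taxon
#' @param path An `evo_path`.
#' @param taxon_index 0-based taxon index.
#' @return Tibble of protein records.
#' @export
proteome <- function(path, taxon_index) {
  stopifnot(taxon_index >= 0, taxon_index < n_taxa(path))
  path$proteomes[[taxon_index + 1L]]
}

# Find one record by id anywhere in the path; NULL if absent.
path_record <- function(path, id) {
  for (p in path$proteomes) {
    i <- match(id, p$id)
    if (!is.na(i)) return(p[i, ])
  }
  NULL
}

#' Load an evolutionary path from a config file
#'
#' The config is a 4-column TSV (with header) listing, per taxon:
#' `taxon_index`, `taxon_name`, `species_name`, `fasta` (proteome FASTA
#' filename, resolved against `proteome_dir`).  Proteomes are loaded eagerly
#' and validated; indices must be contiguous from 0.
#'
#' @param config Path to the TSV config.
#' @param proteome_dir Directory containing the proteome FASTA files.
#' @return An `evo_path`.
#' @export
read_path_config <- function(config, proteome_dir = dirname(config)) {
  df <- utils::read.delim(config, sep = "\t", stringsAsFactors = FALSE)
  need <- c("taxon_index", "taxon_name", "species_name", "fasta")
  if (!all(need %in% names(df))) {
    abort(paste0("Path config must have columns: ", paste(need, collapse = ", ")),
          class = "orthopath_path_error")
  }
  df <- arrange(as_tibble(df), .data$taxon_index)
  missing <- df$fasta[!file.exists(file.path(proteome_dir, df$fasta))]
  if (length(missing)) {
    abort(paste0("Missing proteome FASTA file(s): ", paste(missing, collapse = ", ")),
          class = "orthopath_path_error")
  }
  proteomes <- map(seq_len(nrow(df)), function(i) {
    read_fasta(file.path(proteome_dir, df$fasta[[i]]),
               proteome_id = sprintf("taxon%02d", df$taxon_index[[i]]))
  })
  evo_path(select(df, "taxon_index", "taxon_name", "species_name"),
           proteomes,
           name = sub("\\.tsv$", "", basename(config)))
}

#' Restrict a path to a contiguous sub-range of taxa
#'
#' Realises alternative traversal windows without re-deriving a new path:
#' the selected taxa are re-indexed 0..(b-a).
#'
#' @param path An `evo_path`.
#' @param from,to Inclusive 0-based bounds of the sub-range.
#' @return An `evo_path` over the sub-range.
#' @export
subset_path <- function(path, from, to) {
  stopifnot(from >= 0, to < n_taxa(path), from < to)
  keep <- seq(from, to)
  taxa <- path$taxa[path$taxa$taxon_index %in% keep, ]
  taxa$taxon_index <- taxa$taxon_index - from
  evo_path(taxa, path$proteomes[keep + 1L],
           name = sprintf("%s[%d:%d]", path$name, from, to))
}

#' Default path taxa (cellular organisms to Homo)
#'
#' The fifteen taxa of the default evolutionary path, from the broadest
#' (cellular organisms, index 0) to the terminal genus (Homo, index 14).
#' Proteomes are not bundled; bind your own with [evo_path()] or a path
#' config.
#'
#' @return Tibble with `taxon_index` and `taxon_name`.
#' @examples
#' default_path_taxa()
#' @export
default_path_taxa <- function() {
  f <- system.file("extdata", "default_path_taxa.tsv", package = "orthopath",
                   mustWork = TRUE)
  as_tibble(utils::read.delim(f, sep = "\t", stringsAsFactors = FALSE))
}
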