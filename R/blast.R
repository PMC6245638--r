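#' Parse an NCBI BLAST tabular report (outfmt 6)
#'
#' Reads the standard 12-column tabular format in the canonical column
#' order: qseqid sseqid pident length mismatch gapopen qstart qend sstart
#' send evalue bitscore.
#'
#' @param source Path to a tabular report, or a character vector of lines.
#' @return A tibble, one row per HSP; zero rows for an empty report.
#' @export
read_blast_tabular <- function(source) {
  cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
            "qstart", "qend", "sstart", "send", "evalue", "bitscore")
  lines <- if (length(source) == 1 && file.exists(source)) {
    readLines(source, warn = FALSE)
  } else {
    as.character(source)
  }
  lines <- lines[nzchar(trimws(lines)) & !startsWith(lines, "#")]
  if (!length(lines)) {
    out <- as_tibble(setNames(
      c(list(character(), character()), rep(list(numeric()), 10)), cols))
    return(out)
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 12)) {
    abort("Malformed BLAST tabular line: fewer than 12 columns.",
          class = "orthopath_blast_error")
  }
  tibble(
    qseqid = map_chr(parts, 1),
    sseqid = map_chr(parts, 2),
    pident = as.numeric(map_chr(parts, 3)),
    length = as.numeric(map_chr(parts, 4)),
    mismatch = as.numeric(map_chr(parts, 5)),
    gapopen = as.numeric(map_chr(parts, 6)),
    qstart = as.numeric(map_chr(parts, 7)),
    qend = as.numeric(map_chr(parts, 8)),
    sstart = as.numeric(map_chr(parts, 9)),
    send = as.numeric(map_chr(parts, 10)),
    evalue = as.numeric(map_chr(parts, 11)),
    bitscore = as.numeric(map_chr(parts, 12))
  )
}

#' Rank-1 hit from a BLAST tabular report
#'
#' Applies the same selection rule as [best_hit()]: drop HSPs above the
#' e-value cutoff, then order by bit score descending with ties broken by
#' subject id ascending.
#'
#' @param report Tibble from [read_blast_tabular()].
#' @param evalue_cutoff Maximum e-value retained.
#' @return A one-row tibble in [best_hit()] shape (alignment strings `NA`,
#'   since tabular reports carry none), or `NULL` if nothing passes.
#' @export
blast_rank1 <- function(report, evalue_cutoff = 10) {
  report <- filter(report, .data$evalue <= evalue_cutoff)
  if (!nrow(report)) return(NULL)
  report <- arrange(report, desc(.data$bitscore), .data$sseqid)
  top <- report[1, ]
  tibble(
    query_id = top$qseqid,
    subject_id = top$sseqid,
    query_aligned = NA_character_,
    subject_aligned = NA_character_,
    query_start = as.integer(top$qstart),
    query_end = as.integer(top$qend),
    subject_start = as.integer(top$sstart),
    subject_end = as.integer(top$send),
    raw_score = NA_real_,
    bit_score = top$bitscore,
    evalue = top$evalue,
    subject_sequence = NA_character_,
    subject_proteome = NA_character_,
    rank = 1L
  )
}

#' Search backend backed by external BLAST+ binaries
#'
#' Returns a function with the [best_hit()] contract that shells out to
#' `blastp` against pre-formatted databases (one per proteome, built with
#' [make_blast_dbs()]).  Missing binaries or databases raise an error; there
#' is never a silent fallback to the built-in backend.  Tabular output
#' carries no alignment strings, so chains traced with this backend cannot
#' feed the region tracker.
#'
#' @param db_dir Directory holding the formatted databases (basename =
#'   proteome FASTA name).
#' @param params A [search_params()] object; only `evalue_cutoff` is passed
#'   through (`blastp` keeps its own scoring defaults).
#' @return `function(query, target_db_name)` returning a [best_hit()]-shaped
#'   row or `NULL`.
#' @export
blast_backend <- function(db_dir, params = search_params()) {
  if (Sys.which("blastp") == "") {
    abort("blastp binary not found on PATH.", class = "orthopath_blast_error")
  }
  if (!dir.exists(db_dir)) {
    abort(paste0("BLAST database directory does not exist: ", db_dir),
          class = "orthopath_blast_error")
  }
  force(params)
  function(query, db_name) {
    db <- file.path(db_dir, db_name)
    if (!file.exists(paste0(db, ".pin")) && !file.exists(paste0(db, ".pdb"))) {
      abort(paste0("Proteome not formatted as a BLAST database: ", db),
            class = "orthopath_blast_error")
    }
    qf <- tempfile(fileext = ".fasta")
    on.exit(unlink(qf))
    write_fasta(query, qf)
    out <- suppressWarnings(system2(
      "blastp",
      c("-query", qf, "-db", db, "-outfmt", "6", "-evalue",
        format(params$evalue_cutoff, scientific = FALSE)),
      stdout = TRUE, stderr = FALSE
    ))
    status <- attr(out, "status") %||% 0L
    if (status != 0L) {
      abort("blastp exited with a non-zero status.", class = "orthopath_blast_error")
    }
    note_backend_call()
    blast_rank1(read_blast_tabular(out), params$evalue_cutoff)
  }
}

#' Format path proteomes as BLAST databases
#'
#' Runs `makeblastdb` over every proteome FASTA in a directory.
#'
#' @param proteome_dir Directory of proteome FASTA files (`.fasta`/`.fa`).
#' @param db_dir Output directory (defaults to `proteome_dir`).
#' @return `db_dir`, invisibly.
#' @export
make_blast_dbs <- function(proteome_dir, db_dir = proteome_dir) {
  if (Sys.which("makeblastdb") == "") {
    abort("makeblastdb binary not found on PATH.", class = "orthopath_blast_error")
  }
  dir.create(db_dir, showWarnings = FALSE, recursive = TRUE)
  fas <- list.files(proteome_dir, pattern = "\\.(fasta|fa)$", full.names = TRUE)
  for (f in fas) {
    status <- system2("makeblastdb",
                      c("-in", f, "-dbtype", "prot",
                        "-out", file.path(db_dir, basename(f))),
                      stdout = FALSE, stderr = FALSE)
    if (status != 0L) {
      abort(paste0("makeblastdb failed for ", f), class = "orthopath_blast_error")
    }
  }
  invisible(db_dir)
}
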