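#' Specification of a synthetic protein family on an evolutionary path
#'
#' Describes the ground-truth structure the generator emits: one family
#' member per taxon, diverging step by step away from the terminal taxon
#' (mirroring divergence at increasing taxonomic distance), embedded in
#' proteomes of random decoy proteins.  Optional perturbations plant the
#' situations the chain tracer must handle: family loss at chosen taxa,
#' out-competing paralogs that break reciprocity, and fragments truncated
#' before a conserved motif.
#'
#' @param n_taxa Number of path taxa (default 15).
#' @param proteome_size Records per proteome, family members included.
#' @param family_length Length of the family protein (aa).
#' @param substitution_rate Per-site substitution probability applied at
#'   each step away from the terminal taxon, in `[0, 1)`.
#' @param indel_rate Per-site indel event probability per step (geometric
#'   lengths, mean 2, capped at 5); indels never touch the motif.
#' @param motif Optional conserved motif: `list(start =, length =)` or
#'   `list(start =, sequence =)`.  Motif positions are protected from
#'   substitution in every member, so the motif is conserved family-wide.
#' @param n_families Number of independent families (each with its own
#'   query protein).
#' @param deletions,paralogs,truncations Taxa receiving the perturbation:
#'   an integer vector (applies to family 1) or a named list
#'   `list("1" = c(5), "2" = ...)` keyed by family.  A taxon may not be both
#'   deleted and truncated for the same family; paralogs need a taxon below
#'   the terminal one.
#' @param seed Mandatory integer seed; all randomness flows from it.
#' @return A `family_spec` list.
#' @export
family_spec <- function(n_taxa = 15L, proteome_size = 20L,
                        family_length = 200L,
                        substitution_rate = 0.05, indel_rate = 0,
                        motif = NULL, n_families = 1L,
                        deletions = list(), paralogs = list(),
                        truncations = list(), seed) {
  if (missing(seed)) abort("`seed` is mandatory.", class = "orthopath_spec_error")
  if (substitution_rate < 0 || substitution_rate >= 1 ||
      indel_rate < 0 || indel_rate >= 1) {
    abort("Rates must lie in [0, 1).", class = "orthopath_spec_error")
  }
  norm <- function(x) {
    if (is.list(x)) x else if (length(x)) list("1" = as.integer(x)) else list()
  }
  deletions <- norm(deletions); paralogs <- norm(paralogs); truncations <- norm(truncations)
  if (!is.null(motif)) {
    if (is.null(motif$sequence)) {
      if (is.null(motif$length)) {
        abort("Motif needs `length` or `sequence`.", class = "orthopath_spec_error")
      }
    } else {
      motif$length <- nchar(motif$sequence)
    }
    if (motif$start < 1 || motif$start + motif$length - 1 > family_length) {
      abort("Motif coordinates exceed the family length.", class = "orthopath_spec_error")
    }
  }
  for (f in union(names(deletions), names(truncations))) {
    if (length(intersect(deletions[[f]], truncations[[f]]))) {
      abort("A taxon cannot be both deleted and truncated.", class = "orthopath_spec_error")
    }
  }
  all_taxa <- unlist(c(deletions, paralogs, truncations))
  if (length(all_taxa) && (min(all_taxa) < 0 || max(all_taxa) >= n_taxa)) {
    abort("Perturbation taxa outside 0..n_taxa-1.", class = "orthopath_spec_error")
  }
  if (length(unlist(paralogs)) && max(unlist(paralogs)) >= n_taxa - 1) {
    abort("Paralogs need a taxon below the terminal one.", class = "orthopath_spec_error")
  }
  if (is.null(motif) && length(unlist(truncations))) {
    abort("Truncations need a motif to truncate before.", class = "orthopath_spec_error")
  }
  structure(
    list(n_taxa = as.integer(n_taxa), proteome_size = as.integer(proteome_size),
         family_length = as.integer(family_length),
         substitution_rate = substitution_rate, indel_rate = indel_rate,
         motif = motif, n_families = as.integer(n_families),
         deletions = deletions, paralogs = paralogs, truncations = truncations,
         seed = as.integer(seed)),
    class = "family_spec"
  )
}

random_seq <- function(n) paste(sample(AA_ALPHABET, n, replace = TRUE), collapse = "")

# Mutate one sequence: i.i.d. substitutions to a different residue outside
# the protected interval, then indel events of geometric length that never
# touch it.  Returns the sequence and the (possibly shifted) interval.
mutate_seq <- function(sequence, sub_rate, indel_rate, protect = NULL) {
  chars <- strsplit(sequence, "")[[1]]
  mask <- rep(FALSE, length(chars))
  if (!is.null(protect)) mask[protect[1]:protect[2]] <- TRUE
  elig <- which(!mask)
  hit <- elig[runif(length(elig)) < sub_rate]
  for (i in hit) chars[[i]] <- sample(setdiff(AA_ALPHABET, chars[[i]]), 1)
  n_events <- rbinom(1, length(elig), indel_rate)
  for (e in seq_len(n_events)) {
    len <- min(rgeom(1, 0.5) + 1L, 5L)
    if (runif(1) < 0.5) {
      # deletion: window must avoid the protected interval and fit
      cand <- which(!mask)
      cand <- cand[cand + len - 1L <= length(chars)]
      cand <- cand[map_lgl(cand, function(p) !any(mask[p:(p + len - 1L)]))]
      if (!length(cand)) next
      p <- cand[[sample.int(length(cand), 1)]]
      keep <- setdiff(seq_along(chars), p:(p + len - 1L))
      chars <- chars[keep]
      mask <- mask[keep]
    } else {
      # insertion after position p (0 = at the front); p inside the
      # protected interval would split it, so exclude those positions
      cand <- setdiff(0:length(chars), which(mask & c(mask[-1], FALSE)))
      p <- cand[[sample.int(length(cand), 1)]]
      ins <- sample(AA_ALPHABET, len, replace = TRUE)
      chars <- append(chars, ins, after = p)
      mask <- append(mask, rep(FALSE, len), after = p)
    }
  }
  list(sequence = paste(chars, collapse = ""),
       protect = if (any(mask)) range(which(mask)) else NULL)
}

#' Generate a synthetic evolutionary path with ground truth
#'
#' Emits proteome FASTA files and a path config TSV to `dir`, loads them
#' back through [read_path_config()] (so the generated fixtures also
#' exercise the readers), and returns the loaded path together with the
#' ground truth and one query protein per family.  The family member of
#' taxon k is derived from taxon k+1's member by the spec's substitution
#' and indel rates, so divergence grows with distance from the terminal
#' taxon; motif positions are substitution-protected.  Queries sit outside
#' the path: each is a lightly diverged copy (half the per-step
#' substitution rate) of its family's member at the highest taxon where the
#' family exists.  Everything is reproducible from the spec seed.
#'
#' @param spec A [family_spec()].
#' @param dir Output directory (created; default a fresh tempdir).
#' @return List with `path` (an [evo_path()]), `queries` (record tibble,
#'   one per family, with `family` and `derived_from_taxon`), `truth`
#'   (tibble: `family`, `taxon_index`, `member_id`, `motif_start`,
#'   `motif_end`, `paralog_id`, `anchor_id`), `dir`, `spec`.
#' @export
generate_path <- function(spec, dir = tempfile("synthpath")) {
  stopifnot(inherits(spec, "family_spec"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(spec$seed)

  Tn <- spec$n_taxa
  motif <- spec$motif
  truth <- list()
  members <- list()   # members[[f]][[t+1]] = list(sequence, protect)
  queries <- list()

  for (f in seq_len(spec$n_families)) {
    fam <- as.character(f)
    seqs <- vector("list", Tn)
    term <- random_seq(spec$family_length)
    prot <- NULL
    if (!is.null(motif)) {
      mseq <- motif$sequence %||% random_seq(motif$length)
      term <- paste0(substr(term, 1, motif$start - 1), mseq,
                     substr(term, motif$start + nchar(mseq), nchar(term)))
      prot <- c(motif$start, motif$start + nchar(mseq) - 1L)
    }
    seqs[[Tn]] <- list(sequence = term, protect = prot)
    for (t in rev(seq_len(Tn - 1))) {
      seqs[[t]] <- mutate_seq(seqs[[t + 1]]$sequence, spec$substitution_rate,
                              spec$indel_rate, seqs[[t + 1]]$protect)
    }
    members[[f]] <- seqs

    del <- spec$deletions[[fam]] %||% integer()
    trunc <- spec$truncations[[fam]] %||% integer()
    par <- spec$paralogs[[fam]] %||% integer()

    exists_at <- setdiff(seq_len(Tn) - 1L, del)
    qt <- max(exists_at)
    qsrc <- seqs[[qt + 1]]
    qm <- mutate_seq(qsrc$sequence, spec$substitution_rate / 2, 0, qsrc$protect)
    queries[[f]] <- tibble(
      family = f, id = sprintf("QUERY_F%d", f), description = "synthetic query",
      sequence = qm$sequence, derived_from_taxon = qt,
      motif_start = (qm$protect %||% c(NA_integer_, NA))[1],
      motif_end = (qm$protect %||% c(NA, NA_integer_))[2]
    )

    truth[[f]] <- tibble(
      family = f,
      taxon_index = seq_len(Tn) - 1L,
      member_id = sprintf("F%d_T%02d", f, seq_len(Tn) - 1L),
      motif_start = map_int(seqs, function(s) (s$protect %||% NA_integer_)[1]),
      motif_end = map_int(seqs, function(s) (s$protect %||% c(NA_integer_, NA_integer_))[2]),
      paralog_id = NA_character_, anchor_id = NA_character_
    )
    truth[[f]]$member_id[truth[[f]]$taxon_index %in% del] <- NA_character_
    for (t in trunc) {
      ms <- truth[[f]]$motif_start[[t + 1]]
      seqs[[t + 1]]$sequence <- substr(seqs[[t + 1]]$sequence, 1, ms - 1L)
      seqs[[t + 1]]$protect <- NULL
      truth[[f]]$motif_start[[t + 1]] <- NA_integer_
      truth[[f]]$motif_end[[t + 1]] <- NA_integer_
    }
    members[[f]] <- seqs
    for (t in par) {
      truth[[f]]$paralog_id[[t + 1]] <- sprintf("F%d_T%02d_PAR", f, t)
      truth[[f]]$anchor_id[[t + 2]] <- sprintf("F%d_T%02d_ANCHOR", f, t + 1L)
    }
  }
  truth <- bind_rows(truth)
  queries <- bind_rows(queries)

  # assemble proteomes and write them out
  cfg <- tibble(taxon_index = seq_len(Tn) - 1L,
                taxon_name = sprintf("Taxon%02d", seq_len(Tn) - 1L),
                species_name = sprintf("Species %02d", seq_len(Tn) - 1L),
                fasta = sprintf("taxon%02d.fasta", seq_len(Tn) - 1L))
  extra <- rep(list(tibble(id = character(), description = character(),
                           sequence = character())), Tn)
  for (f in seq_len(spec$n_families)) {
    for (t in spec$paralogs[[as.character(f)]] %||% integer()) {
      anchor_seq <- random_seq(2L * spec$family_length)
      base <- mutate_seq(members[[f]][[t + 2]]$sequence,
                         spec$substitution_rate / 2, 0,
                         members[[f]][[t + 2]]$protect)
      # paralog (taxon t) wins the forward search as the least diverged
      # relative of the search query, but reciprocates to its anchor
      # (taxon t+1): a longer exact match that outscores any family member
      extra[[t + 1]] <- bind_rows(extra[[t + 1]], tibble(
        id = sprintf("F%d_T%02d_PAR", f, t), description = "planted paralog",
        sequence = paste0(base$sequence, anchor_seq)))
      extra[[t + 2]] <- bind_rows(extra[[t + 2]], tibble(
        id = sprintf("F%d_T%02d_ANCHOR", f, t + 1L),
        description = "paralog anchor", sequence = anchor_seq))
    }
  }
  for (t in seq_len(Tn) - 1L) {
    recs <- list()
    for (f in seq_len(spec$n_families)) {
      row <- truth[truth$family == f & truth$taxon_index == t, ]
      if (!is.na(row$member_id)) {
        recs <- c(recs, list(tibble(id = row$member_id,
                                    description = sprintf("family %d member", f),
                                    sequence = members[[f]][[t + 1]]$sequence)))
      }
    }
    here <- bind_rows(c(recs, list(extra[[t + 1]])))
    n_decoy <- max(0L, spec$proteome_size - nrow(here))
    if (n_decoy > 0) {
      here <- bind_rows(here, tibble(
        id = sprintf("T%02d_D%03d", t, seq_len(n_decoy)),
        description = "decoy",
        sequence = map_chr(seq_len(n_decoy),
                           function(i) random_seq(sample(60:120, 1)))
      ))
    }
    write_fasta(here, file.path(dir, sprintf("taxon%02d.fasta", t)))
  }
  utils::write.table(cfg, file.path(dir, "path.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_fasta(queries, file.path(dir, "queries.fasta"))
  jsonlite::write_json(truth, file.path(dir, "truth.json"), na = "null")

  list(path = read_path_config(file.path(dir, "path.tsv"), dir),
       queries = queries, truth = truth, dir = dir, spec = spec)
}

#' Generate query-side GO annotations from a term plan
#'
#' A term plan maps each GO term to a set of taxa; a query is annotated
#' with the term iff its family exists only within those taxa (so a
#' "clade-specific" plan annotates exactly the families restricted to that
#' clade, and a plan covering all taxa annotates every query).
#'
#' @param generated Result of [generate_path()].
#' @param term_plan Named list: GO term id -> integer vector of taxa.
#' @param file Optional TSV output path (`protein_id<TAB>GO_id`).
#' @return An `annotation_table` over the query proteins.
#' @export
generate_annotations <- function(generated, term_plan, file = NULL) {
  Tn <- n_taxa(generated$path)
  rows <- list()
  for (term in names(term_plan)) {
    taxa <- as.integer(term_plan[[term]])
    if (length(taxa) && (min(taxa) < 0 || max(taxa) >= Tn)) {
      abort(paste0("Term plan for ", term, " references unknown taxa."),
            class = "orthopath_spec_error")
    }
    for (f in unique(generated$truth$family)) {
      fam_taxa <- generated$truth$taxon_index[
        generated$truth$family == f & !is.na(generated$truth$member_id)]
      if (length(fam_taxa) && all(fam_taxa %in% taxa)) {
        qid <- generated$queries$id[generated$queries$family == f]
        rows <- c(rows, list(tibble(protein_id = qid, go_id = term)))
      }
    }
  }
  out <- if (length(rows)) distinct(bind_rows(rows)) else
    tibble(protein_id = character(), go_id = character())
  class(out) <- c("annotation_table", class(out))
  if (!is.null(file)) {
    utils::write.table(out, file, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
  }
  out
}
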