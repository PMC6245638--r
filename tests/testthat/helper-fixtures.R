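# Small in-code fixtures shared across test files.

rec <- function(id, sequence, proteome_id = NA_character_) {
  tibble::tibble(id = id, description = "", sequence = sequence,
                 proteome_id = proteome_id)
}

# A path of single-protein proteomes all holding the same sequence.
identical_path <- function(n = 4, sequence = strrep("MKVLLTAGHE", 4)) {
  taxa <- tibble::tibble(taxon_index = seq_len(n) - 1L,
                         taxon_name = sprintf("Taxon%02d", seq_len(n) - 1L),
                         species_name = sprintf("Sp%02d", seq_len(n) - 1L))
  proteomes <- lapply(seq_len(n) - 1L, function(t) {
    rec(sprintf("P_T%02d", t), sequence, sprintf("taxon%02d", t))
  })
  evo_path(taxa, proteomes, name = "identical")
}

# Write FASTA + config for a hand-built path; returns the config path.
write_path_fixture <- function(proteomes, dir = withr::local_tempdir(.local_envir = parent.frame())) {
  n <- length(proteomes)
  for (t in seq_len(n) - 1L) {
    write_fasta(proteomes[[t + 1L]], file.path(dir, sprintf("taxon%02d.fasta", t)))
  }
  cfg <- data.frame(taxon_index = seq_len(n) - 1L,
                    taxon_name = sprintf("Taxon%02d", seq_len(n) - 1L),
                    species_name = sprintf("Sp%02d", seq_len(n) - 1L),
                    fasta = sprintf("taxon%02d.fasta", seq_len(n) - 1L))
  utils::write.table(cfg, file.path(dir, "path.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  file.path(dir, "path.tsv")
}
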