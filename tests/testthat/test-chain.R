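test_that("a path of identical single-protein proteomes chains orthologs end to end", {
  p <- identical_path(4)
  # all members tie, so entry tie-breaks to the terminal-most taxon
  q <- rec("P_T03", strrep("MKVLLTAGHE", 4))
  ch <- trace_chain(q, p)
  expect_equal(ch$entry_taxon, 3)
  st <- dplyr::arrange(ch$steps, taxon_index)
  expect_equal(st$relation, c("ortholog", "ortholog", "ortholog", "query"))
  # each non-entry step searched with the previous taxon's hit
  expect_equal(st$search_query_id[st$taxon_index == 2], "P_T03")
  expect_equal(st$search_query_id[st$taxon_index == 1], "P_T02")
  expect_equal(st$search_query_id[st$taxon_index == 0], "P_T01")
})

test_that("entry lands on an exact self-match at its own taxon", {
  g <- generate_path(family_spec(n_taxa = 6, proteome_size = 6,
                                 family_length = 80, substitution_rate = 0.1,
                                 seed = 40))
  member <- proteome(g$path, 3)
  member <- member[member$id == "F1_T03", ]
  e <- find_entry(member[, c("id", "sequence")], g$path)
  expect_equal(e$entry_taxon, 3)
  expect_equal(e$relation, "query")
})

test_that("identical best scores at two taxa enter at the higher taxon", {
  seqv <- strrep("MKVLLTAGHE", 3)
  taxa <- tibble::tibble(taxon_index = 0:3,
                         taxon_name = paste0("t", 0:3),
                         species_name = paste0("s", 0:3))
  set.seed(41)
  prots <- list(rec("P0", random_peptide(30)),
                rec("TWIN1", seqv),
                rec("P2", random_peptide(30)),
                rec("TWIN9", seqv))
  p <- evo_path(taxa, prots)
  e <- find_entry(rec("Q", seqv), p)
  expect_equal(e$entry_taxon, 3)
})

test_that("a query with no passing hit anywhere raises an empty-chain error", {
  set.seed(42)
  p <- identical_path(3)
  expect_error(
    trace_chain(rec("Q", random_peptide(12)), p,
                search_params(evalue_cutoff = 1e-9)),
    class = "orthopath_empty_chain")
})

test_that("family deletion yields NONE and the next step reuses the last ortholog", {
  g <- generate_path(family_spec(n_taxa = 8, proteome_size = 10,
                                 family_length = 150, substitution_rate = 0.1,
                                 deletions = c(4), seed = 43))
  ch <- trace_chain(g$queries[1, c("id", "sequence")], g$path,
                    search_params(evalue_cutoff = 1e-6))
  st <- dplyr::arrange(ch$steps, taxon_index)
  expect_equal(st$relation[st$taxon_index == 4], "none")
  # descending from entry 7: step 3 is searched with the taxon-5 ortholog
  expect_equal(st$search_query_id[st$taxon_index == 3], "F1_T05")
  expect_equal(st$relation[st$taxon_index == 3], "ortholog")
})

test_that("an out-competing paralog is recorded as homolog and never seeds a search", {
  g <- generate_path(family_spec(n_taxa = 8, proteome_size = 10,
                                 family_length = 150, substitution_rate = 0.1,
                                 paralogs = c(3), seed = 44))
  ch <- trace_chain(g$queries[1, c("id", "sequence")], g$path)
  st <- dplyr::arrange(ch$steps, taxon_index)
  expect_equal(st$relation[st$taxon_index == 3], "homolog")
  expect_equal(st$hit_id[st$taxon_index == 3], "F1_T03_PAR")
  expect_false("F1_T03_PAR" %in% st$search_query_id)
  expect_equal(st$search_query_id[st$taxon_index == 2], "F1_T04")
})

test_that("chain reports render NA hits and round-trip through JSON", {
  g <- generate_path(family_spec(n_taxa = 5, proteome_size = 8,
                                 family_length = 120, substitution_rate = 0.1,
                                 deletions = c(2), seed = 45))
  ch <- trace_chain(g$queries[1, c("id", "sequence")], g$path,
                    search_params(evalue_cutoff = 1e-6))
  prefix <- file.path(withr::local_tempdir(), "run")
  files <- write_chain_report(ch, prefix)
  tsv <- utils::read.delim(files[["tsv"]], na.strings = "NA")
  expect_equal(nrow(tsv), 5)
  expect_true(is.na(tsv$hit_id[tsv$taxon_index == 2]))
  back <- read_chain_report(files[["json"]])
  expect_equal(back$entry_taxon, ch$entry_taxon)
  expect_equal(back$query, ch$query)
  expect_equal(as.data.frame(back$steps), as.data.frame(ch$steps))
  expect_equal(back$params, ch$params)
})

test_that("validate_chain rejects a homolog used as a search query", {
  p <- identical_path(4)
  ch <- trace_chain(rec("P_T03", strrep("MKVLLTAGHE", 4)), p)
  ch$steps$search_query_id[ch$steps$taxon_index == 1] <- "NOT_THE_ORTHOLOG"
  expect_error(validate_chain(ch), class = "orthopath_chain_error")
})

test_that("tidy and glance summarise a chain", {
  p <- identical_path(3)
  ch <- trace_chain(rec("P_T02", strrep("MKVLLTAGHE", 4)), p)
  td <- tidy(ch)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 3)
  gl <- glance(ch)
  expect_equal(gl$n_ortholog, 2)
  expect_equal(gl$entry_taxon, 2)
})
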