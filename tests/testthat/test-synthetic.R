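test_that("zero divergence produces identical members and an all-ortholog chain", {
  g <- generate_path(family_spec(n_taxa = 5, proteome_size = 6,
                                 family_length = 100, substitution_rate = 0,
                                 seed = 100))
  members <- vapply(0:4, function(t) {
    p <- proteome(g$path, t)
    p$sequence[p$id == sprintf("F1_T%02d", t)]
  }, character(1))
  expect_equal(length(unique(members)), 1)
  ch <- trace_chain(g$queries[1, c("id", "sequence")], g$path)
  expect_true(all(ch$steps$relation == "ortholog"))
})

test_that("the same seed reproduces byte-identical outputs", {
  spec <- family_spec(n_taxa = 4, proteome_size = 6, family_length = 90,
                      substitution_rate = 0.1, indel_rate = 0.01,
                      motif = list(start = 30, length = 20), seed = 101)
  g1 <- generate_path(spec, dir = withr::local_tempdir())
  g2 <- generate_path(spec, dir = withr::local_tempdir())
  for (f in c("taxon00.fasta", "taxon03.fasta", "path.tsv", "queries.fasta")) {
    expect_identical(readLines(file.path(g1$dir, f)),
                     readLines(file.path(g2$dir, f)))
  }
  expect_identical(g1$truth, g2$truth)
})

test_that("adjacent members diverge at about the substitution rate, decaying with distance", {
  ident <- function(a, b) {
    av <- strsplit(a, "")[[1]]; bv <- strsplit(b, "")[[1]]
    mean(av == bv)
  }
  adj <- c()
  far <- c()
  for (seed in 1:10) {
    g <- generate_path(family_spec(n_taxa = 15, proteome_size = 1,
                                   family_length = 200, substitution_rate = 0.1,
                                   seed = 200 + seed))
    mem <- vapply(0:14, function(t) {
      p <- proteome(g$path, t)
      p$sequence[p$id == sprintf("F1_T%02d", t)]
    }, character(1))
    adj <- c(adj, vapply(1:14, function(i) ident(mem[[i]], mem[[i + 1]]), 1))
    far <- c(far, ident(mem[[1]], mem[[15]]))
  }
  expect_equal(mean(adj), 0.9, tolerance = 0.03)
  # identity decays with taxon distance
  expect_lt(mean(far), mean(adj) - 0.2)
})

test_that("contradictory or invalid specs are rejected", {
  expect_error(family_spec(seed = 1, substitution_rate = 1.2),
               class = "orthopath_spec_error")
  expect_error(family_spec(substitution_rate = 0.1),
               class = "orthopath_spec_error") # seed mandatory
  expect_error(family_spec(seed = 1, motif = list(start = 190, length = 20),
                           family_length = 200),
               class = "orthopath_spec_error")
  expect_error(family_spec(seed = 1, deletions = c(3), truncations = c(3),
                           motif = list(start = 50, length = 20)),
               class = "orthopath_spec_error")
  expect_error(family_spec(seed = 1, n_taxa = 5, paralogs = c(4)),
               class = "orthopath_spec_error")
  expect_error(family_spec(seed = 1, truncations = c(2)),
               class = "orthopath_spec_error") # truncation without motif
})

test_that("annotation plans annotate exactly the families inside their taxa", {
  g <- generate_path(family_spec(n_taxa = 6, proteome_size = 4,
                                 family_length = 80, n_families = 3,
                                 deletions = list("2" = c(0, 1, 5)),
                                 seed = 103))
  f <- withr::local_tempfile(fileext = ".tsv")
  anns <- generate_annotations(
    g, list("GO:0000010" = 2:4, "GO:0000011" = 0:5), file = f)
  expect_equal(term_proteins(anns, "GO:0000010"), "QUERY_F2")
  expect_setequal(term_proteins(anns, "GO:0000011"),
                  c("QUERY_F1", "QUERY_F2", "QUERY_F3"))
  expect_equal(nrow(anns), 4)
  back <- read_annotations(f)
  expect_equal(dplyr::arrange(as.data.frame(back), protein_id, go_id),
               dplyr::arrange(as.data.frame(anns), protein_id, go_id))
  # empty plan -> empty table
  empty <- generate_annotations(g, list())
  expect_equal(nrow(empty), 0)
  expect_error(generate_annotations(g, list("GO:0000012" = c(9))),
               class = "orthopath_spec_error")
})

test_that("all generator randomness flows from the spec seed", {
  spec <- family_spec(n_taxa = 4, proteome_size = 5, family_length = 80,
                      substitution_rate = 0.1, seed = 104)
  set.seed(1); g1 <- generate_path(spec, dir = withr::local_tempdir())
  set.seed(999); g2 <- generate_path(spec, dir = withr::local_tempdir())
  expect_identical(g1$queries$sequence, g2$queries$sequence)
  expect_identical(proteome(g1$path, 0)$sequence, proteome(g2$path, 0)$sequence)
})
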