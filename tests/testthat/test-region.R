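test_that("region length validation enforces the 10-100 aa interval", {
  owner <- rec("Q", random_peptide(150))
  expect_silent(validate_region(locked_region("Q", 22, 60), owner)) # 39 aa
  expect_error(validate_region(locked_region("Q", 1, 9), owner),
               class = "orthopath_region_length")
  expect_error(validate_region(locked_region("Q", 1, 101), owner),
               class = "orthopath_region_length")
  expect_error(validate_region(locked_region("Q", 140, 160), owner),
               class = "orthopath_region_bounds")
  expect_error(locked_region("Q", 10, 5), class = "orthopath_region_bounds")
})

test_that("identity alignments project a region onto itself", {
  set.seed(50)
  s <- random_peptide(100)
  aln <- local_align(s, s)
  m <- map_region(22, 60, aln, 0.75)
  expect_true(m$mapped)
  expect_equal(m$mapped_start, 22)
  expect_equal(m$mapped_end, 60)
  expect_equal(m$coverage, 1.0)
  expect_equal(m$subsequence, substr(s, 22, 60))
  expect_equal(m$column_residues, substr(s, 22, 60))
})

test_that("a 12-residue subject gap inside a 39-residue region fails a 75% threshold", {
  # hand-built alignment: query 1..60 ungapped, subject gapped under
  # query positions 30..41 (12 of region 22..60 face gaps)
  q <- random_peptide(60)
  s_left <- substr(q, 1, 29)
  s_right <- substr(q, 42, 60)
  aln <- tibble::tibble(
    query_aligned = q,
    subject_aligned = paste0(s_left, strrep("-", 12), s_right),
    query_start = 1L, query_end = 60L,
    subject_start = 1L, subject_end = 48L
  )
  m <- map_region(22, 60, aln, 0.75)
  expect_equal(m$coverage, 27 / 39)
  expect_false(m$mapped)
  m0 <- map_region(22, 60, aln, 0)
  expect_true(m0$mapped)
})

test_that("a region outside the aligned query range has coverage zero", {
  s <- random_peptide(80)
  aln <- tibble::tibble(query_aligned = substr(s, 1, 30),
                        subject_aligned = substr(s, 1, 30),
                        query_start = 1L, query_end = 30L,
                        subject_start = 1L, subject_end = 30L)
  m <- map_region(40, 60, aln, 0.75)
  expect_false(m$mapped)
  expect_equal(m$coverage, 0)
})

test_that("identity chains map the locked region unchanged at every step", {
  p <- identical_path(5, sequence = strrep("MKVLLTAGHE", 6))
  ch <- trace_chain(rec("P_T04", strrep("MKVLLTAGHE", 6)), p)
  maps <- propagate_region(ch, locked_region("P_T04", 11, 40))
  expect_equal(nrow(maps), 5)
  expect_true(all(maps$mapped))
  expect_true(all(maps$coverage == 1))
  expect_true(all(maps$mapped_start == 11))
  expect_true(all(maps$mapped_end == 40))
})

test_that("a fragment step is unmapped and downstream steps rescue at planted coordinates", {
  ok <- 0L
  for (seed in 1:8) {
    g <- generate_path(family_spec(
      n_taxa = 8, proteome_size = 8, family_length = 160,
      substitution_rate = 0.1, indel_rate = 0.005,
      motif = list(start = 80, length = 30), truncations = c(4),
      seed = 60 + seed))
    q <- g$queries[1, ]
    ch <- trace_chain(q[, c("id", "sequence")], g$path)
    maps <- propagate_region(ch, locked_region(q$id, q$motif_start, q$motif_end))
    frag <- maps[maps$taxon_index == 4, ]
    below <- maps[maps$taxon_index < 4, ]
    truth <- g$truth[g$truth$taxon_index < 4, ]
    hit_truth <- dplyr::left_join(below, truth, by = "taxon_index")
    good <- !frag$mapped && all(below$mapped) &&
      all(abs(hit_truth$mapped_start - hit_truth$motif_start) <= 2) &&
      all(abs(hit_truth$mapped_end - hit_truth$motif_end) <= 2)
    ok <- ok + as.integer(good)
  }
  expect_gte(ok, 7)
})

test_that("re-locking from a chain ortholog triggers no new searches", {
  g <- generate_path(family_spec(n_taxa = 6, proteome_size = 8,
                                 family_length = 120, substitution_rate = 0.08,
                                 seed = 70))
  ch <- trace_chain(g$queries[1, c("id", "sequence")], g$path)
  orthopath:::reset_backend_calls()
  maps <- propagate_region(ch, locked_region("F1_T03", 30, 70))
  expect_identical(orthopath:::backend_call_count(), 0L)
  expect_equal(nrow(maps), 6)
  expect_true(maps$mapped[maps$protein_id == "F1_T03"])
  expect_true(sum(maps$mapped) >= 5)
})

test_that("mapped subsequences are never shorter than the coverage floor", {
  set.seed(51)
  for (i in 1:10) {
    a <- random_peptide(90)
    # a diverged relative of `a`: long alignments with scattered mismatches
    bv <- strsplit(a, "")[[1]]
    flip <- sample(90, 20)
    for (j in flip) bv[[j]] <- sample(setdiff(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], bv[[j]]), 1)
    aln <- local_align(a, paste(bv, collapse = ""))
    expect_gte(aln$query_end - aln$query_start, 30)
    m <- map_region(aln$query_start, aln$query_start + 29L, aln, 0.5)
    expect_gte(m$coverage, 0)
    expect_lte(m$coverage, 1)
    expect_true(m$mapped)
    expect_gte(nchar(gsub("-", "", m$column_residues)), ceiling(0.5 * 30))
  }
})
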