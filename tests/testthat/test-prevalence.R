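# Hand-built presence matrix helper: rows = queries, cols = taxa 0..T-1.
presence_fixture <- function(m) {
  structure(m, class = c("presence_matrix", "matrix", "array"))
}

test_that("presence rows mirror chain relations, with NA at the query taxon", {
  p <- identical_path(4)
  ch <- trace_chain(rec("P_T03", strrep("MKVLLTAGHE", 4)), p)
  pres <- build_presence(list(ch))
  expect_equal(unname(pres[1, 1:3]), rep(TRUE, 3))
  expect_true(is.na(pres[1, 4])) # the query's own step
})

test_that("NONE steps appear as FALSE in the presence matrix", {
  g <- generate_path(family_spec(n_taxa = 6, proteome_size = 8,
                                 family_length = 120, substitution_rate = 0.1,
                                 deletions = c(2), seed = 90))
  ch <- trace_chain(g$queries[1, c("id", "sequence")], g$path,
                    search_params(evalue_cutoff = 1e-6))
  pres <- build_presence(list(ch))
  expect_false(pres[1, "2"])
  expect_true(pres[1, "1"])
})

test_that("chains from different paths refuse to combine", {
  ch1 <- trace_chain(rec("P_T01", strrep("MKVLLTAGHE", 4)), identical_path(3))
  p2 <- identical_path(4)
  p2$name <- "other"
  ch2 <- trace_chain(rec("P_T01", strrep("MKVLLTAGHE", 4)), p2)
  expect_error(build_presence(list(ch1, ch2)),
               class = "orthopath_prevalence_error")
})

test_that("term ratios equal hand-counted fractions", {
  m <- presence_fixture(matrix(
    c(TRUE, TRUE, FALSE, NA,
      TRUE, FALSE, FALSE, NA,
      TRUE, TRUE, TRUE, NA,
      FALSE, TRUE, TRUE, NA,
      TRUE, TRUE, FALSE, NA),
    nrow = 5, byrow = TRUE,
    dimnames = list(paste0("Q", 1:5), as.character(0:3))))
  anns <- read_annotations(c("Q1\tGO:0000001", "Q2\tGO:0000001",
                             "Q3\tGO:0000001", "Q4\tGO:0000001",
                             "Q5\tGO:0000001", "Q9\tGO:0000001",
                             "Q1\tGO:0000002"))
  tr <- term_ratio("GO:0000001", m, anns)
  expect_equal(tr$ratio, c(4/5, 4/5, 2/5, NA))
  expect_equal(tr$n_queries, rep(5L, 4))
  # the 'all queries' denominator divides by every row instead
  tr1 <- term_ratio("GO:0000002", m, anns, denominator = "all")
  expect_equal(tr1$ratio, c(1/5, 1/5, 0, NA))
})

test_that("queries not annotated with a term never change its ratios", {
  m <- presence_fixture(matrix(c(TRUE, FALSE, NA,
                                 FALSE, TRUE, NA),
                               nrow = 2, byrow = TRUE,
                               dimnames = list(c("Q1", "Q2"), as.character(0:2))))
  anns <- read_annotations(c("Q1\tGO:0000001"))
  before <- term_ratio("GO:0000001", m, anns)$ratio
  m2 <- presence_fixture(rbind(m, Q3 = c(TRUE, TRUE, NA)))
  after <- term_ratio("GO:0000001", m2, anns)$ratio
  expect_equal(before, after)
})

test_that("flipping one presence cell raises exactly that taxon's ratio by 1/n", {
  set.seed(91)
  for (i in 1:10) {
    nq <- sample(3:8, 1)
    nt <- sample(3:6, 1)
    m <- matrix(sample(c(TRUE, FALSE), nq * nt, replace = TRUE), nrow = nq,
                dimnames = list(paste0("Q", seq_len(nq)), as.character(seq_len(nt) - 1L)))
    anns <- read_annotations(paste0("Q", seq_len(nq), "\tGO:0000001"))
    pm <- presence_fixture(m)
    base <- term_ratio("GO:0000001", pm, anns)$ratio
    r <- sample(nq, 1)
    off <- which(!m[r, ])
    if (!length(off)) next
    cidx <- off[[sample.int(length(off), 1)]]
    m2 <- m
    m2[r, cidx] <- TRUE
    flipped <- term_ratio("GO:0000001", presence_fixture(m2), anns)$ratio
    delta <- flipped - base
    expect_equal(delta[[cidx]], 1 / nq)
    expect_equal(delta[-cidx], rep(0, nt - 1))
  }
})

test_that("a term annotating no query signals an empty result", {
  m <- presence_fixture(matrix(TRUE, 1, 2, dimnames = list("Q1", c("0", "1"))))
  anns <- read_annotations(c("Q1\tGO:0000001"))
  expect_error(term_ratio("GO:0009999", m, anns), class = "orthopath_empty_term")
})

test_that("prevalence reports order by term then taxon and round-trip", {
  m <- presence_fixture(matrix(c(TRUE, FALSE, NA), 1, 3,
                               dimnames = list("Q1", as.character(0:2))))
  anns <- read_annotations(c("Q1\tGO:0000002", "Q1\tGO:0000001"))
  f <- withr::local_tempfile(fileext = ".tsv")
  rep <- prevalence_report(c("GO:0000002", "GO:0000001"), m, anns, file = f)
  expect_equal(nrow(rep), 6)
  expect_equal(rep$term, rep(c("GO:0000001", "GO:0000002"), each = 3))
  back <- read_prevalence(f)
  expect_equal(back$ratio, rep$ratio)
  expect_true(is.na(back$ratio[back$taxon_index == 2][1]))
})

test_that("a clade-restricted family yields zero ratios outside its clade", {
  # family 2 exists only in taxa 3-5; family 1 spans the whole path
  g <- generate_path(family_spec(
    n_taxa = 7, proteome_size = 8, family_length = 120,
    substitution_rate = 0.08, n_families = 2,
    deletions = list("2" = c(0, 1, 2, 6)), seed = 92))
  chains <- lapply(seq_len(2), function(f) {
    q <- g$queries[g$queries$family == f, c("id", "sequence")]
    trace_chain(q, g$path, search_params(evalue_cutoff = 1e-6))
  })
  pres <- build_presence(chains)
  anns <- generate_annotations(g, list("GO:0000003" = 3:5,
                                       "GO:0000004" = 0:6))
  # the clade term annotates only the restricted family's query
  expect_equal(term_proteins(anns, "GO:0000003"), "QUERY_F2")
  tr <- term_ratio("GO:0000003", pres, anns)
  outside <- tr$ratio[tr$taxon_index %in% c(0, 1, 2, 6)]
  expect_equal(outside[!is.na(outside)], rep(0, sum(!is.na(outside))))
  inside <- tr$ratio[tr$taxon_index %in% 3:5]
  expect_true(all(inside[!is.na(inside)] > 0))
})
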