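# Independent brute-force affine-gap local-alignment oracle (Gotoh
# three-state DP, score only).  Written against the recurrence directly and
# kept free of any package code so it can stand as the second route in
# oracle-equivalence tests.
sw_oracle <- function(a, b, mat, gap_open = 11, gap_extend = 1) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  m <- length(av)
  n <- length(bv)
  NEG <- -1e9
  M <- matrix(0, m + 1, n + 1)   # alignment ends in a substitution
  X <- matrix(NEG, m + 1, n + 1) # ends in a gap in b (a-residue vs -)
  Y <- matrix(NEG, m + 1, n + 1) # ends in a gap in a
  best <- 0
  for (i in seq_len(m)) {
    for (j in seq_len(n)) {
      s <- mat[av[[i]], bv[[j]]]
      M[i + 1, j + 1] <- max(0,
                             M[i, j] + s,
                             X[i, j] + s,
                             Y[i, j] + s)
      X[i + 1, j + 1] <- max(M[i, j + 1] - gap_open - gap_extend,
                             X[i, j + 1] - gap_extend)
      Y[i + 1, j + 1] <- max(M[i + 1, j] - gap_open - gap_extend,
                             Y[i + 1, j] - gap_extend)
      best <- max(best, M[i + 1, j + 1])
    }
  }
  best
}

oracle_matrix <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
})

random_peptide <- function(n) {
  paste(sample(c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V"),
               n, replace = TRUE), collapse = "")
}
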