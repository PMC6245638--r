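#' @importFrom rlang abort warn .data
#' @importFrom tibble tibble as_tibble
#' @import dplyr
#' @importFrom purrr map map_chr map_int map_dbl map_lgl imap pmap
#' @importFrom stats setNames rbinom rgeom runif
#' @importFrom utils head tail
NULL

# The 20 standard amino acids, plus X for any unknown/non-standard residue.
AA_ALPHABET <- c("A","R","N","D","C","Q","E","G","H","I",
                 "L","K","M","F","P","S","T","W","Y","V")
AA_ALLOWED <- c(AA_ALPHABET, "X")

# Residues outside the standard 20 that real proteomes contain; mapped to X
# at load time so the aligner stays total.
AA_REMAP <- c("U", "B", "Z", "O")

`%||%` <- function(x, y) if (is.null(x)) y else x

# Counter for backend (alignment) searches; region re-locking must never
# touch it, and tests assert on that.
.backend <- new.env(parent = emptyenv())
.backend$calls <- 0L

backend_call_count <- function() .backend$calls
reset_backend_calls <- function() {
  .backend$calls <- 0L
  invisible(NULL)
}
note_backend_call <- function(n = 1L) {
  .backend$calls <- .backend$calls + as.integer(n)
  invisible(NULL)
}

#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
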