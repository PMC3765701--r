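#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over plain character vectors. Non-ACGT
#' symbols other than N are rejected upstream; N maps to N.
#'
#' @param x character vector of DNA sequences.
#' @return character vector of the same length.
#' @export
revcomp <- function(x) {
  vapply(x, function(s) {
    chartr("ACGTN", "TGCAN", intToUtf8(rev(utf8ToInt(s))))
  }, character(1), USE.NAMES = FALSE)
}

#' Phred scores of a quality string
#'
#' @param qual phred+33 encoded quality string.
#' @return integer vector of phred scores.
#' @export
phred_scores <- function(qual) {
  utf8ToInt(qual) - 33L
}

#' @noRd
phred_symbol <- function(q) intToUtf8(q + 33L)

# Hamming distance between two equal-length strings.
#' @noRd
hamming <- function(a, b) {
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# All k-mers of a string as a character vector (empty if too short).
#' @noRd
kmers <- function(s, k) {
  n <- nchar(s)
  if (n < k) return(character(0))
  substring(s, seq_len(n - k + 1L), seq_len(n - k + 1L) + k - 1L)
}

# Run expr with a temporary RNG seed, restoring the caller's RNG state.
#' @noRd
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Derive a stage-specific sub-seed from the master seed; kept < 2^31.
#' @noRd
sub_seed <- function(seed, offset) {
  (as.numeric(seed) * 1009 + offset) %% 2147483647
}

#' @noRd
stop_config <- function(...) {
  stop(sprintf(...), call. = FALSE)
}
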