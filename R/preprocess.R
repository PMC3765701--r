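#' Demultiplex pooled reads by inline barcode
#'
#' The first `barcode_len` bases of read 1 are matched exactly (0 mismatches)
#' against the barcode set; matching pairs are assigned to that line and the
#' barcode is trimmed from read 1's sequence and quality. Exact matching is
#' safe because the barcode set has pairwise Hamming distance >= 2.
#'
#' @param reads pooled read-pair table (columns `read_id`, `seq1`, `qual1`,
#'   `seq2`, `qual2`; any others are carried through).
#' @param barcodes named character vector, names = line ids.
#' @return list with `stores` (per-line read tables, barcode trimmed) and
#'   `report` (per-barcode pair counts plus the unassigned count).
#' @export
demultiplex <- function(reads, barcodes) {
  if (length(barcodes) == 0) stop_config("empty barcode map")
  if (is.null(names(barcodes)) || any(!nzchar(names(barcodes))))
    stop_config("barcodes must be named by line id")
  blen <- unique(nchar(barcodes))
  if (length(blen) != 1) stop_config("barcodes must have equal length")
  check_barcode_set(barcodes, blen)

  prefix <- substr(reads$seq1, 1L, blen)
  line <- names(barcodes)[match(prefix, barcodes)]
  assigned <- !is.na(line)

  stores <- lapply(names(barcodes), function(l) {
    s <- reads[assigned & line == l, , drop = FALSE]
    s$seq1 <- substring(s$seq1, blen + 1L)
    s$qual1 <- substring(s$qual1, blen + 1L)
    rownames(s) <- NULL
    s
  })
  names(stores) <- names(barcodes)

  report <- data.frame(
    line_id = names(barcodes), barcode = unname(barcodes),
    n_pairs = vapply(stores, nrow, integer(1)), row.names = NULL)
  list(stores = stores,
       report = list(per_line = report,
                     n_input = nrow(reads),
                     n_assigned = sum(assigned),
                     n_unassigned = sum(!assigned)))
}

# mean phred over the last `tail_len` bases of one quality string
#' @noRd
tail_mean_q <- function(qual, tail_len) {
  n <- nchar(qual)
  if (n < tail_len) return(NA_real_)
  mean(phred_scores(substring(qual, n - tail_len + 1L, n)))
}

#' Tail-quality filter for read pairs
#'
#' A pair is discarded when the mean phred score over the last `tail_len`
#' bases of either mate falls below `min_q` (strictly below: a mean of
#' exactly `min_q` is kept). Reads shorter than the tail window are
#' discarded with a warning.
#'
#' @param store per-line read table (post-demultiplexing).
#' @param min_q phred threshold (default Q20).
#' @param tail_len tail window in bases (default 5).
#' @return list with `kept` (filtered table), `n_discarded`, and the
#'   per-pair logical `keep`.
#' @export
quality_filter <- function(store, min_q = 20, tail_len = 5L) {
  if (nrow(store) == 0)
    return(list(kept = store, n_discarded = 0L, keep = logical(0)))
  m1 <- vapply(store$qual1, tail_mean_q, numeric(1), tail_len = tail_len,
               USE.NAMES = FALSE)
  m2 <- vapply(store$qual2, tail_mean_q, numeric(1), tail_len = tail_len,
               USE.NAMES = FALSE)
  short <- is.na(m1) | is.na(m2)
  if (any(short))
    warning(sprintf("%d pairs shorter than the %d nt tail window discarded",
                    sum(short), tail_len))
  keep <- !short & m1 >= min_q & m2 >= min_q
  kept <- store[keep, , drop = FALSE]
  rownames(kept) <- NULL
  list(kept = kept, n_discarded = sum(!keep), keep = keep)
}
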