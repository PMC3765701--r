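#' Build an exact-seed index over reference contigs
#'
#' Hashes every `seed_len`-mer of the forward strand of each contig to its
#' (contig, offset) locations. Reverse-strand placements are found at query
#' time by also looking up the reverse-complemented read, so the index holds
#' one strand only.
#'
#' @param contigs contig table (`contig_id`, `sequence`); rows with a
#'   `flag` column are restricted to `flag == "retained"`.
#' @param seed_len exact seed length (default 20; must be >= 8 and no longer
#'   than the shortest contig).
#' @return object of class `seed_index`.
#' @export
build_index <- function(contigs, seed_len = 20L) {
  if (!is.null(contigs$flag))
    contigs <- contigs[contigs$flag == "retained", , drop = FALSE]
  if (nrow(contigs) == 0) stop_config("no contigs to index")
  if (seed_len < 8) stop_config("seed_len must be >= 8")
  if (seed_len > min(nchar(contigs$sequence)))
    stop_config("seed_len exceeds the shortest contig")

  env <- new.env(parent = emptyenv())
  for (ci in seq_len(nrow(contigs))) {
    s <- contigs$sequence[ci]
    n <- nchar(s)
    starts <- seq_len(n - seed_len + 1L)
    ks <- substring(s, starts, starts + seed_len - 1L)
    for (i in seq_along(ks)) {
      prev <- get0(ks[i], envir = env)
      entry <- c(ci, starts[i] - 1L)
      assign(ks[i], if (is.null(prev)) matrix(entry, ncol = 2)
                    else rbind(prev, entry), envir = env)
    }
  }
  structure(list(env = env, seed_len = as.integer(seed_len),
                 contig_id = contigs$contig_id,
                 sequence = contigs$sequence,
                 contig_len = nchar(contigs$sequence)),
            class = "seed_index")
}

#' Look up exact seed hits
#'
#' @param index a [build_index()] result.
#' @param seed a sequence of length `index$seed_len`.
#' @return matrix with columns (contig index, 0-based offset); zero rows if
#'   the seed is absent.
#' @export
seed_hits <- function(index, seed) {
  h <- get0(seed, envir = index$env)
  if (is.null(h)) matrix(integer(0), ncol = 2) else h
}

#' Map one sheared-end read against the reference
#'
#' Seed-and-extend with end-to-end (ungapped, Hamming) comparison. Disjoint
#' seeds tile the read, so any placement with at most `max_mismatches`
#' mismatches has at least one exact seed. Among qualifying placements:
#' hits on more than one contig are discarded as `multi`; equal-best
#' placements on a single contig as `ambiguous`; no placement (including
#' reads overhanging a contig end) as `unmapped`.
#'
#' @param read read sequence (its full length is aligned).
#' @param index a [build_index()] result.
#' @param max_mismatches maximum Hamming mismatches (default 3).
#' @return list: either `list(mapped = TRUE, contig_id, contig, start,
#'   strand, mismatches)` (0-based `start`) or
#'   `list(mapped = FALSE, reason)`.
#' @export
map_read <- function(read, index, max_mismatches = 3L) {
  sl <- index$seed_len
  rl <- nchar(read)
  offsets <- seq(0L, rl - sl, by = sl)
  cand <- list()
  for (strand in c("+", "-")) {
    oriented <- if (strand == "+") read else revcomp(read)
    for (off in offsets) {
      h <- seed_hits(index, substr(oriented, off + 1L, off + sl))
      if (nrow(h) == 0) next
      for (r in seq_len(nrow(h))) {
        ci <- h[r, 1]; start <- h[r, 2] - off
        if (start < 0 || start + rl > index$contig_len[ci]) next
        key <- paste(ci, start, strand)
        if (!is.null(cand[[key]])) next
        mm <- hamming(oriented,
                      substr(index$sequence[ci], start + 1L, start + rl))
        if (mm <= max_mismatches)
          cand[[key]] <- list(ci = ci, start = start, strand = strand,
                              mm = mm)
      }
    }
  }
  if (length(cand) == 0) return(list(mapped = FALSE, reason = "unmapped"))
  cis <- vapply(cand, `[[`, numeric(1), "ci")
  if (length(unique(cis)) > 1) return(list(mapped = FALSE, reason = "multi"))
  mms <- vapply(cand, `[[`, numeric(1), "mm")
  best <- which(mms == min(mms))
  if (length(best) > 1) return(list(mapped = FALSE, reason = "ambiguous"))
  b <- cand[[best]]
  list(mapped = TRUE, contig_id = index$contig_id[b$ci], contig = b$ci,
       start = b$start, strand = b$strand, mismatches = b$mm)
}

#' Map a line's sheared-end mates
#'
#' Applies [map_read()] to every mate of a read store and keeps the oriented
#' sequence and quality of accepted alignments for pileup construction.
#'
#' @param store per-line read table (post quality filter).
#' @param index a [build_index()] result.
#' @param line_id line identifier stamped into the records.
#' @param max_mismatches maximum Hamming mismatches (default 3).
#' @return list with `alignments` (data frame: `read_id`, `line_id`,
#'   `contig_id`, `start`, `strand`, `mismatches`, `oriented_seq`,
#'   `oriented_qual`) and `report` (accepted / unmapped / multi / ambiguous
#'   counts).
#' @export
align_reads <- function(store, index, line_id, max_mismatches = 3L) {
  n <- nrow(store)
  rows <- vector("list", n)
  reasons <- c(unmapped = 0L, multi = 0L, ambiguous = 0L)
  for (i in seq_len(n)) {
    m <- map_read(store$seq2[i], index, max_mismatches = max_mismatches)
    if (!m$mapped) {
      reasons[m$reason] <- reasons[m$reason] + 1L
      next
    }
    minus <- m$strand == "-"
    rows[[i]] <- data.frame(
      read_id = store$read_id[i], line_id = line_id,
      contig_id = m$contig_id, start = m$start, strand = m$strand,
      mismatches = m$mismatches,
      oriented_seq = if (minus) revcomp(store$seq2[i]) else store$seq2[i],
      oriented_qual = if (minus) intToUtf8(rev(utf8ToInt(store$qual2[i])))
                      else store$qual2[i],
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1))]
  alignments <- if (length(rows)) do.call(rbind, rows)
                else data.frame(read_id = character(0),
                                line_id = character(0),
                                contig_id = character(0), start = integer(0),
                                strand = character(0),
                                mismatches = integer(0),
                                oriented_seq = character(0),
                                oriented_qual = character(0))
  rownames(alignments) <- NULL
  list(alignments = alignments,
       report = list(n_reads = n, n_accepted = nrow(alignments),
                     n_unmapped = reasons[["unmapped"]],
                     n_multi = reasons[["multi"]],
                     n_ambiguous = reasons[["ambiguous"]]))
}

#' Build per-line pileups over the reference
#'
#' Accumulates per-position base counts for one line from its accepted
#' alignments. Reverse-strand reads contribute their reverse-complemented
#' (reference-oriented) bases. Bases below `min_base_qual` are excluded
#' from the counts, mirroring standard pileup practice.
#'
#' @param alignments alignment table from [align_reads()] (one line).
#' @param contigs reference contig table (`contig_id`, `sequence`).
#' @param min_base_qual minimum phred base quality counted (default 13).
#' @return named list (by `contig_id`) of 4 x contig-length count matrices
#'   with rownames A, C, G, T.
#' @export
build_pileups <- function(alignments, contigs, min_base_qual = 13L) {
  if (!is.null(contigs$flag))
    contigs <- contigs[contigs$flag == "retained", , drop = FALSE]
  piles <- lapply(nchar(contigs$sequence), function(n)
    matrix(0L, nrow = 4, ncol = n, dimnames = list(c("A", "C", "G", "T"),
                                                   NULL)))
  names(piles) <- contigs$contig_id
  clen <- stats::setNames(nchar(contigs$sequence), contigs$contig_id)
  base_idx <- integer(128)
  base_idx[utf8ToInt("A")] <- 1L; base_idx[utf8ToInt("C")] <- 2L
  base_idx[utf8ToInt("G")] <- 3L; base_idx[utf8ToInt("T")] <- 4L

  for (i in seq_len(nrow(alignments))) {
    cid <- alignments$contig_id[i]
    if (is.null(piles[[cid]])) stop("alignment to unknown contig")
    b <- utf8ToInt(alignments$oriented_seq[i])
    q <- utf8ToInt(alignments$oriented_qual[i]) - 33L
    pos <- alignments$start[i] + seq_along(b)   # 1-based columns
    if (pos[length(pos)] > clen[[cid]])
      stop("alignment exceeds contig bounds")
    bi <- base_idx[b]
    ok <- q >= min_base_qual & bi > 0L
    if (!any(ok)) next
    idx <- cbind(bi[ok], pos[ok])
    piles[[cid]][idx] <- piles[[cid]][idx] + 1L
  }
  piles
}
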