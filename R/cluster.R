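#' Cluster reads into RAD loci by exact single-end identity
#'
#' Reads sharing a byte-identical (barcode-trimmed) read-1 sequence form one
#' RAD locus. Loci with depth below `min_depth` suffer from thin paired-end
#' coverage and assemble poorly; loci above `max_depth` are suspected
#' high-copy contamination (plastid DNA, repeats) and are likewise excluded.
#'
#' @param store per-line read table (demultiplexed, quality filtered).
#' @param min_depth,max_depth inclusive depth gates (defaults 50 and 750).
#' @return list with `loci` (kept loci in lexicographic `se_key` order, each
#'   carrying `locus_id`, `se_key`, `depth` and its mates' `seq2`/`qual2`)
#'   and `report` (input reads, total/below/above/kept locus counts, and
#'   retained vs gated-out read totals).
#' @export
cluster_loci <- function(store, min_depth = 50L, max_depth = 750L) {
  groups <- split(seq_len(nrow(store)), store$seq1)
  keys <- names(groups)
  o <- order(keys, method = "radix")
  groups <- groups[o]
  keys <- keys[o]
  depth <- lengths(groups)

  below <- depth < min_depth
  above <- depth > max_depth
  kept_idx <- which(!below & !above)

  loci <- lapply(seq_along(kept_idx), function(j) {
    i <- kept_idx[j]
    rows <- groups[[i]]
    list(locus_id = sprintf("locus%06d", j),
         se_key = keys[i], depth = length(rows),
         mates = data.frame(read_id = store$read_id[rows],
                            seq2 = store$seq2[rows],
                            qual2 = store$qual2[rows],
                            stringsAsFactors = FALSE))
  })
  report <- list(n_reads = nrow(store),
                 n_clusters = length(groups),
                 n_below_min = sum(below), n_above_max = sum(above),
                 n_kept = length(kept_idx),
                 reads_kept = sum(depth[kept_idx]),
                 reads_gated = sum(depth[below | above]))
  list(loci = loci, report = report)
}

#' Expected fold coverage across a RAD locus span
#'
#' With only the sheared-end mates contributing, a cluster of `depth` reads
#' of `read2_len` bases spread over a `locus_span` bp locus yields
#' `read2_len * depth / locus_span` fold coverage (the rationale behind the
#' 50x single-end depth gate: (80 x 50) / 400 = 10x).
#'
#' @param read2_len sheared-end mate length in bp.
#' @param depth number of reads in the cluster.
#' @param locus_span locus span in bp.
#' @return fold coverage (numeric).
#' @export
expected_locus_coverage <- function(read2_len, depth, locus_span) {
  if (locus_span <= 0) stop_config("locus_span must be positive")
  if (read2_len <= 0) stop_config("read2_len must be positive")
  if (depth < 0) stop_config("depth must be non-negative")
  read2_len * depth / locus_span
}
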