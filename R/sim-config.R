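#' Simulation configuration for a multi-line RAD-Seq library
#'
#' Bundles every knob of the synthetic-data generator: the ancestral genome,
#' the inbred lines derived from it, the restriction digest, shearing and
#' size selection, and the asymmetric paired-end read chemistry (a 40 bp
#' barcode-anchored mate at the restriction site plus an 80 bp mate from the
#' sheared end).
#'
#' Defaults reflect the study conditions this package emulates: six inbred
#' sunflower-like lines, roughly one SNP per 143 bp against the common
#' ancestor, a transition/transversion ratio of 1.72, PstI (CTGCA/G)
#' digestion, shearing to ~500 bp and gel selection of 300-700 bp.
#'
#' @param genome_length ancestral genome length in bp.
#' @param gc_content target GC fraction of the ancestral genome.
#' @param n_lines number of inbred lines.
#' @param snp_rate expected SNPs per bp between any line and the ancestor.
#' @param tstv_ratio expected transition/transversion ratio of planted SNPs.
#' @param het_rate fraction of a line's variant sites left heterozygous
#'   (residual heterozygosity of an inbred line; 0 = fully homozygous).
#' @param enzyme_site restriction recognition sequence (PstI: CTGCAG).
#' @param cut_offset top-strand cut position within the site (CTGCA/G = 5).
#' @param methylated_site_fraction fraction of recognition sites masked from
#'   digestion (5mC-style blocking).
#' @param shear_mean,shear_sd fragment-length distribution of random shearing.
#' @param size_min,size_max size-selection window in bp.
#' @param read1_len,read2_len mate lengths (barcode mate, sheared-end mate).
#' @param barcode_len inline barcode length at the start of read 1.
#' @param reads_per_locus read pairs drawn per RAD locus per line.
#' @param error_rate per-base substitution error probability.
#' @param seed master RNG seed; every stage derives its own sub-seed from it.
#' @param line_ids optional line names (default line_1..line_n).
#' @param barcodes optional named barcode vector (names = line ids); the
#'   default set of six 4-nt codes has pairwise Hamming distance >= 2.
#' @return an object of class `sim_config`.
#' @export
sim_config <- function(genome_length = 200000,
                       gc_content = 0.361,
                       n_lines = 6,
                       snp_rate = 1 / 143,
                       tstv_ratio = 1.72,
                       het_rate = 0,
                       enzyme_site = "CTGCAG",
                       cut_offset = 5L,
                       methylated_site_fraction = 0,
                       shear_mean = 500,
                       shear_sd = 100,
                       size_min = 300,
                       size_max = 700,
                       read1_len = 40L,
                       read2_len = 80L,
                       barcode_len = 4L,
                       reads_per_locus = 60L,
                       error_rate = 0,
                       seed = 1L,
                       line_ids = NULL,
                       barcodes = NULL) {
  if (genome_length <= 0) stop_config("genome_length must be positive")
  if (gc_content < 0 || gc_content > 1)
    stop_config("gc_content must lie in [0, 1]")
  if (snp_rate < 0 || snp_rate >= 1)
    stop_config("snp_rate must lie in [0, 1)")
  if (tstv_ratio <= 0) stop_config("tstv_ratio must be positive")
  for (f in c(het_rate, methylated_site_fraction, error_rate))
    if (f < 0 || f > 1) stop_config("fractions must lie in [0, 1]")
  if (!nzchar(enzyme_site) || grepl("[^ACGT]", enzyme_site))
    stop_config("enzyme_site must be a non-empty ACGT string")
  if (cut_offset < 0 || cut_offset > nchar(enzyme_site))
    stop_config("cut_offset must lie in [0, nchar(enzyme_site)]")
  if (size_min >= size_max) stop_config("size_min must be < size_max")
  if (read1_len <= barcode_len)
    stop_config("read1_len must exceed barcode_len")
  if (reads_per_locus < 1) stop_config("reads_per_locus must be >= 1")
  if (is.null(line_ids)) line_ids <- sprintf("line_%d", seq_len(n_lines))
  if (length(line_ids) != n_lines) stop_config("need one id per line")
  if (is.null(barcodes)) {
    pool <- c("AACC", "CCAA", "GGTT", "TTGG", "ACGG", "CATT")
    if (n_lines > length(pool))
      stop_config("supply barcodes explicitly for more than %d lines",
                  length(pool))
    barcodes <- stats::setNames(pool[seq_len(n_lines)], line_ids)
  }
  if (length(barcodes) != n_lines) stop_config("need one barcode per line")
  if (is.null(names(barcodes))) names(barcodes) <- line_ids
  check_barcode_set(barcodes, barcode_len)

  structure(list(
    genome_length = as.integer(genome_length), gc_content = gc_content,
    n_lines = as.integer(n_lines), snp_rate = snp_rate,
    tstv_ratio = tstv_ratio, het_rate = het_rate,
    enzyme_site = enzyme_site, cut_offset = as.integer(cut_offset),
    methylated_site_fraction = methylated_site_fraction,
    shear_mean = shear_mean, shear_sd = shear_sd,
    size_min = as.integer(size_min), size_max = as.integer(size_max),
    read1_len = as.integer(read1_len), read2_len = as.integer(read2_len),
    barcode_len = as.integer(barcode_len),
    reads_per_locus = as.integer(reads_per_locus),
    error_rate = error_rate, seed = as.integer(seed),
    line_ids = line_ids, barcodes = barcodes
  ), class = "sim_config")
}

# Barcode sanity shared by sim_config() and emit_reads().
#' @noRd
check_barcode_set <- function(barcodes, barcode_len) {
  if (anyDuplicated(barcodes))
    stop_config("barcodes must be unique")
  if (any(nchar(barcodes) != barcode_len))
    stop_config("all barcodes must have length %d", barcode_len)
  n <- length(barcodes)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in seq(i + 1, n)) {
      if (hamming(barcodes[[i]], barcodes[[j]]) < 2)
        stop_config("barcodes '%s' and '%s' are within Hamming distance 1",
                    barcodes[[i]], barcodes[[j]])
    }
  }
  invisible(TRUE)
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(
    "RAD-Seq simulation config: %s bp genome (GC %.1f%%), %d lines\n",
    format(x$genome_length, big.mark = ","), 100 * x$gc_content, x$n_lines))
  cat(sprintf("  snp_rate 1/%.0f, ts/tv %.2f, het %.3f, error %.4g\n",
              1 / max(x$snp_rate, 1e-12), x$tstv_ratio, x$het_rate,
              x$error_rate))
  cat(sprintf("  %s (cut %d/%d), shear N(%g, %g) select [%d, %d]\n",
              x$enzyme_site, x$cut_offset,
              nchar(x$enzyme_site) - x$cut_offset, x$shear_mean, x$shear_sd,
              x$size_min, x$size_max))
  cat(sprintf("  reads: %d+%d bp (%d nt barcode), %d pairs/locus, seed %d\n",
              x$read1_len, x$read2_len, x$barcode_len, x$reads_per_locus,
              x$seed))
  invisible(x)
}
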