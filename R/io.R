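#' Write a paired FASTQ library
#'
#' @param reads read-pair table as produced by [simulate_rad_library()] or
#'   [demultiplex()] (columns `read_id`, `seq1`, `qual1`, `seq2`, `qual2`).
#' @param prefix output path prefix; `<prefix>_1.fastq` / `<prefix>_2.fastq`.
#' @return invisibly, the two file paths.
#' @export
write_fastq_pair <- function(reads, prefix) {
  p1 <- paste0(prefix, "_1.fastq")
  p2 <- paste0(prefix, "_2.fastq")
  write_fastq(reads$seq1, reads$qual1, paste0(reads$read_id, "/1"), p1)
  write_fastq(reads$seq2, reads$qual2, paste0(reads$read_id, "/2"), p2)
  invisible(c(p1, p2))
}

#' @noRd
write_fastq <- function(seqs, quals, ids, path) {
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, format = "fastq",
                              qualities = Biostrings::BStringSet(quals))
  invisible(path)
}

#' Read a paired FASTQ library into a read-pair table
#'
#' Mate files must be parallel (same order, ids suffixed /1 and /2).
#'
#' @param prefix path prefix used by [write_fastq_pair()], or a length-2
#'   vector of explicit mate file paths.
#' @return read-pair data frame (`read_id`, `seq1`, `qual1`, `seq2`, `qual2`).
#' @export
read_fastq_pair <- function(prefix) {
  paths <- if (length(prefix) == 2) prefix
           else paste0(prefix, c("_1.fastq", "_2.fastq"))
  m1 <- Biostrings::readDNAStringSet(paths[1], format = "fastq",
                                     with.qualities = TRUE)
  m2 <- Biostrings::readDNAStringSet(paths[2], format = "fastq",
                                     with.qualities = TRUE)
  if (length(m1) != length(m2)) stop_config("mate files differ in length")
  data.frame(
    read_id = sub("/1$", "", names(m1)),
    seq1 = as.character(m1), qual1 = as.character(S4Vectors::mcols(m1)$qualities),
    seq2 = as.character(m2), qual2 = as.character(S4Vectors::mcols(m2)$qualities),
    stringsAsFactors = FALSE, row.names = NULL)
}

#' Write contigs as FASTA
#'
#' @param contigs data frame with `contig_id` and `sequence`.
#' @param path output file.
#' @export
write_reference_fasta <- function(contigs, path) {
  x <- Biostrings::DNAStringSet(contigs$sequence)
  names(x) <- contigs$contig_id
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @noRd
write_bed <- function(intervals, path, chrom = "ancestral") {
  df <- data.frame(chrom = chrom, start = intervals$start,
                   end = intervals$end, name = intervals$locus_id)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

# Writes FASTQ pair, truth VCF/BED and a config echo for a simulation.
#' @noRd
write_sim_artifacts <- function(sim, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  write_fastq_pair(sim$reads, file.path(outdir, "reads"))
  write_truth_vcf(sim$truth$variants, sim$config, nchar(sim$ancestral),
                  file.path(outdir, "truth.vcf"))
  write_bed(sim$truth$loci, file.path(outdir, "truth_loci.bed"))
  cfg <- sim$config
  scalars <- cfg[!names(cfg) %in% c("line_ids", "barcodes")]
  echo <- c(sprintf("%s\t%s", names(scalars), vapply(scalars, format,
                                                     character(1))),
            sprintf("line\t%s\t%s", cfg$line_ids, cfg$barcodes[cfg$line_ids]))
  writeLines(echo, file.path(outdir, "config.txt"))
  invisible(outdir)
}

#' Write planted truth variants as VCF
#'
#' One record per distinct ancestral position, genotypes across lines
#' relative to the ancestral (REF) allele; 1-based VCF coordinates.
#'
#' @param truth_variants long truth table (`line_id`, `pos`, `ref`, `alt`,
#'   `het`) from [derive_line_genomes()] / [simulate_rad_library()].
#' @param config the [sim_config()] that produced them.
#' @param genome_length ancestral genome length for the contig header.
#' @param path output file.
#' @export
write_truth_vcf <- function(truth_variants, config, genome_length, path) {
  lines_out <- c(
    "##fileformat=VCFv4.2",
    "##source=radsnp-simulator",
    sprintf("##contig=<ID=ancestral,length=%d>", genome_length),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", config$line_ids), collapse = "\t"))
  if (nrow(truth_variants) > 0) {
    split_pos <- split(truth_variants, truth_variants$pos)
    recs <- vapply(split_pos, function(d) {
      alts <- unique(d$alt)
      gts <- vapply(config$line_ids, function(l) {
        r <- d[d$line_id == l, ]
        if (nrow(r) == 0) return("0/0")
        ai <- match(r$alt[1], alts)
        if (r$het[1]) sprintf("0/%d", ai) else sprintf("%d/%d", ai, ai)
      }, character(1))
      paste(c("ancestral", d$pos[1] + 1L, ".", d$ref[1],
              paste(alts, collapse = ","), ".", "PASS", ".", "GT", gts),
            collapse = "\t")
    }, character(1))
    recs <- recs[order(as.integer(names(split_pos)))]
    lines_out <- c(lines_out, unname(recs))
  }
  writeLines(lines_out, path)
  invisible(path)
}
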