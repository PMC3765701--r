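#' Write a variant set as VCF
#'
#' VCF v4.2, 1-based positions, per-line `GT:DP` fields (`0/0`, `1/1`,
#' `0/1`, `./.`). Alleles are checked against the reference contigs.
#'
#' @param variants a `variant_set` from [call_variants()] or the panel from
#'   [filter_cascade()].
#' @param contigs reference contig table (`contig_id`, `sequence`; `flag`
#'   rows restricted to retained).
#' @param path output file.
#' @return the path, invisibly.
#' @export
write_vcf <- function(variants, contigs, path) {
  if (!is.null(contigs$flag))
    contigs <- contigs[contigs$flag == "retained", , drop = FALSE]
  clen <- stats::setNames(nchar(contigs$sequence), contigs$contig_id)
  s <- variants$sites
  if (nrow(s) > 0) {
    if (any(is.na(clen[s$contig_id])))
      stop_config("variant on unknown contig")
    if (any(s$pos + 1L > clen[s$contig_id]))
      stop_config("variant position exceeds contig length")
    refb <- substr(contigs$sequence[match(s$contig_id, contigs$contig_id)],
                   s$pos + 1L, s$pos + 1L)
    if (any(refb != s$ref))
      stop_config("REF allele disagrees with reference contig")
  }
  header <- c(
    "##fileformat=VCFv4.2",
    "##source=radsnp",
    sprintf("##contig=<ID=%s,length=%d>", contigs$contig_id,
            nchar(contigs$sequence)),
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", variants$lines), collapse = "\t"))
  body <- character(0)
  if (nrow(s) > 0) {
    code <- c(hom_ref = "0/0", hom_alt = "1/1", het = "0/1",
              missing = "./.")
    body <- vapply(seq_len(nrow(s)), function(i) {
      fields <- sprintf("%s:%d", code[variants$gt[i, ]],
                        as.integer(variants$dp[i, ]))
      paste(c(s$contig_id[i], s$pos[i] + 1L, ".", s$ref[i], s$alt[i], ".",
              "PASS", ".", "GT:DP", fields), collapse = "\t")
    }, character(1))
  }
  writeLines(c(header, body), path)
  invisible(path)
}

#' Read a radsnp VCF back into site and genotype tables
#'
#' Minimal reader for files produced by [write_vcf()] /
#' [write_truth_vcf()]; used for round-trip checks and downstream scripts.
#'
#' @param path VCF file.
#' @return list with `sites` (`contig_id`, `pos` 0-based, `ref`, `alt`) and
#'   `gt` (site x sample genotype string matrix).
#' @export
read_vcf_minimal <- function(path) {
  ln <- readLines(path)
  hdr <- ln[startsWith(ln, "#CHROM")]
  samples <- strsplit(hdr, "\t")[[1]][-(1:9)]
  body <- ln[!startsWith(ln, "#")]
  if (length(body) == 0) {
    return(list(sites = data.frame(contig_id = character(0),
                                   pos = integer(0), ref = character(0),
                                   alt = character(0)),
                gt = matrix(character(0), ncol = length(samples),
                            dimnames = list(NULL, samples))))
  }
  f <- do.call(rbind, strsplit(body, "\t"))
  gt <- sub(":.*$", "", f[, -(1:9), drop = FALSE])
  colnames(gt) <- samples
  list(sites = data.frame(contig_id = f[, 1],
                          pos = as.integer(f[, 2]) - 1L,
                          ref = f[, 4], alt = f[, 5],
                          stringsAsFactors = FALSE),
       gt = gt)
}

#' Write SNP-centred flanking sequences for assay design
#'
#' One FASTA record per panel SNP: `flank_len` bases either side of the
#' site, with the SNP itself as the IUPAC code of its two alleles.
#'
#' @param variants panel `variant_set`.
#' @param contigs reference contig table.
#' @param path output FASTA.
#' @param flank_len flank length (default 50).
#' @export
write_panel_fasta <- function(variants, contigs, path, flank_len = 50L) {
  if (!is.null(contigs$flag))
    contigs <- contigs[contigs$flag == "retained", , drop = FALSE]
  s <- variants$sites
  iupac <- c(AC = "M", AG = "R", AT = "W", CG = "S", CT = "Y", GT = "K")
  seqs <- vapply(seq_len(nrow(s)), function(i) {
    ctg <- contigs$sequence[match(s$contig_id[i], contigs$contig_id)]
    pair <- paste0(pmin(s$ref[i], s$alt[i]), pmax(s$ref[i], s$alt[i]))
    paste0(substr(ctg, s$pos[i] - flank_len + 1L, s$pos[i]),
           iupac[[pair]],
           substr(ctg, s$pos[i] + 2L, s$pos[i] + flank_len + 1L))
  }, character(1))
  x <- Biostrings::BStringSet(seqs)
  names(x) <- sprintf("%s_%d_%s%s", s$contig_id, s$pos + 1L, s$ref, s$alt)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' Write alignments as SAM
#'
#' Minimal mandatory-column SAM with an NM tag; ungapped alignments only
#' (CIGAR is full-length M).
#'
#' @param alignments alignment table from [align_reads()] (any lines).
#' @param contigs reference contig table.
#' @param path output file.
#' @export
write_sam <- function(alignments, contigs, path) {
  if (!is.null(contigs$flag))
    contigs <- contigs[contigs$flag == "retained", , drop = FALSE]
  hdr <- c("@HD\tVN:1.6\tSO:unknown",
           sprintf("@SQ\tSN:%s\tLN:%d", contigs$contig_id,
                   nchar(contigs$sequence)))
  body <- character(0)
  if (nrow(alignments) > 0) {
    flag <- ifelse(alignments$strand == "-", 16L, 0L)
    body <- sprintf("%s\t%d\t%s\t%d\t255\t%dM\t*\t0\t0\t%s\t%s\tNM:i:%d",
                    alignments$read_id, flag, alignments$contig_id,
                    alignments$start + 1L, nchar(alignments$oriented_seq),
                    alignments$oriented_seq, alignments$oriented_qual,
                    alignments$mismatches)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}
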