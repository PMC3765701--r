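#' Generate a random ancestral genome
#'
#' Draws an i.i.d. nucleotide sequence with the configured GC content. The
#' ancestral genome is the common reference from which every inbred line is
#' derived by planting line-specific SNPs.
#'
#' @param config a [sim_config()].
#' @return a single character string of length `config$genome_length`.
#' @export
generate_ancestral_genome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  gc <- config$gc_content
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  with_seed(sub_seed(config$seed, 1), {
    paste(sample(names(p), config$genome_length, replace = TRUE, prob = p),
          collapse = "")
  })
}

# transition partner of each base
TS_PARTNER <- c(A = "G", G = "A", C = "T", T = "C")
TV_PARTNERS <- list(A = c("C", "T"), G = c("C", "T"),
                    C = c("A", "G"), T = c("A", "G"))

#' Derive inbred line genomes from an ancestor
#'
#' Each line receives an independent Binomial(genome_length, snp_rate) set of
#' variant positions. Substitution types are drawn so that the expected
#' transition/transversion ratio equals `tstv_ratio` (a transition with
#' probability tstv/(1+tstv), otherwise one of the two transversions
#' uniformly). A fraction `het_rate` of a line's variant sites is left
#' heterozygous (derived allele on haplotype 1 only); the rest are fixed on
#' both haplotypes, reflecting near-complete inbreeding.
#'
#' @param ancestral ancestral genome string.
#' @param config a [sim_config()].
#' @return a list with `lines` (per-line list of `line_id`, `hap1`, `hap2`,
#'   `variants` data frame with 0-based `pos`, `ref`, `alt`, `het`) and
#'   `variants`, the concatenated truth table across lines.
#' @export
derive_line_genomes <- function(ancestral, config) {
  stopifnot(inherits(config, "sim_config"))
  if (!nzchar(ancestral)) stop_config("ancestral genome is empty")
  if (config$snp_rate >= 1) stop_config("snp_rate must be < 1")
  anc <- strsplit(ancestral, "", fixed = TRUE)[[1]]
  n <- length(anc)
  p_ts <- config$tstv_ratio / (1 + config$tstv_ratio)

  lines <- vector("list", config$n_lines)
  for (i in seq_len(config$n_lines)) {
    lines[[i]] <- with_seed(sub_seed(config$seed, 100 + i), {
      pos <- if (config$snp_rate > 0) which(stats::runif(n) < config$snp_rate)
             else integer(0)
      m <- length(pos)
      ref <- anc[pos]
      alt <- character(m)
      if (m > 0) {
        is_ts <- stats::runif(m) < p_ts
        alt[is_ts] <- TS_PARTNER[ref[is_ts]]
        if (any(!is_ts)) {
          pick <- 1L + (stats::runif(sum(!is_ts)) < 0.5)
          alt[!is_ts] <- mapply(function(b, j) TV_PARTNERS[[b]][j],
                                ref[!is_ts], pick)
        }
        het <- stats::runif(m) < config$het_rate
      } else {
        het <- logical(0)
      }
      h1 <- anc; h1[pos] <- alt
      h2 <- anc; h2[pos[!het]] <- alt[!het]
      list(line_id = config$line_ids[i],
           hap1 = paste(h1, collapse = ""),
           hap2 = paste(h2, collapse = ""),
           variants = data.frame(pos = pos - 1L, ref = ref, alt = alt,
                                 het = het, stringsAsFactors = FALSE))
    })
  }
  names(lines) <- config$line_ids
  truth <- do.call(rbind, lapply(lines, function(l) {
    if (nrow(l$variants) == 0) return(NULL)
    cbind(line_id = l$line_id, l$variants)
  }))
  if (is.null(truth))
    truth <- data.frame(line_id = character(0), pos = integer(0),
                        ref = character(0), alt = character(0),
                        het = logical(0))
  rownames(truth) <- NULL
  list(lines = lines, variants = truth)
}

#' In-silico restriction digest
#'
#' Cuts the genome at `site_start + cut_offset` for every occurrence of the
#' recognition site that is not in the methylation mask. Fragments tile the
#' genome exactly: concatenating them in order reconstructs the input.
#'
#' @param genome genome string.
#' @param config a [sim_config()].
#' @param methylation_mask integer vector of 0-based site start positions
#'   blocked from cleavage (5mC-style protection).
#' @return data frame with 0-based half-open `start`, `end` and `seq`.
#' @export
digest_genome <- function(genome, config, methylation_mask = integer(0)) {
  stopifnot(inherits(config, "sim_config"))
  n <- nchar(genome)
  hits <- gregexpr(config$enzyme_site, genome, fixed = TRUE)[[1]]
  sites0 <- if (hits[1] == -1) integer(0) else as.integer(hits) - 1L
  sites0 <- setdiff(sites0, as.integer(methylation_mask))
  cuts <- sort(sites0 + config$cut_offset)
  cuts <- cuts[cuts > 0 & cuts < n]
  bounds <- c(0L, cuts, n)
  start <- bounds[-length(bounds)]
  end <- bounds[-1]
  data.frame(start = start, end = end,
             seq = substring(genome, start + 1L, end),
             stringsAsFactors = FALSE)
}

# Sample the set of methylation-masked site positions on a genome.
#' @noRd
sample_methylation_mask <- function(genome, config) {
  if (config$methylated_site_fraction <= 0) return(integer(0))
  hits <- gregexpr(config$enzyme_site, genome, fixed = TRUE)[[1]]
  if (hits[1] == -1) return(integer(0))
  sites0 <- as.integer(hits) - 1L
  with_seed(sub_seed(config$seed, 7), {
    keep <- stats::runif(length(sites0)) < config$methylated_site_fraction
    sites0[keep]
  })
}

# truncated-normal draw on [lo, hi] via inverse CDF
#' @noRd
rtrunc_norm <- function(n, mean, sd, lo, hi) {
  plo <- stats::pnorm(lo, mean, sd)
  phi <- stats::pnorm(hi, mean, sd)
  if (phi <= plo) stop_config("size-selection window excludes all lengths")
  u <- stats::runif(n, plo, phi)
  round(stats::qnorm(u, mean, sd))
}

#' Shear fragments and size-select RAD sub-fragments
#'
#' Every restriction-cut end of a digested fragment seeds one RAD locus.
#' For each locus, `n_per_end` molecules are drawn whose lengths follow a
#' Normal(shear_mean, shear_sd) truncated to the size-selection window and to
#' the parent fragment; molecules still shorter than `size_min` after
#' truncation are discarded (they would run off the gel window).
#'
#' Locus anchors include the enzyme's 4-nt 3' overhang, so reads from either
#' side of a cut start with the same site remnant (TGCAG for PstI).
#'
#' @param fragments data frame from [digest_genome()].
#' @param config a [sim_config()].
#' @param n_per_end molecules drawn per cut-site flank.
#' @param seed RNG seed for the shear draws.
#' @return data frame of sheared molecules: `locus_id`, `dir` (+/-),
#'   `anchor` (cut-proximal coordinate), `len`, plus the covered 0-based
#'   half-open interval `start`, `end` on the source genome.
#' @export
shear_and_select <- function(fragments, config,
                             n_per_end = config$reads_per_locus,
                             seed = sub_seed(config$seed, 300)) {
  stopifnot(inherits(config, "sim_config"))
  if (nrow(fragments) == 0) stop_config("no fragments to shear")
  glen <- max(fragments$end)
  overhang <- max(0L, 2L * config$cut_offset - nchar(config$enzyme_site))

  ends <- list()
  for (i in seq_len(nrow(fragments))) {
    f <- fragments[i, ]
    if (f$start > 0) {   # left boundary is a cut: forward locus
      anchor <- f$start - overhang
      ends[[length(ends) + 1L]] <- list(
        locus_id = sprintf("cut%09d_R", f$start), dir = "+",
        anchor = anchor, avail = f$end - anchor)
    }
    if (f$end < glen) {  # right boundary is a cut: reverse locus
      ends[[length(ends) + 1L]] <- list(
        locus_id = sprintf("cut%09d_L", f$end), dir = "-",
        anchor = f$end, avail = f$end - f$start)
    }
  }
  if (length(ends) == 0) {
    warning("no cut sites: no RAD loci produced")
    return(data.frame(locus_id = character(0), dir = character(0),
                      anchor = integer(0), len = integer(0),
                      start = integer(0), end = integer(0)))
  }

  with_seed(seed, {
    out <- lapply(ends, function(e) {
      len <- rtrunc_norm(n_per_end, config$shear_mean, config$shear_sd,
                         config$size_min, config$size_max)
      len <- pmin(len, e$avail)
      len <- len[len >= config$size_min]
      if (length(len) == 0) return(NULL)
      if (e$dir == "+")
        data.frame(locus_id = e$locus_id, dir = "+", anchor = e$anchor,
                   len = len, start = e$anchor, end = e$anchor + len,
                   stringsAsFactors = FALSE)
      else
        data.frame(locus_id = e$locus_id, dir = "-", anchor = e$anchor,
                   len = len, start = e$anchor - len, end = e$anchor,
                   stringsAsFactors = FALSE)
    })
    out <- do.call(rbind, out)
    if (is.null(out)) {
      warning("size-selection window removed every molecule")
      out <- data.frame(locus_id = character(0), dir = character(0),
                        anchor = integer(0), len = integer(0),
                        start = integer(0), end = integer(0))
    }
    rownames(out) <- NULL
    out
  })
}

#' Emit asymmetric paired-end reads from sheared molecules
#'
#' Read 1 is the barcode followed by the cut-proximal genomic sequence
#' (beginning with the retained site remnant); read 2 is the reverse
#' complement of the last `read2_len` bases at the sheared end. Substitution
#' errors are applied per base at `error_rate`; erroneous bases carry a low
#' phred symbol, correct bases a high one.
#'
#' @param sheared data frame from [shear_and_select()].
#' @param genome the haplotype string the molecules were drawn from.
#' @param line_id line identifier stamped into read ids.
#' @param barcode the line's inline barcode.
#' @param config a [sim_config()].
#' @param seed RNG seed for the error process.
#' @return data frame of read pairs: `read_id`, `line_id`, `locus_id`,
#'   `seq1`, `qual1`, `seq2`, `qual2`.
#' @export
emit_reads <- function(sheared, genome, line_id, barcode, config,
                       seed = sub_seed(config$seed, 400)) {
  stopifnot(inherits(config, "sim_config"))
  if (nchar(barcode) != config$barcode_len)
    stop_config("barcode length mismatch")
  g1 <- config$read1_len - config$barcode_len
  keep <- sheared$len >= max(config$read2_len, g1)
  if (!all(keep)) {
    warning(sprintf("%d molecules shorter than a mate were skipped",
                    sum(!keep)))
    sheared <- sheared[keep, , drop = FALSE]
  }
  n <- nrow(sheared)
  if (n == 0) {
    return(data.frame(read_id = character(0), line_id = character(0),
                      locus_id = character(0), seq1 = character(0),
                      qual1 = character(0), seq2 = character(0),
                      qual2 = character(0)))
  }

  region <- substring(genome, sheared$start + 1L, sheared$end)
  minus <- sheared$dir == "-"
  oriented <- region
  oriented[minus] <- revcomp(region[minus])
  seq1 <- paste0(barcode, substring(oriented, 1L, g1))
  seq2 <- revcomp(substring(oriented, sheared$len - config$read2_len + 1L,
                            sheared$len))

  q_hi <- "I"  # phred 40
  q_lo <- "#"  # phred 2
  qual1 <- strrep(q_hi, config$read1_len)
  qual2 <- strrep(q_hi, config$read2_len)
  res <- data.frame(
    read_id = sprintf("%s_%s_%04d", line_id, sheared$locus_id,
                      stats::ave(seq_len(n), sheared$locus_id,
                                 FUN = seq_along)),
    line_id = line_id, locus_id = sheared$locus_id,
    seq1 = seq1, qual1 = qual1, seq2 = seq2, qual2 = qual2,
    stringsAsFactors = FALSE)

  if (config$error_rate > 0) {
    res <- with_seed(seed, {
      res$seq1 <- mutate_reads(res$seq1, config$error_rate)
      res$qual1 <- flag_quals(res$seq1, seq1, q_hi, q_lo)
      res$seq2 <- mutate_reads(res$seq2, config$error_rate)
      res$qual2 <- flag_quals(res$seq2, seq2, q_hi, q_lo)
      res
    })
  }
  res
}

# substitute bases at random positions with probability `rate` each
#' @noRd
mutate_reads <- function(seqs, rate) {
  bases <- c("A", "C", "G", "T")
  vapply(seqs, function(s) {
    v <- strsplit(s, "", fixed = TRUE)[[1]]
    hit <- which(stats::runif(length(v)) < rate)
    for (i in hit) {
      v[i] <- sample(setdiff(bases, v[i]), 1)
    }
    paste(v, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

# low-quality symbol wherever observed != template
#' @noRd
flag_quals <- function(observed, template, q_hi, q_lo) {
  mapply(function(o, t) {
    a <- utf8ToInt(o); b <- utf8ToInt(t)
    q <- rep(q_hi, length(a)); q[a != b] <- q_lo
    paste(q, collapse = "")
  }, observed, template, USE.NAMES = FALSE)
}

#' Simulate a pooled multi-line RAD-Seq library
#'
#' End-to-end generator: ancestral genome, line genomes with planted SNPs,
#' per-line digestion (line SNPs may create or destroy sites), shearing and
#' size selection, and pooled asymmetric paired-end reads, together with the
#' truth files that make every downstream stage testable.
#'
#' @param config a [sim_config()].
#' @param outdir optional directory; when given, pooled FASTQ (mate1/mate2),
#'   truth VCF, truth BED and a config echo are written there.
#' @return an object of class `rad_sim`: `config`, `ancestral`, `lines`,
#'   `reads` (pooled read-pair table), and `truth` (`variants`, `loci`,
#'   `seed`).
#' @export
simulate_rad_library <- function(config, outdir = NULL) {
  stopifnot(inherits(config, "sim_config"))
  ancestral <- generate_ancestral_genome(config)
  derived <- derive_line_genomes(ancestral, config)
  mask <- sample_methylation_mask(ancestral, config)

  all_reads <- list()
  for (i in seq_len(config$n_lines)) {
    ln <- derived$lines[[i]]
    haps <- if (config$het_rate > 0) c("hap1", "hap2") else "hap1"
    n_hap <- if (length(haps) == 2)
      c(ceiling(config$reads_per_locus / 2), floor(config$reads_per_locus / 2))
    else config$reads_per_locus
    for (h in seq_along(haps)) {
      genome <- ln[[haps[h]]]
      frags <- digest_genome(genome, config, methylation_mask = mask)
      sheared <- shear_and_select(frags, config, n_per_end = n_hap[h],
                                  seed = sub_seed(config$seed,
                                                  300 + 10 * i + h))
      all_reads[[length(all_reads) + 1L]] <- emit_reads(
        sheared, genome, ln$line_id, config$barcodes[[ln$line_id]], config,
        seed = sub_seed(config$seed, 400 + 10 * i + h))
    }
  }
  reads <- do.call(rbind, all_reads)
  rownames(reads) <- NULL

  truth_loci <- truth_locus_intervals(ancestral, config, mask)
  truth <- list(variants = derived$variants, loci = truth_loci,
                seed = config$seed)
  sim <- structure(list(config = config, ancestral = ancestral,
                        lines = derived$lines, reads = reads, truth = truth),
                   class = "rad_sim")
  if (!is.null(outdir)) write_sim_artifacts(sim, outdir)
  sim
}

# Maximal possible locus spans on the ancestral genome (truth BED).
#' @noRd
truth_locus_intervals <- function(ancestral, config, mask = integer(0)) {
  frags <- digest_genome(ancestral, config, methylation_mask = mask)
  glen <- nchar(ancestral)
  overhang <- max(0L, 2L * config$cut_offset - nchar(config$enzyme_site))
  rows <- list()
  for (i in seq_len(nrow(frags))) {
    f <- frags[i, ]
    if (f$start > 0) {
      anchor <- f$start - overhang
      span <- min(config$size_max, f$end - anchor)
      if (span >= config$size_min)
        rows[[length(rows) + 1L]] <- data.frame(
          locus_id = sprintf("cut%09d_R", f$start),
          start = anchor, end = anchor + span, stringsAsFactors = FALSE)
    }
    if (f$end < glen) {
      span <- min(config$size_max, f$end - f$start)
      if (span >= config$size_min)
        rows[[length(rows) + 1L]] <- data.frame(
          locus_id = sprintf("cut%09d_L", f$end),
          start = f$end - span, end = f$end, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(locus_id = character(0), start = integer(0),
                      end = integer(0))
  out
}

#' @export
print.rad_sim <- function(x, ...) {
  cat(sprintf("RAD-Seq simulation: %d lines, %s read pairs, %d truth SNPs\n",
              x$config$n_lines, format(nrow(x$reads), big.mark = ","),
              nrow(x$truth$variants)))
  invisible(x)
}
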