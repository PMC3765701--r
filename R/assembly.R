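#' Assemble one RAD locus from its sheared-end mates
#'
#' Small de Bruijn assembler: k-mers of the mates and their reverse
#' complements are counted, k-mers below `coverage_cutoff` are pruned
#' (sequencing-error k-mers are rare and fall below the cutoff at RAD depths),
#' and contigs are grown greedily from the highest-count unused k-mer.
#' Extension ties are broken by higher k-mer count, then by base order
#' (A < C < G < T). Since each k-mer and its reverse complement represent the
#' same double-stranded state, both are retired together, so each contig is
#' reported once in a canonical orientation.
#'
#' @param mates character vector of mate sequences (one locus).
#' @param k odd k-mer size (default 31; must be < read length).
#' @param coverage_cutoff minimum k-mer count kept in the graph (default 3).
#' @param min_contig_len contigs shorter than this are flagged `too_short`
#'   and excluded from the retained set (default 200).
#' @return data frame of contigs with `sequence`, `length`, `mean_cov`,
#'   `too_short`; zero rows if every k-mer was pruned.
#' @export
assemble_locus <- function(mates, k = 31L, coverage_cutoff = 3L,
                           min_contig_len = 200L) {
  if (length(mates) == 0) stop_config("no mates to assemble")
  if (k %% 2L == 0L) stop_config("k must be odd")
  if (k >= min(nchar(mates))) {
    return(data.frame(sequence = character(0), length = integer(0),
                      mean_cov = numeric(0), too_short = logical(0)))
  }
  km <- unlist(lapply(c(mates, revcomp(mates)), kmers, k = k),
               use.names = FALSE)
  tab <- table(km)
  tab <- tab[tab >= coverage_cutoff]
  if (length(tab) == 0) {
    return(data.frame(sequence = character(0), length = integer(0),
                      mean_cov = numeric(0), too_short = logical(0)))
  }

  cnt <- new.env(parent = emptyenv(), size = length(tab))
  used <- new.env(parent = emptyenv(), size = length(tab))
  keys <- names(tab)
  vals <- as.integer(tab)
  for (i in seq_along(keys)) assign(keys[i], vals[i], envir = cnt)

  get_cnt <- function(x) {
    v <- mget(x, envir = cnt, ifnotfound = list(NULL))
    vapply(v, function(z) if (is.null(z)) -1L else z, integer(1))
  }
  is_used <- function(x) !is.null(get0(x, envir = used))
  retire <- function(x) {
    assign(x, TRUE, envir = used)
    assign(revcomp(x), TRUE, envir = used)
  }
  bases <- c("A", "C", "G", "T")

  # usable neighbours of a k-mer, best-first (count desc, base order)
  best_next <- function(cands) {
    cc <- get_cnt(cands)
    ok <- cc >= 0 & !vapply(cands, is_used, logical(1))
    if (!any(ok)) return(NULL)
    i <- which(ok)[order(-cc[ok])][1]  # order() is stable: base order on ties
    list(kmer = cands[i], count = cc[i])
  }

  seed_order <- keys[order(-vals, keys, method = "radix")]
  contigs <- list()
  for (seed in seed_order) {
    if (is_used(seed)) next
    retire(seed)
    path_counts <- get_cnt(seed)
    right <- character(0)
    cur <- seed
    repeat {
      nx <- best_next(paste0(substr(cur, 2L, k), bases))
      if (is.null(nx)) break
      retire(nx$kmer)
      right <- c(right, substr(nx$kmer, k, k))
      path_counts <- c(path_counts, nx$count)
      cur <- nx$kmer
    }
    left <- character(0)
    cur <- seed
    repeat {
      nx <- best_next(paste0(bases, substr(cur, 1L, k - 1L)))
      if (is.null(nx)) break
      retire(nx$kmer)
      left <- c(substr(nx$kmer, 1L, 1L), left)
      path_counts <- c(nx$count, path_counts)
      cur <- nx$kmer
    }
    contig <- paste0(paste(left, collapse = ""), seed,
                     paste(right, collapse = ""))
    rc <- revcomp(contig)
    if (rc < contig) contig <- rc   # canonical orientation
    contigs[[length(contigs) + 1L]] <-
      list(sequence = contig, mean_cov = mean(path_counts))
  }

  out <- data.frame(
    sequence = vapply(contigs, `[[`, character(1), "sequence"),
    mean_cov = vapply(contigs, `[[`, numeric(1), "mean_cov"),
    stringsAsFactors = FALSE)
  out$length <- nchar(out$sequence)
  out$too_short <- out$length < min_contig_len
  out[, c("sequence", "length", "mean_cov", "too_short")]
}

#' Assemble every RAD locus of a line
#'
#' Runs [assemble_locus()] per locus and applies the one-contig-per-locus
#' rule: among contigs meeting the length threshold, the longest is retained
#' (ties broken by higher mean k-mer coverage); further survivors are flagged
#' `secondary`, short ones `too_short`.
#'
#' @param loci locus list from [cluster_loci()].
#' @inheritParams assemble_locus
#' @return list with `contigs` (all assembled contigs: `contig_id`,
#'   `locus_id`, `sequence`, `length`, `mean_cov`, `flag`) where
#'   `flag == "retained"` marks the reference set, and `report` (flag counts
#'   plus loci with no assembly).
#' @export
assemble_rad_loci <- function(loci, k = 31L, coverage_cutoff = 3L,
                              min_contig_len = 200L) {
  rows <- list()
  n_empty <- 0L
  for (lc in loci) {
    ctg <- assemble_locus(lc$mates$seq2, k = k,
                          coverage_cutoff = coverage_cutoff,
                          min_contig_len = min_contig_len)
    if (nrow(ctg) == 0) { n_empty <- n_empty + 1L; next }
    flag <- ifelse(ctg$too_short, "too_short", "secondary")
    ok <- which(!ctg$too_short)
    if (length(ok) > 0) {
      best <- ok[order(-ctg$length[ok], -ctg$mean_cov[ok])][1]
      flag[best] <- "retained"
    }
    ctg$flag <- flag
    ctg$locus_id <- lc$locus_id
    ctg$contig_id <- sprintf("%s_c%d", lc$locus_id, seq_len(nrow(ctg)))
    rows[[length(rows) + 1L]] <- ctg
  }
  contigs <- if (length(rows)) do.call(rbind, rows)
             else data.frame(sequence = character(0), length = integer(0),
                             mean_cov = numeric(0), too_short = logical(0),
                             flag = character(0), locus_id = character(0),
                             contig_id = character(0))
  rownames(contigs) <- NULL
  contigs <- contigs[, c("contig_id", "locus_id", "sequence", "length",
                         "mean_cov", "flag")]
  list(contigs = contigs,
       report = list(n_loci = length(loci), n_empty = n_empty,
                     n_assembled = nrow(contigs),
                     n_retained = sum(contigs$flag == "retained"),
                     n_too_short = sum(contigs$flag == "too_short"),
                     n_secondary = sum(contigs$flag == "secondary")))
}

#' Screen contigs for contaminant (plastid) homology
#'
#' A contig is flagged when a seeded local alignment against any contaminant
#' record reaches at least `min_identity` over at least `min_span` aligned
#' bases (either orientation). A shared `seed_k`-mer is required before the
#' Smith-Waterman step, so unrelated contigs are dismissed cheaply.
#'
#' @param contigs contig table from [assemble_rad_loci()]; only rows with
#'   `flag == "retained"` are screened.
#' @param contaminants character vector (or `DNAStringSet`) of contaminant
#'   sequences, e.g. a plastid genome set.
#' @param min_identity minimum alignment identity (default 0.90).
#' @param min_span minimum aligned span in bp (default 100).
#' @param seed_k exact seed length for the prefilter (default 15).
#' @return list with `contigs` (flags updated: hits become
#'   `plastid_removed`) and `report` (`n_screened`, `n_flagged`,
#'   `n_retained`).
#' @export
plastid_screen <- function(contigs, contaminants, min_identity = 0.90,
                           min_span = 100L, seed_k = 15L) {
  contaminants <- as.character(contaminants)
  if (length(contaminants) == 0 || all(!nzchar(contaminants)))
    stop_config("contaminant database is empty")
  idx <- which(contigs$flag == "retained")
  if (length(idx) == 0) {
    return(list(contigs = contigs,
                report = list(n_screened = 0L, n_flagged = 0L,
                              n_retained = 0L)))
  }
  db_kmers <- unique(unlist(lapply(c(contaminants, revcomp(contaminants)),
                                   kmers, k = seed_k), use.names = FALSE))
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1)

  hit <- logical(length(idx))
  for (j in seq_along(idx)) {
    ctg <- contigs$sequence[idx[j]]
    if (!any(kmers(ctg, seed_k) %in% db_kmers)) next
    for (db in contaminants) {
      for (q in c(ctg, revcomp(ctg))) {
        aln <- Biostrings::pairwiseAlignment(
          q, db, type = "local", substitutionMatrix = mat,
          gapOpening = 4, gapExtension = 2)
        w <- Biostrings::nchar(aln)
        if (w >= min_span &&
            Biostrings::nmatch(aln) / w >= min_identity) {
          hit[j] <- TRUE
          break
        }
      }
      if (hit[j]) break
    }
  }
  contigs$flag[idx[hit]] <- "plastid_removed"
  list(contigs = contigs,
       report = list(n_screened = length(idx), n_flagged = sum(hit),
                     n_retained = length(idx) - sum(hit)))
}

#' Nx contig length statistic
#'
#' The length L such that contigs of length >= L comprise at least
#' `frac` of the total assembly length (N50 at `frac = 0.5`).
#'
#' @param lengths integer vector of contig lengths.
#' @param frac cumulative fraction in (0, 1].
#' @return the Nx length.
#' @export
contig_nx <- function(lengths, frac) {
  if (length(lengths) == 0) stop_config("no contig lengths")
  if (frac <= 0 || frac > 1) stop_config("frac must lie in (0, 1]")
  s <- sort(lengths, decreasing = TRUE)
  s[which(cumsum(as.numeric(s)) >= frac * sum(as.numeric(s)))[1]]
}

#' Assembly summary statistics
#'
#' Contig count, total/min/max length, GC percent over the concatenated
#' sequence, N50/N90 and a 100 bp length histogram, computed over the
#' retained contig set.
#'
#' @param contigs contig table; rows with `flag == "retained"` are used
#'   (all rows if no `flag` column).
#' @param bin histogram bin width in bp.
#' @return object of class `assembly_stats`.
#' @export
assembly_stats <- function(contigs, bin = 100L) {
  if (!is.null(contigs$flag))
    contigs <- contigs[contigs$flag == "retained", , drop = FALSE]
  if (nrow(contigs) == 0) stop_config("no retained contigs")
  lens <- contigs$length
  cat_freq <- colSums(Biostrings::alphabetFrequency(
    Biostrings::DNAStringSet(contigs$sequence)))
  acgt <- cat_freq[c("A", "C", "G", "T")]
  gc <- 100 * sum(acgt[c("C", "G")]) / sum(acgt)
  breaks <- seq(0L, (max(lens) %/% bin + 1L) * bin, by = bin)
  structure(list(
    n_contigs = length(lens),
    total_length = sum(lens),
    min_len = min(lens), max_len = max(lens),
    gc_percent = gc,
    n50 = contig_nx(lens, 0.5), n90 = contig_nx(lens, 0.9),
    length_hist = table(cut(lens, breaks = breaks, right = FALSE))
  ), class = "assembly_stats")
}

#' @export
print.assembly_stats <- function(x, ...) {
  cat(sprintf(
    "%d contigs, %s bp total (min %d, max %d), GC %.1f%%, N50 %d, N90 %d\n",
    x$n_contigs, format(x$total_length, big.mark = ","), x$min_len,
    x$max_len, x$gc_percent, x$n50, x$n90))
  invisible(x)
}
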