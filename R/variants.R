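BASES <- c("A", "C", "G", "T")

#' Genotype one pileup column for one line
#'
#' Depth below `min_depth` yields a missing call. Otherwise the major allele
#' is called homozygous when its fraction reaches `hom_fraction`; failing
#' that, a heterozygous call is made when the minor allele fraction reaches
#' `het_minor_fraction`; anything else is ambiguous and reported missing.
#'
#' @param counts length-4 vector of base counts (A, C, G, T order).
#' @param min_depth minimum depth for a confident call (default 4).
#' @param hom_fraction major-allele fraction for a homozygous call (0.90).
#' @param het_minor_fraction minimum minor-allele fraction for a het (0.25).
#' @return list with `state` (`hom`, `het` or `missing`), `alleles`
#'   (called bases, length 0-2) and `depth`.
#' @export
genotype_site <- function(counts, min_depth = 4L, hom_fraction = 0.90,
                          het_minor_fraction = 0.25) {
  depth <- sum(counts)
  if (depth < min_depth)
    return(list(state = "missing", alleles = character(0), depth = depth))
  major <- which.max(counts)
  if (counts[major] / depth >= hom_fraction)
    return(list(state = "hom", alleles = BASES[major], depth = depth))
  rest <- counts
  rest[major] <- 0L
  minor <- which.max(rest)
  if (rest[minor] / depth >= het_minor_fraction)
    return(list(state = "het", alleles = BASES[c(major, minor)],
                depth = depth))
  list(state = "missing", alleles = character(0), depth = depth)
}

# Vectorised genotyping of a whole 4 x L pileup matrix.
# Returns integer allele indices (0 = none) and a state code per column:
# 0 missing, 1 hom, 2 het.
#' @noRd
genotype_matrix <- function(m, min_depth = 4L, hom_fraction = 0.90,
                            het_minor_fraction = 0.25) {
  depth <- colSums(m)
  major <- max.col(t(m), ties.method = "first")
  maxc <- m[cbind(major, seq_len(ncol(m)))]
  m2 <- m
  m2[cbind(major, seq_len(ncol(m)))] <- 0L
  minor <- max.col(t(m2), ties.method = "first")
  secc <- m2[cbind(minor, seq_len(ncol(m)))]

  state <- integer(ncol(m))
  covered <- depth >= min_depth
  is_hom <- covered & maxc >= hom_fraction * depth
  is_het <- covered & !is_hom & secc >= het_minor_fraction * depth
  state[is_hom] <- 1L
  state[is_het] <- 2L
  a1 <- ifelse(state > 0L, major, 0L)
  a2 <- ifelse(state == 2L, minor, ifelse(state == 1L, major, 0L))
  list(state = state, a1 = a1, a2 = a2, depth = depth)
}

#' Call bi-allelic variant sites across lines
#'
#' A reference position is a variant when at least one line has a confident
#' genotype containing a non-reference allele. Sites presenting more than
#' two alleles across lines (reference included) are excluded as
#' multi-allelic and counted separately.
#'
#' @param pileups_by_line named list (line id) of [build_pileups()] results.
#' @param contigs reference contig table (`contig_id`, `sequence`; rows with
#'   `flag` restricted to retained).
#' @param min_depth,hom_fraction,het_minor_fraction see [genotype_site()].
#' @return object of class `variant_set`: `sites` (data frame `contig_id`,
#'   `pos` 0-based, `ref`, `alt`, `n_missing`), `gt` (site x line state
#'   matrix with entries hom_ref/hom_alt/het/missing), `dp` (site x line
#'   depth matrix), `n_multiallelic`.
#' @export
call_variants <- function(pileups_by_line, contigs, min_depth = 4L,
                          hom_fraction = 0.90, het_minor_fraction = 0.25) {
  if (!is.null(contigs$flag))
    contigs <- contigs[contigs$flag == "retained", , drop = FALSE]
  lines <- names(pileups_by_line)
  sites <- list()
  gt_rows <- list()
  dp_rows <- list()
  n_multi <- 0L

  for (ci in seq_len(nrow(contigs))) {
    cid <- contigs$contig_id[ci]
    refb <- utf8ToInt(contigs$sequence[ci])
    refi <- match(intToUtf8(refb, multiple = TRUE), BASES)
    L <- length(refi)
    gts <- lapply(lines, function(l) {
      p <- pileups_by_line[[l]][[cid]]
      if (is.null(p)) p <- matrix(0L, nrow = 4, ncol = L)
      genotype_matrix(p, min_depth, hom_fraction, het_minor_fraction)
    })
    names(gts) <- lines

    # positions where any confident line carries a non-reference allele
    nonref <- rep(FALSE, L)
    for (g in gts)
      nonref <- nonref | (g$state > 0L & (g$a1 != refi | g$a2 != refi))
    for (pos in which(nonref)) {
      alleles <- refi[pos]
      for (g in gts) if (g$state[pos] > 0L)
        alleles <- union(alleles, c(g$a1[pos], g$a2[pos]))
      if (length(alleles) > 2L) {
        n_multi <- n_multi + 1L
        next
      }
      alt <- setdiff(alleles, refi[pos])
      states <- vapply(gts, function(g) {
        if (g$state[pos] == 0L) return("missing")
        if (g$state[pos] == 2L) return("het")
        if (g$a1[pos] == refi[pos]) "hom_ref" else "hom_alt"
      }, character(1))
      depths <- vapply(gts, function(g) g$depth[pos], numeric(1))
      sites[[length(sites) + 1L]] <- data.frame(
        contig_id = cid, pos = pos - 1L, ref = BASES[refi[pos]],
        alt = BASES[alt], n_missing = sum(states == "missing"),
        stringsAsFactors = FALSE)
      gt_rows[[length(gt_rows) + 1L]] <- states
      dp_rows[[length(dp_rows) + 1L]] <- depths
    }
  }

  sites <- if (length(sites)) do.call(rbind, sites)
           else data.frame(contig_id = character(0), pos = integer(0),
                           ref = character(0), alt = character(0),
                           n_missing = integer(0))
  rownames(sites) <- NULL
  gt <- if (length(gt_rows)) do.call(rbind, gt_rows)
        else matrix(character(0), ncol = length(lines))
  dp <- if (length(dp_rows)) do.call(rbind, dp_rows)
        else matrix(numeric(0), ncol = length(lines))
  colnames(gt) <- lines
  colnames(dp) <- lines
  structure(list(sites = sites, gt = gt, dp = dp,
                 n_multiallelic = n_multi, lines = lines),
            class = "variant_set")
}

#' @export
print.variant_set <- function(x, ...) {
  cat(sprintf("%d bi-allelic variant sites over %d lines (%d multi-allelic excluded)\n",
              nrow(x$sites), length(x$lines), x$n_multiallelic))
  invisible(x)
}

#' Marker filter cascade for array-suitable SNPs
#'
#' Stage 1 removes sites with missing genotypes in `max_missing_lines` or
#' more lines (insufficient genotype data). Stage 2 removes sites with less
#' than `flank_len` bp to either contig end (no room for a probe). Stage 3
#' removes sites with another stage-1-surviving variant within `flank_len`
#' bp on the same contig; both neighbours fall. Each stage's bookkeeping is
#' recorded in a conservation-checked ledger.
#'
#' @param variants a `variant_set` from [call_variants()].
#' @param contig_lengths named integer vector (contig id -> length).
#' @param max_missing_lines missing-line threshold (default 3).
#' @param flank_len required clean flank in bp (default 50).
#' @return list with `panel` (surviving `variant_set`) and `ledger`
#'   (data frame `stage`, `input`, `removed`, `output`).
#' @export
filter_cascade <- function(variants, contig_lengths, max_missing_lines = 3L,
                           flank_len = 50L) {
  s <- variants$sites
  if (nrow(s) > 1) {
    o <- order(s$contig_id, s$pos, method = "radix")
    if (!identical(o, seq_len(nrow(s))))
      stop_config("variants must be sorted by (contig, pos)")
  }
  n0 <- nrow(s)

  keep1 <- s$n_missing < max_missing_lines
  n1 <- sum(keep1)

  clen <- contig_lengths[s$contig_id]
  has_flank <- s$pos >= flank_len & (clen - s$pos - 1L) >= flank_len
  keep2 <- keep1 & has_flank
  n2 <- sum(keep2)

  # neighbour interference against all stage-1 survivors
  keep3 <- keep2
  idx2 <- which(keep2)
  idx1 <- which(keep1)
  for (i in idx2) {
    same <- idx1[s$contig_id[idx1] == s$contig_id[i] & idx1 != i]
    if (length(same) && any(abs(s$pos[same] - s$pos[i]) <= flank_len))
      keep3[i] <- FALSE
  }
  n3 <- sum(keep3)

  ledger <- data.frame(
    stage = c("low_genotype_data", "insufficient_flank",
              "nearby_polymorphism"),
    input = c(n0, n1, n2),
    removed = c(n0 - n1, n1 - n2, n2 - n3),
    output = c(n1, n2, n3),
    stringsAsFactors = FALSE)

  panel <- structure(list(
    sites = s[keep3, , drop = FALSE],
    gt = variants$gt[keep3, , drop = FALSE],
    dp = variants$dp[keep3, , drop = FALSE],
    n_multiallelic = variants$n_multiallelic,
    lines = variants$lines), class = "variant_set")
  rownames(panel$sites) <- NULL
  list(panel = panel, ledger = ledger)
}

#' Round half away from zero
#'
#' Fixed-precision rounding where .5 always rounds up, matching how the
#' percentage columns of marker-filtering reports are conventionally
#' printed (base R's `round()` rounds half to even).
#'
#' @param x numeric vector.
#' @param digits decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1L) {
  floor(x * 10^digits + 0.5) / 10^digits
}

#' Derived bookkeeping of the SNP filter ledger
#'
#' Pure arithmetic over the headline counts of a discovery run: total
#' possible genotypes, high-confidence call counts and percentage
#' breakdowns (one decimal, half-up), counts surviving the initial
#' missing-data filter, and the final array-suitable panel size.
#'
#' @param n_variants total variant sites identified.
#' @param n_lines lines genotyped.
#' @param n_missing_calls genotype calls that were missing or low quality.
#' @param n_low_data_loci sites with missing calls in too many lines.
#' @param n_het_calls heterozygous calls among the high-confidence calls.
#' @param n_flank_fail sites lacking flanking sequence.
#' @param n_nearby_poly sites with a polymorphism within the flank window.
#' @return named list of derived quantities.
#' @export
ledger_report <- function(n_variants, n_lines, n_missing_calls,
                          n_low_data_loci, n_het_calls, n_flank_fail,
                          n_nearby_poly) {
  if (n_lines <= 0) stop_config("n_lines must be positive")
  if (any(c(n_variants, n_missing_calls, n_low_data_loci, n_het_calls,
            n_flank_fail, n_nearby_poly) < 0))
    stop_config("counts must be non-negative")
  total <- n_variants * n_lines
  high_conf <- total - n_missing_calls
  fixed <- high_conf - n_het_calls
  passing <- n_variants - n_low_data_loci
  panel <- passing - n_flank_fail - n_nearby_poly
  list(
    total_possible_genotypes = total,
    n_high_confidence = high_conf,
    pct_high_confidence = round_half_up(100 * high_conf / total),
    pct_missing = round_half_up(100 * n_missing_calls / total),
    n_passing_initial = passing,
    n_fixed_calls = fixed,
    pct_fixed = round_half_up(100 * fixed / high_conf),
    pct_het = round_half_up(100 * n_het_calls / high_conf),
    pct_flank_fail = round_half_up(100 * n_flank_fail / passing),
    n_panel = panel)
}

#' Substitution-type and positional summary of a variant set
#'
#' Transitions are A<->G and C<->T; all other ref/alt pairs are
#' transversions. The positional histogram bins each variant's offset from
#' its contig start.
#'
#' @param variants a `variant_set` (or its `sites` data frame).
#' @param n_contigs total retained contigs, for the fraction with >= 1 SNP
#'   (optional).
#' @param bin positional histogram bin width in bp (default 100).
#' @return object of class `snp_summary`: `transitions`, `transversions`,
#'   `tstv` (NA when no transversions), `pos_hist`, `per_contig`,
#'   `n_contigs_with_snp`, `frac_contigs_with_snp`.
#' @export
snp_summary <- function(variants, n_contigs = NA_integer_, bin = 100L) {
  s <- if (inherits(variants, "variant_set")) variants$sites else variants
  if (nrow(s) == 0) stop_config("empty variant set")
  pair <- paste0(pmin(s$ref, s$alt), pmax(s$ref, s$alt))
  is_ts <- pair %in% c("AG", "CT")
  ts <- sum(is_ts)
  tv <- sum(!is_ts)
  per_contig <- table(s$contig_id)
  breaks <- seq(0L, (max(s$pos) %/% bin + 1L) * bin, by = bin)
  structure(list(
    transitions = ts, transversions = tv,
    tstv = if (tv > 0) ts / tv else NA_real_,
    pos_hist = table(cut(s$pos, breaks = breaks, right = FALSE)),
    per_contig = per_contig,
    n_contigs_with_snp = length(per_contig),
    frac_contigs_with_snp =
      if (is.na(n_contigs)) NA_real_ else length(per_contig) / n_contigs
  ), class = "snp_summary")
}

#' @export
print.snp_summary <- function(x, ...) {
  cat(sprintf("Ts %d / Tv %d (ratio %s); %d contigs carry a SNP",
              x$transitions, x$transversions,
              if (is.na(x$tstv)) "undefined" else sprintf("%.2f", x$tstv),
              x$n_contigs_with_snp))
  if (!is.na(x$frac_contigs_with_snp))
    cat(sprintf(" (%.0f%%)", 100 * x$frac_contigs_with_snp))
  cat("\n")
  invisible(x)
}
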