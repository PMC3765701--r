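#' Run the full RAD-Seq discovery pipeline on a simulated library
#'
#' Chains simulate, demultiplex, quality filter, cluster, assemble, screen,
#' align, call, filter and report, collecting a machine-readable manifest of
#' per-stage record counts. The reference is assembled from the first line
#' (mirroring a single-line framework assembly); all lines, the reference
#' line included, are then aligned to it and genotyped.
#'
#' @param config a [sim_config()].
#' @param contaminants optional contaminant sequences for the plastid
#'   screen; when `NULL` the screen stage flags nothing.
#' @param outdir optional directory for artifacts (reference FASTA, VCFs,
#'   ledger and summary TSVs, manifest JSON).
#' @param cluster_min,cluster_max RAD locus depth gates (50 / 750).
#' @param k,coverage_cutoff,min_contig_len assembler settings (31 / 3 / 200).
#' @param seed_len,max_mismatches aligner settings (20 / 3).
#' @param min_base_qual minimum phred base quality counted in pileups (13).
#' @param gt_min_depth,hom_fraction,het_minor_fraction genotyping settings
#'   (4 / 0.90 / 0.25).
#' @param max_missing_lines,flank_len filter-cascade settings (3 / 50).
#' @return object of class `rad_run` carrying every stage's artifacts and
#'   the manifest.
#' @export
run_pipeline <- function(config, contaminants = NULL, outdir = NULL,
                         cluster_min = 50L, cluster_max = 750L,
                         k = 31L, coverage_cutoff = 3L,
                         min_contig_len = 200L,
                         seed_len = 20L, max_mismatches = 3L,
                         min_base_qual = 13L,
                         gt_min_depth = 4L, hom_fraction = 0.90,
                         het_minor_fraction = 0.25,
                         max_missing_lines = 3L, flank_len = 50L) {
  stopifnot(inherits(config, "sim_config"))
  manifest <- list(config_seed = config$seed,
                   version = as.character(utils::packageVersion("radsnp")),
                   stages = list())
  note <- function(stage, n_in, n_out, t0) {
    manifest$stages[[length(manifest$stages) + 1L]] <<- list(
      stage = stage, n_in = n_in, n_out = n_out,
      seconds = round(as.numeric(proc.time()[3] - t0), 2))
  }
  fail <- function(stage, e) {
    stop(sprintf("pipeline stage '%s' failed: %s", stage,
                 conditionMessage(e)), call. = FALSE)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e) fail(stage, e))
  }

  t0 <- proc.time()[3]
  sim <- run_stage("simulate", simulate_rad_library(config))
  note("simulate", config$genome_length, nrow(sim$reads), t0)

  t0 <- proc.time()[3]
  dm <- run_stage("demux", demultiplex(sim$reads, config$barcodes))
  note("demux", nrow(sim$reads), dm$report$n_assigned, t0)

  t0 <- proc.time()[3]
  filtered <- run_stage("quality_filter",
                        lapply(dm$stores, quality_filter))
  stores <- lapply(filtered, `[[`, "kept")
  note("quality_filter", dm$report$n_assigned,
       sum(vapply(stores, nrow, integer(1))), t0)

  ref_line <- config$line_ids[1]
  t0 <- proc.time()[3]
  cl <- run_stage("cluster",
                  cluster_loci(stores[[ref_line]], min_depth = cluster_min,
                               max_depth = cluster_max))
  note("cluster", nrow(stores[[ref_line]]), cl$report$n_kept, t0)

  t0 <- proc.time()[3]
  asm <- run_stage("assemble",
                   assemble_rad_loci(cl$loci, k = k,
                                     coverage_cutoff = coverage_cutoff,
                                     min_contig_len = min_contig_len))
  note("assemble", cl$report$n_kept, asm$report$n_retained, t0)

  t0 <- proc.time()[3]
  if (!is.null(contaminants)) {
    scr <- run_stage("screen", plastid_screen(asm$contigs, contaminants))
    contigs <- scr$contigs
    screen_report <- scr$report
  } else {
    contigs <- asm$contigs
    screen_report <- list(n_screened = asm$report$n_retained,
                          n_flagged = 0L,
                          n_retained = asm$report$n_retained)
  }
  note("screen", screen_report$n_screened, screen_report$n_retained, t0)

  t0 <- proc.time()[3]
  retained <- contigs[contigs$flag == "retained", , drop = FALSE]
  if (nrow(retained) == 0)
    fail("align", simpleError("no retained contigs to align against"))
  index <- run_stage("align", build_index(retained, seed_len = seed_len))
  aligned <- run_stage("align", lapply(config$line_ids, function(l)
    align_reads(stores[[l]], index, l, max_mismatches = max_mismatches)))
  names(aligned) <- config$line_ids
  n_accepted <- sum(vapply(aligned, function(a) a$report$n_accepted,
                           integer(1)))
  note("align", sum(vapply(stores, nrow, integer(1))), n_accepted, t0)

  t0 <- proc.time()[3]
  pileups <- run_stage("call", lapply(aligned, function(a)
    build_pileups(a$alignments, retained, min_base_qual = min_base_qual)))
  variants <- run_stage("call",
    call_variants(pileups, retained, min_depth = gt_min_depth,
                  hom_fraction = hom_fraction,
                  het_minor_fraction = het_minor_fraction))
  note("call", n_accepted, nrow(variants$sites), t0)

  t0 <- proc.time()[3]
  clen <- stats::setNames(nchar(retained$sequence), retained$contig_id)
  casc <- run_stage("filter",
    filter_cascade(variants, clen, max_missing_lines = max_missing_lines,
                   flank_len = flank_len))
  note("filter", nrow(variants$sites), nrow(casc$panel$sites), t0)

  t0 <- proc.time()[3]
  stats <- run_stage("report", assembly_stats(contigs))
  summ <- if (nrow(variants$sites) > 0)
    snp_summary(variants, n_contigs = nrow(retained)) else NULL
  note("report", nrow(casc$panel$sites), nrow(casc$panel$sites), t0)

  run <- structure(list(
    config = config, sim = sim, demux_report = dm$report,
    stores = stores,
    quality_discarded = vapply(filtered, `[[`, integer(1), "n_discarded"),
    cluster_report = cl$report, loci = cl$loci,
    contigs = contigs, assembly_report = asm$report,
    screen_report = screen_report, assembly_stats = stats,
    align_reports = lapply(aligned, `[[`, "report"),
    alignments = lapply(aligned, `[[`, "alignments"),
    pileups = pileups, variants = variants,
    panel = casc$panel, ledger = casc$ledger,
    summary = summ, manifest = manifest,
    params = list(min_base_qual = min_base_qual,
                  gt_min_depth = gt_min_depth,
                  max_missing_lines = max_missing_lines,
                  flank_len = flank_len)), class = "rad_run")
  if (!is.null(outdir)) write_run_artifacts(run, outdir)
  run
}

#' @export
print.rad_run <- function(x, ...) {
  cat(sprintf(
    "RAD-Seq run (seed %d): %d retained contigs, %d variants, %d panel SNPs\n",
    x$config$seed, sum(x$contigs$flag == "retained"),
    nrow(x$variants$sites), nrow(x$panel$sites)))
  invisible(x)
}

#' @noRd
write_run_artifacts <- function(run, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  retained <- run$contigs[run$contigs$flag == "retained", , drop = FALSE]
  write_reference_fasta(retained, file.path(outdir, "reference.fasta"))
  write_vcf(run$variants, retained, file.path(outdir, "variants.vcf"))
  write_vcf(run$panel, retained, file.path(outdir, "panel.vcf"))
  utils::write.table(run$ledger, file.path(outdir, "filter_ledger.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(run$manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(outdir)
}

# Map retained contigs back to ancestral-genome coordinates by exact search
# against the reference line's haplotype (error-free contigs are exact
# substrings; contigs that cannot be placed are reported unmapped).
#' @noRd
map_contigs_to_genome <- function(run) {
  genome <- run$sim$lines[[run$config$line_ids[1]]]$hap1
  retained <- run$contigs[run$contigs$flag == "retained", , drop = FALSE]
  rows <- lapply(seq_len(nrow(retained)), function(i) {
    ctg <- retained$sequence[i]
    m <- regexpr(ctg, genome, fixed = TRUE)
    if (m > 0)
      return(data.frame(contig_id = retained$contig_id[i],
                        gstart = as.integer(m) - 1L, strand = "+",
                        len = nchar(ctg), stringsAsFactors = FALSE))
    m <- regexpr(revcomp(ctg), genome, fixed = TRUE)
    if (m > 0)
      return(data.frame(contig_id = retained$contig_id[i],
                        gstart = as.integer(m) - 1L, strand = "-",
                        len = nchar(ctg), stringsAsFactors = FALSE))
    NULL
  })
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows)) do.call(rbind, rows)
  else data.frame(contig_id = character(0), gstart = integer(0),
                  strand = character(0), len = integer(0))
}

# ancestral position of a site at contig offset `pos`
#' @noRd
contig_pos_to_genome <- function(map_row, pos) {
  if (map_row$strand == "+") map_row$gstart + pos
  else map_row$gstart + map_row$len - 1L - pos
}

#' Score a pipeline run against its simulation truth
#'
#' Maps retained contigs back to ancestral coordinates and compares the
#' called variants and the final panel with the planted truth SNPs.
#' Precision is the fraction of panel SNPs that are planted truth SNPs
#' (position and allele set). Recall is computed over the *eligible* truth
#' subset: planted SNPs that fall at least `flank_len` bp inside a retained
#' contig, have no other planted SNP within `flank_len` bp on that contig,
#' present at most two alleles, are covered at genotyping depth in all but
#' at most `max_missing_lines - 1` lines, and are polymorphic against the
#' reference base among the covered lines.
#'
#' @param run a `rad_run`.
#' @param truth a simulation truth list; defaults to the run's own. A seed
#'   mismatch between run and truth is an error.
#' @return list with `precision`, `recall`, counts at each eligibility
#'   stage, and the mapped panel table.
#' @export
evaluate_against_truth <- function(run, truth = run$sim$truth) {
  stopifnot(inherits(run, "rad_run"))
  if (!identical(truth$seed, run$config$seed))
    stop_config("truth seed (%s) does not match run seed (%s)",
                truth$seed, run$config$seed)
  p <- run$params
  flank <- p$flank_len
  cmap <- map_contigs_to_genome(run)
  tv <- truth$variants

  # panel sites in ancestral coordinates
  panel <- run$panel$sites
  panel$gpos <- rep(NA_integer_, nrow(panel))
  for (i in seq_len(nrow(panel))) {
    r <- cmap[cmap$contig_id == panel$contig_id[i], ]
    if (nrow(r) == 1) panel$gpos[i] <- contig_pos_to_genome(r, panel$pos[i])
  }

  truth_pos <- unique(tv$pos)
  if (length(truth_pos) == 0) {
    precision <- if (nrow(panel) == 0) NA_real_ else 0
    return(list(precision = precision, recall = NA_real_,
                n_truth = 0L, n_in_contig = 0L, n_eligible = 0L,
                n_found = 0L, panel = panel))
  }

  # per-position truth allele table (ancestral + per-line derived)
  anc <- run$sim$ancestral
  line_ids <- run$config$line_ids
  allele_at <- function(pos) {
    a <- substr(anc, pos + 1L, pos + 1L)
    al <- stats::setNames(rep(a, length(line_ids)), line_ids)
    hits <- tv[tv$pos == pos, ]
    al[hits$line_id] <- hits$alt
    al
  }

  # precision: every panel SNP must be a planted SNP with consistent
  # alleles (complemented for contigs mapped to the minus strand)
  is_tp <- vapply(seq_len(nrow(panel)), function(i) {
    g <- panel$gpos[i]
    if (is.na(g) || !(g %in% truth_pos)) return(FALSE)
    truth_alleles <- unique(c(substr(anc, g + 1L, g + 1L), allele_at(g)))
    strand <- cmap$strand[match(panel$contig_id[i], cmap$contig_id)]
    obs <- c(panel$ref[i], panel$alt[i])
    if (identical(strand, "-")) obs <- chartr("ACGT", "TGCA", obs)
    all(obs %in% truth_alleles)
  }, logical(1))
  precision <- if (nrow(panel) == 0) NA_real_ else mean(is_tp)

  # eligibility of each planted SNP position
  in_contig <- integer(0)
  eligible <- integer(0)
  for (g in truth_pos) {
    hit <- cmap[cmap$gstart <= g & g < cmap$gstart + cmap$len, ]
    if (nrow(hit) == 0) next
    hit <- hit[1, ]
    off <- if (hit$strand == "+") g - hit$gstart
           else hit$gstart + hit$len - 1L - g
    in_contig <- c(in_contig, g)
    if (off < flank || hit$len - off - 1L < flank) next
    neigh <- setdiff(truth_pos[abs(truth_pos - g) <= flank], g)
    neigh <- neigh[neigh >= hit$gstart & neigh < hit$gstart + hit$len]
    if (length(neigh) > 0) next
    al <- allele_at(g)
    if (length(unique(c(substr(anc, g + 1L, g + 1L), al))) > 2) next
    depth <- vapply(line_ids, function(l) {
      m <- run$pileups[[l]][[hit$contig_id]]
      if (is.null(m)) return(0)
      sum(m[, off + 1L])
    }, numeric(1))
    covered <- depth >= p$gt_min_depth
    if (sum(!covered) >= p$max_missing_lines) next
    refbase <- substr(run$contigs$sequence[
      match(hit$contig_id, run$contigs$contig_id)], off + 1L, off + 1L)
    if (hit$strand == "-") refbase <- chartr("ACGT", "TGCA", refbase)
    if (!any(al[covered] != refbase)) next
    eligible <- c(eligible, g)
  }
  found <- intersect(eligible, panel$gpos[is_tp])
  recall <- if (length(eligible) == 0) NA_real_
            else length(found) / length(eligible)
  list(precision = precision, recall = recall,
       n_truth = length(truth_pos), n_in_contig = length(in_contig),
       n_eligible = length(eligible), n_found = length(found),
       panel = panel)
}

#' False-positive rate of a null run
#'
#' For a run simulated with `snp_rate = 0`, every called variant is a false
#' positive. The rate is expressed per 50 kb of pileup, where the pileup
#' size is the number of covered (line, contig, position) columns.
#'
#' @param run a `rad_run`.
#' @return list with `n_fp`, `pileup_bp` and `fp_per_50kb`.
#' @export
false_positive_rate <- function(run) {
  pileup_bp <- sum(vapply(run$pileups, function(pl)
    sum(vapply(pl, function(m) sum(colSums(m) > 0), numeric(1))),
    numeric(1)))
  n_fp <- nrow(run$variants$sites)
  list(n_fp = n_fp, pileup_bp = pileup_bp,
       fp_per_50kb = if (pileup_bp > 0) n_fp / pileup_bp * 50000
                     else NA_real_)
}
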