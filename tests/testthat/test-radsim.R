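test_that("ancestral genome generation honours length, GC and seed", {
  expect_error(sim_config(genome_length = 0), "genome_length")
  expect_error(sim_config(gc_content = 1.2), "gc_content")

  cfg <- sim_config(genome_length = 100000, gc_content = 0.361, seed = 7)
  g <- generate_ancestral_genome(cfg)
  expect_equal(nchar(g), 100000)
  expect_false(grepl("[^ACGT]", g))
  counts <- table(strsplit(g, "")[[1]])
  gc <- sum(counts[c("C", "G")]) / sum(counts)
  expect_gte(gc, 0.341)
  expect_lte(gc, 0.381)
  expect_identical(g, generate_ancestral_genome(cfg))
})

test_that("line genomes plant SNPs at the configured rate and Ts/Tv", {
  cfg0 <- sim_config(genome_length = 5000, snp_rate = 0, seed = 3)
  anc <- generate_ancestral_genome(cfg0)
  d0 <- derive_line_genomes(anc, cfg0)
  expect_identical(d0$lines[[1]]$hap1, anc)
  expect_equal(nrow(d0$variants), 0)

  # binomial density: n = 1.43 Mb, p = 1/143 -> 10,000 +- 3 sd per line
  cfg <- sim_config(genome_length = 1430000, snp_rate = 1 / 143,
                    n_lines = 1, seed = 5)
  anc <- generate_ancestral_genome(cfg)
  d <- derive_line_genomes(anc, cfg)
  n <- nrow(d$variants)
  sd <- sqrt(1430000 * (1 / 143) * (1 - 1 / 143))
  expect_lt(abs(n - 10000), 3 * sd)

  # empirical Ts/Tv near the configured 1.72 at >= 10k variants
  is_ts <- paste0(pmin(d$variants$ref, d$variants$alt),
                  pmax(d$variants$ref, d$variants$alt)) %in% c("AG", "CT")
  tstv <- sum(is_ts) / sum(!is_ts)
  expect_gte(tstv, 1.55)
  expect_lte(tstv, 1.90)

  # every planted variant differs from the ancestor on haplotype 1
  v <- d$variants[sample.int(n, 50), ]
  h1 <- d$lines[[1]]$hap1
  expect_true(all(substring(h1, v$pos + 1, v$pos + 1) == v$alt))
  expect_true(all(substring(anc, v$pos + 1, v$pos + 1) == v$ref))

  cfg_bad <- cfg
  cfg_bad$snp_rate <- 1
  expect_error(derive_line_genomes(anc, cfg_bad), "snp_rate")
})

test_that("heterozygous sites differ between haplotypes at het_rate", {
  cfg <- sim_config(genome_length = 50000, het_rate = 0.5, n_lines = 1,
                    seed = 9)
  d <- derive_line_genomes(generate_ancestral_genome(cfg), cfg)
  v <- d$lines[[1]]$variants
  expect_gt(sum(v$het), 0)
  h1 <- d$lines[[1]]$hap1
  h2 <- d$lines[[1]]$hap2
  het <- v[v$het, ]
  hom <- v[!v$het, ]
  expect_true(all(substring(h2, het$pos + 1, het$pos + 1) == het$ref))
  expect_true(all(substring(h1, het$pos + 1, het$pos + 1) == het$alt))
  expect_true(all(substring(h2, hom$pos + 1, hom$pos + 1) == hom$alt))
})

test_that("digestion cuts at unmasked sites and tiles the genome", {
  cfg <- sim_config(genome_length = 100, seed = 1)
  g <- "AAACTGCAGTTTCTGCAGGGG"   # sites at 0-based 3 and 12
  f <- digest_genome(g, cfg)
  expect_equal(f$start, c(0, 8, 17))
  expect_equal(f$end, c(8, 17, 21))
  expect_identical(paste(f$seq, collapse = ""), g)

  f0 <- digest_genome("AAATTTGGGCCC", cfg)
  expect_equal(nrow(f0), 1)
  expect_equal(f0$end, 12)

  fm <- digest_genome(g, cfg, methylation_mask = c(12L))
  expect_equal(fm$start, c(0, 8))
  expect_equal(fm$end, c(8, 21))
})

test_that("digestion conservation holds on random genomes", {
  for (s in 1:25) {
    g <- genome_with_sites(3000, 8, seed = s)
    cfg <- sim_config(genome_length = 3000, seed = s)
    f <- digest_genome(g, cfg)
    expect_identical(paste(f$seq, collapse = ""), g)
  }
})

test_that("shearing draws size-selected molecules anchored at cut ends", {
  cfg <- sim_config(genome_length = 3000, seed = 4)
  # a too-short parent between two cuts yields nothing
  short_parent <- data.frame(start = 100L, end = 350L,
                             seq = strrep("A", 250))
  expect_warning(
    sh0 <- shear_and_select(short_parent, cfg, n_per_end = 20, seed = 1),
    "size-selection")
  expect_equal(nrow(sh0), 0)

  # truncated-normal moments: mean of 10,000 draws in [490, 510]
  long_parent <- data.frame(start = 1000L, end = 3000L,
                            seq = strrep("A", 2000))
  sh <- shear_and_select(long_parent, cfg, n_per_end = 10000, seed = 2)
  expect_true(all(sh$len >= 300 & sh$len <= 700))
  expect_gt(mean(sh$len), 490)
  expect_lt(mean(sh$len), 510)

  # an internal fragment bounded by cuts on both sides yields two loci
  frags <- data.frame(start = c(800L, 1800L), end = c(1800L, 2200L),
                      seq = c(strrep("A", 1000), strrep("C", 400)))
  sh2 <- shear_and_select(frags, cfg, n_per_end = 5, seed = 3)
  expect_setequal(unique(sh2$dir), c("+", "-"))
  expect_gte(length(unique(sh2$locus_id)), 2)
})

test_that("emitted reads carry the barcode, site remnant and truth ids", {
  cfg <- sim_config(genome_length = 20000, n_lines = 2, seed = 11,
                    reads_per_locus = 5)
  sim <- simulate_rad_library(cfg)
  expect_gt(nrow(sim$reads), 0)
  # read1 = barcode + remnant TGCAG at slice [4:9)
  bc <- cfg$barcodes[sim$reads$line_id]
  expect_true(all(substr(sim$reads$seq1, 1, 4) == bc))
  expect_true(all(substr(sim$reads$seq1, 5, 9) == "TGCAG"))
  expect_true(all(nchar(sim$reads$seq1) == 40))
  expect_true(all(nchar(sim$reads$seq2) == 80))
  expect_true(all(nchar(sim$reads$qual1) == 40))

  # error-free round trip: the genomic part of read1 is a substring of its
  # line's haplotype (either strand)
  h <- vapply(sim$reads$line_id, function(l) sim$lines[[l]]$hap1,
              character(1))
  for (i in sample.int(nrow(sim$reads), min(25, nrow(sim$reads)))) {
    genomic <- substr(sim$reads$seq1[i], 5, 40)
    expect_true(grepl(genomic, h[i], fixed = TRUE) ||
                  grepl(revcomp(genomic), h[i], fixed = TRUE))
  }

  # duplicate / near-duplicate barcodes are a configuration error
  expect_error(sim_config(n_lines = 2,
                          barcodes = c(a = "ACGT", b = "ACGA")),
               "Hamming")
  expect_error(sim_config(n_lines = 2,
                          barcodes = c(a = "ACGT", b = "ACGT")),
               "unique")
})

test_that("FASTQ emission is structurally sound and seed-deterministic", {
  cfg <- sim_config(genome_length = 20000, n_lines = 2, seed = 13,
                    reads_per_locus = 5, error_rate = 0.01)
  d1 <- file.path(tempdir(), "simA")
  d2 <- file.path(tempdir(), "simB")
  sim1 <- simulate_rad_library(cfg, outdir = d1)
  sim2 <- simulate_rad_library(cfg, outdir = d2)

  fq <- readLines(file.path(d1, "reads_1.fastq"))
  expect_equal(length(fq), 4 * nrow(sim1$reads))
  expect_true(all(startsWith(fq[seq(1, length(fq), 4)], "@")))

  for (f in c("reads_1.fastq", "reads_2.fastq", "truth.vcf",
              "truth_loci.bed")) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), label = f)
  }
  unlink(c(d1, d2), recursive = TRUE)
})

test_that("paired FASTQ round-trips through the readers", {
  cfg <- sim_config(genome_length = 20000, n_lines = 1, seed = 17,
                    reads_per_locus = 5)
  sim <- simulate_rad_library(cfg)
  pre <- file.path(tempdir(), "rt")
  write_fastq_pair(sim$reads, pre)
  back <- read_fastq_pair(pre)
  expect_equal(back$seq1, sim$reads$seq1)
  expect_equal(back$qual2, sim$reads$qual2)
  expect_equal(back$read_id, sim$reads$read_id)
  unlink(paste0(pre, c("_1.fastq", "_2.fastq")))
})

test_that("methylation masking suppresses cuts in the library", {
  cfg_all <- sim_config(genome_length = 60000, seed = 19,
                        methylated_site_fraction = 1)
  g <- generate_ancestral_genome(cfg_all)
  mask <- radsnp:::sample_methylation_mask(g, cfg_all)
  expect_equal(nrow(digest_genome(g, cfg_all, methylation_mask = mask)), 1)
})
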