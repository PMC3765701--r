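counts <- function(A = 0, C = 0, G = 0, T = 0) c(A = A, C = C, G = G, T = T)

test_that("per-site genotyping follows depth and fraction thresholds", {
  expect_equal(genotype_site(counts(A = 3))$state, "missing")
  g <- genotype_site(counts(G = 10))
  expect_equal(g$state, "hom")
  expect_equal(g$alleles, "G")
  h <- genotype_site(counts(A = 5, G = 5))
  expect_equal(h$state, "het")
  expect_setequal(h$alleles, c("A", "G"))
  # 9:1 at depth 10 -> major fraction 0.9 is homozygous
  expect_equal(genotype_site(counts(A = 9, G = 1))$state, "hom")
  # 8:2 -> neither hom (0.8) nor is the minor < 0.25: het
  expect_equal(genotype_site(counts(A = 8, G = 2))$state, "missing")
  expect_equal(genotype_site(counts(A = 7, G = 3))$state, "het")
})

# build pileup lists directly: one contig, bases given per line as strings
pileup_from_strings <- function(contig, per_line) {
  lapply(per_line, function(reads) {
    m <- matrix(0L, nrow = 4, ncol = nchar(contig),
                dimnames = list(c("A", "C", "G", "T"), NULL))
    for (r in reads) {
      b <- strsplit(r, "")[[1]]
      for (j in seq_along(b)) {
        if (b[j] == ".") b[j] <- substr(contig, j, j)
        m[b[j], j] <- m[b[j], j] + 1L
      }
    }
    list(c1 = m)
  })
}

test_that("variant calling reports bi-allelic non-reference sites", {
  ctg <- strrep("ACGT", 10)
  contigs <- data.frame(contig_id = "c1", sequence = ctg)

  dots <- strrep(".", 40)

  # all hom-ref: no variants
  same <- pileup_from_strings(ctg, list(l1 = rep(dots, 10),
                                        l2 = rep(dots, 10)))
  v0 <- call_variants(same, contigs)
  expect_equal(nrow(v0$sites), 0)

  # one line hom-alt at position 5 (0-based 4; ref A -> G)
  alt <- paste0(substr(ctg, 1, 4), "G", substr(ctg, 6, 40))
  alt_reads <- pileup_from_strings(ctg, list(l1 = rep(dots, 10),
                                             l2 = rep(alt, 10)))
  v1 <- call_variants(alt_reads, contigs)
  expect_equal(nrow(v1$sites), 1)
  expect_equal(v1$sites$pos, 4)
  expect_equal(v1$sites$ref, "A")
  expect_equal(v1$sites$alt, "G")
  expect_equal(unname(v1$gt[1, ]), c("hom_ref", "hom_alt"))

  # three alleles across lines -> excluded and counted
  alt2 <- paste0(substr(ctg, 1, 4), "C", substr(ctg, 6, 40))
  multi <- pileup_from_strings(ctg, list(l1 = rep(dots, 10),
                                         l2 = rep(alt, 10),
                                         l3 = rep(alt2, 10)))
  v2 <- call_variants(multi, contigs)
  expect_equal(nrow(v2$sites), 0)
  expect_equal(v2$n_multiallelic, 1)
})

fake_variants <- function(contig_id, pos, n_missing = 0,
                          lines = c("l1", "l2")) {
  n <- length(pos)
  structure(list(
    sites = data.frame(contig_id = contig_id, pos = as.integer(pos),
                       ref = "A", alt = "G",
                       n_missing = rep_len(n_missing, n),
                       stringsAsFactors = FALSE),
    gt = matrix("hom_ref", n, length(lines),
                dimnames = list(NULL, lines)),
    dp = matrix(10, n, length(lines), dimnames = list(NULL, lines)),
    n_multiallelic = 0L, lines = lines), class = "variant_set")
}

test_that("the filter cascade applies flank and neighbour rules", {
  clen <- c(c1 = 400L)
  # a site 30 bp from the contig start fails the flank stage
  v <- fake_variants("c1", c(30, 200))
  fc <- filter_cascade(v, clen)
  expect_equal(fc$ledger$removed, c(0, 1, 0))
  expect_equal(fc$panel$sites$pos, 200)

  # two survivors 40 bp apart both fall at the neighbour stage
  v2 <- fake_variants("c1", c(150, 190))
  fc2 <- filter_cascade(v2, clen)
  expect_equal(fc2$ledger$removed, c(0, 0, 2))
  expect_equal(nrow(fc2$panel$sites), 0)

  # 51 bp apart mid-contig: both retained
  v3 <- fake_variants("c1", c(150, 201))
  fc3 <- filter_cascade(v3, clen)
  expect_equal(nrow(fc3$panel$sites), 2)

  # a stage-1 survivor that fails the flank stage still interferes
  v4 <- fake_variants("c1", c(30, 70))
  fc4 <- filter_cascade(v4, clen)
  expect_equal(fc4$ledger$removed, c(0, 1, 1))

  # missing-data stage: >= 3 missing lines removed first
  v5 <- fake_variants("c1", c(100, 200), n_missing = c(3, 0))
  fc5 <- filter_cascade(v5, clen)
  expect_equal(fc5$ledger$removed[1], 1)

  expect_error(filter_cascade(fake_variants("c1", c(200, 100)), clen),
               "sorted")
})

test_that("ledger conservation holds on random variant sets", {
  set.seed(91)
  for (i in 1:20) {
    n <- sample.int(60, 1)
    clen <- c(cA = 400L, cB = 300L)
    v <- fake_variants(sample(names(clen), n, replace = TRUE),
                       sample.int(280, n, replace = TRUE) - 1L,
                       n_missing = sample(0:4, n, replace = TRUE))
    o <- order(v$sites$contig_id, v$sites$pos)
    v$sites <- v$sites[o, ]
    v$gt <- v$gt[o, , drop = FALSE]
    v$dp <- v$dp[o, , drop = FALSE]
    fc <- filter_cascade(v, clen)
    ld <- fc$ledger
    expect_equal(ld$input - ld$removed, ld$output)
    expect_equal(ld$input[-1], ld$output[-length(ld$output)])
    expect_equal(ld$input[1], n)
    expect_equal(ld$output[nrow(ld)], nrow(fc$panel$sites))
  }
})

test_that("snp summaries classify substitution types", {
  s <- data.frame(contig_id = c("c1", "c1", "c2"), pos = c(10, 150, 20),
                  ref = c("A", "C", "A"), alt = c("G", "T", "C"))
  sm <- snp_summary(s, n_contigs = 4)
  expect_equal(sm$transitions, 2)
  expect_equal(sm$transversions, 1)
  expect_equal(sm$tstv, 2.0)
  expect_equal(sm$n_contigs_with_snp, 2)
  expect_equal(sum(sm$pos_hist), 3)

  tv_only <- snp_summary(data.frame(contig_id = "c1", pos = 5,
                                    ref = "A", alt = "T"))
  expect_equal(tv_only$tstv, 0 / 1)
  ts_only <- snp_summary(data.frame(contig_id = "c1", pos = 5,
                                    ref = "A", alt = "G"))
  expect_true(is.na(ts_only$tstv))
})
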