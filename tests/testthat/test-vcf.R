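simulated_variant_set <- function(n_sites, contig_len = 2000L, seed = 101) {
  set.seed(seed)
  ctg <- random_dna(contig_len)
  pos <- sort(sample.int(contig_len - 2L, n_sites))
  ref <- substring(ctg, pos + 1L, pos + 1L)
  alt <- vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b),
                                        1), character(1))
  lines <- c("l1", "l2", "l3")
  gt <- matrix(sample(c("hom_ref", "hom_alt", "het", "missing"),
                      n_sites * 3, replace = TRUE), ncol = 3,
               dimnames = list(NULL, lines))
  dp <- matrix(sample(4:60, n_sites * 3, replace = TRUE), ncol = 3)
  dp[gt == "missing"] <- sample(0:3, sum(gt == "missing"), replace = TRUE)
  list(contigs = data.frame(contig_id = "c1", sequence = ctg),
       vs = structure(list(
         sites = data.frame(contig_id = "c1", pos = pos, ref = ref,
                            alt = unname(alt), n_missing = 0L),
         gt = gt, dp = dp, n_multiallelic = 0L, lines = lines),
         class = "variant_set"))
}

test_that("VCF output uses 1-based positions and GT codes", {
  x <- simulated_variant_set(5)
  x$vs$gt[1, ] <- c("hom_ref", "het", "hom_alt")
  path <- tempfile(fileext = ".vcf")
  write_vcf(x$vs, x$contigs, path)
  back <- read_vcf_minimal(path)
  expect_equal(back$sites$pos, x$vs$sites$pos)   # 0-based after re-read
  ln <- readLines(path)
  first <- strsplit(ln[!startsWith(ln, "#")][1], "\t")[[1]]
  expect_equal(as.integer(first[2]), x$vs$sites$pos[1] + 1L)
  expect_equal(first[10:12], sprintf("%s:%d",
                                     c("0/0", "0/1", "1/1"),
                                     as.integer(x$vs$dp[1, ])))
  unlink(path)
})

test_that("a thousand simulated variants survive a VCF round trip", {
  x <- simulated_variant_set(1000)
  path <- tempfile(fileext = ".vcf")
  write_vcf(x$vs, x$contigs, path)

  # independent parser: vcfR
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  expect_equal(nrow(v@fix), 1000)
  expect_equal(as.integer(v@fix[, "POS"]), x$vs$sites$pos + 1L)
  expect_equal(unname(v@fix[, "REF"]), x$vs$sites$ref)
  expect_equal(unname(v@fix[, "ALT"]), x$vs$sites$alt)
  gt <- vcfR::extract.gt(v)
  code <- c(hom_ref = "0/0", hom_alt = "1/1", het = "0/1")
  for (l in x$vs$lines) {
    want <- unname(code[x$vs$gt[, l]])
    want[is.na(want)] <- "./."
    got <- unname(gt[, l])
    got[is.na(got)] <- "./."
    expect_equal(got, want)
  }
  unlink(path)
})

test_that("VCF writing validates positions and alleles", {
  x <- simulated_variant_set(3)
  bad <- x$vs
  bad$sites$pos[1] <- nchar(x$contigs$sequence[1]) + 5L
  expect_error(write_vcf(bad, x$contigs, tempfile()), "exceeds")
  bad2 <- x$vs
  bad2$sites$ref[1] <- setdiff(c("A", "C", "G", "T"),
                               bad2$sites$ref[1])[1]
  expect_error(write_vcf(bad2, x$contigs, tempfile()), "REF")
})

test_that("panel flanking FASTA centres the SNP as an IUPAC code", {
  x <- simulated_variant_set(4, contig_len = 500)
  keep <- x$vs$sites$pos >= 50 & x$vs$sites$pos < 449
  vs <- x$vs
  vs$sites <- vs$sites[keep, ]
  vs$gt <- vs$gt[keep, , drop = FALSE]
  vs$dp <- vs$dp[keep, , drop = FALSE]
  path <- tempfile(fileext = ".fasta")
  write_panel_fasta(vs, x$contigs, path)
  fa <- Biostrings::readBStringSet(path)
  expect_equal(length(fa), nrow(vs$sites))
  expect_true(all(Biostrings::width(fa) == 101))
  expect_true(all(!substr(as.character(fa), 51, 51) %in%
                    c("A", "C", "G", "T")))
  unlink(path)
})

test_that("SAM output carries mandatory columns and the NM tag", {
  set.seed(103)
  ctg <- random_dna(200)
  contigs <- data.frame(contig_id = "c1", sequence = ctg)
  idx <- build_index(contigs, seed_len = 20)
  store <- pair_table(seq1 = strrep("A", 36), qual1 = qstr(rep(40, 36)),
                      seq2 = revcomp(substr(ctg, 21, 100)),
                      qual2 = qstr(rep(40, 80)))
  al <- align_reads(store, idx, "lineX")
  path <- tempfile(fileext = ".sam")
  write_sam(al$alignments, contigs, path)
  ln <- readLines(path)
  expect_true(any(startsWith(ln, "@SQ\tSN:c1\tLN:200")))
  rec <- strsplit(ln[!startsWith(ln, "@")][1], "\t")[[1]]
  expect_equal(rec[2], "16")          # reverse strand flag
  expect_equal(as.integer(rec[4]), 21)
  expect_equal(rec[6], "80M")
  expect_equal(rec[12], "NM:i:0")
  unlink(path)
})
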