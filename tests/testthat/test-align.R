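ref_contigs <- function(...) {
  seqs <- c(...)
  data.frame(contig_id = sprintf("c%d", seq_along(seqs)), sequence = seqs,
             stringsAsFactors = FALSE)
}

test_that("the seed index resolves exact hits on both strands", {
  set.seed(71)
  ctg <- random_dna(200)
  idx <- build_index(ref_contigs(ctg), seed_len = 20)
  seed <- substr(ctg, 51, 70)
  h <- seed_hits(idx, seed)
  expect_equal(nrow(h), 1)
  expect_equal(h[1, 2], 50)           # 0-based offset
  expect_equal(nrow(seed_hits(idx, strrep("A", 20))), 0)

  # a read from the minus strand maps with strand "-"
  read <- revcomp(substr(ctg, 61, 140))
  m <- map_read(read, idx)
  expect_true(m$mapped)
  expect_equal(m$strand, "-")
  expect_equal(m$start, 60)
  expect_equal(m$mismatches, 0)

  expect_error(build_index(ref_contigs(ctg), seed_len = 7), ">= 8")
})

test_that("mapping enforces the mismatch ceiling and uniqueness", {
  set.seed(73)
  c1 <- random_dna(300)
  c2 <- random_dna(300)
  idx <- build_index(ref_contigs(c1, c2), seed_len = 20)

  exact <- substr(c1, 101, 180)
  m <- map_read(exact, idx)
  expect_true(m$mapped)
  expect_equal(m$contig_id, "c1")
  expect_equal(m$start, 100)
  expect_equal(m$mismatches, 0)

  # mutate 3 bases (outside one seed block) -> still mapped
  mut3 <- exact
  for (p in c(25, 45, 65))
    substr(mut3, p, p) <- setdiff(c("A", "C", "G", "T"),
                                  substr(exact, p, p))[1]
  m3 <- map_read(mut3, idx)
  expect_true(m3$mapped)
  expect_equal(m3$mismatches, 3)

  # a 4th mismatch exceeds the ceiling
  mut4 <- mut3
  substr(mut4, 35, 35) <- setdiff(c("A", "C", "G", "T"),
                                  substr(exact, 35, 35))[1]
  m4 <- map_read(mut4, idx)
  expect_false(m4$mapped)
  expect_equal(m4$reason, "unmapped")

  # a read present on two contigs is discarded as multi
  shared <- random_dna(80)
  idx2 <- build_index(ref_contigs(paste0(shared, random_dna(120)),
                                  paste0(random_dna(120), shared)),
                      seed_len = 20)
  mm <- map_read(shared, idx2)
  expect_false(mm$mapped)
  expect_equal(mm$reason, "multi")

  # reads overhanging the contig end cannot be placed
  over <- paste0(substr(c1, 261, 300), random_dna(40))
  expect_false(map_read(over, idx)$mapped)
})

test_that("pileups stack oriented bases and conserve depth", {
  set.seed(79)
  ctg <- random_dna(200)
  contigs <- ref_contigs(ctg)
  idx <- build_index(contigs, seed_len = 20)

  store1 <- pair_table(seq1 = strrep("A", 36), qual1 = qstr(rep(40, 36)),
                       seq2 = substr(ctg, 21, 100),
                       qual2 = qstr(rep(40, 80)))
  al <- align_reads(store1, idx, "lineX")
  expect_equal(al$report$n_accepted, 1)
  pl <- build_pileups(al$alignments, contigs)
  m <- pl$c1
  expect_equal(sum(m), 80)
  covered <- which(colSums(m) > 0)
  expect_equal(covered, 21:100)
  refbases <- strsplit(substr(ctg, 21, 100), "")[[1]]
  expect_true(all(m[cbind(match(refbases, c("A", "C", "G", "T")),
                          21:100)] == 1))

  # two overlapping reads disagreeing at one position
  alt_read <- substr(ctg, 21, 100)
  p <- 40L  # contig position 60
  substr(alt_read, p, p) <- setdiff(c("A", "C", "G", "T"),
                                    substr(alt_read, p, p))[1]
  store2 <- rbind(store1,
                  pair_table(seq1 = strrep("A", 36),
                             qual1 = qstr(rep(40, 36)),
                             seq2 = alt_read, qual2 = qstr(rep(40, 80)),
                             id = "r900"))
  al2 <- align_reads(store2, idx, "lineX")
  pl2 <- build_pileups(al2$alignments, contigs)
  col <- pl2$c1[, 60]
  expect_equal(sum(col), 2)
  expect_equal(sort(col[col > 0]), c(1L, 1L), ignore_attr = TRUE)

  # depth conservation: 80 x accepted alignments
  expect_equal(sum(pl2$c1), 80 * al2$report$n_accepted)

  # empty alignment set gives empty pileups
  pl0 <- build_pileups(al2$alignments[0, ], contigs)
  expect_equal(sum(pl0$c1), 0)
})

test_that("low-quality bases are excluded from pileup counts", {
  set.seed(83)
  ctg <- random_dna(200)
  contigs <- ref_contigs(ctg)
  idx <- build_index(contigs, seed_len = 20)
  read <- substr(ctg, 21, 100)
  qual <- qstr(c(2, rep(40, 79)))   # first base below the Q13 floor
  store <- pair_table(seq1 = strrep("A", 36), qual1 = qstr(rep(40, 36)),
                      seq2 = read, qual2 = qual)
  al <- align_reads(store, idx, "lineX")
  pl <- build_pileups(al$alignments, contigs, min_base_qual = 13)
  expect_equal(sum(pl$c1), 79)
  expect_equal(sum(pl$c1[, 21]), 0)

  # a minus-strand read's qualities follow its bases
  storem <- pair_table(seq1 = strrep("A", 36), qual1 = qstr(rep(40, 36)),
                       seq2 = revcomp(read), qual2 = qual)
  alm <- align_reads(storem, idx, "lineX")
  expect_equal(alm$alignments$strand, "-")
  plm <- build_pileups(alm$alignments, contigs, min_base_qual = 13)
  # the low-quality symbol sat on the first base of the reversed read,
  # i.e. contig position 100
  expect_equal(sum(plm$c1[, 100]), 0)
  expect_equal(sum(plm$c1), 79)
})
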