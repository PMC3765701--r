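# Shared settings for the analysis scripts (run 01..05 in order from the
# repository root). Intermediate R objects live under scratch/, final
# tables under results/.

suppressPackageStartupMessages(library(radsnp))

STUDY_SEED <- 20260926L

# study conditions: six inbred lines, ~1 SNP / 143 bp per line against the
# ancestor, Ts/Tv 1.72, PstI digestion, 300-700 bp size selection, 60 read
# pairs per RAD locus, error-free chemistry for the discovery run
study_config <- function(error_rate = 0, snp_rate = 1 / 143,
                         seed = STUDY_SEED) {
  sim_config(genome_length = 200000, n_lines = 6, snp_rate = snp_rate,
             tstv_ratio = 1.72, reads_per_locus = 60,
             error_rate = error_rate, seed = seed)
}

SCRATCH <- "scratch/analysis"
RESULTS <- "results/analysis"
dir.create(SCRATCH, recursive = TRUE, showWarnings = FALSE)
dir.create(RESULTS, recursive = TRUE, showWarnings = FALSE)

write_tsv <- function(df, name) {
  path <- file.path(RESULTS, name)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cat("  wrote", path, "\n")
}
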