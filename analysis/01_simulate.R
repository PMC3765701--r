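# Simulate the pooled six-line PstI RAD-Seq library with known truth.

source("analysis/00_config.R")

cfg <- study_config()
print(cfg)

sim <- simulate_rad_library(cfg, outdir = file.path(SCRATCH, "library"))
print(sim)

cat(sprintf("truth: %d planted SNP records at %d distinct positions, %d RAD loci\n",
            nrow(sim$truth$variants), length(unique(sim$truth$variants$pos)),
            nrow(sim$truth$loci)))
saveRDS(sim, file.path(SCRATCH, "sim.rds"))

write_tsv(data.frame(
  quantity = c("read_pairs", "truth_snp_records", "truth_positions",
               "rad_loci"),
  value = c(nrow(sim$reads), nrow(sim$truth$variants),
            length(unique(sim$truth$variants$pos)), nrow(sim$truth$loci))),
  "01_simulation_counts.tsv")
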