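# Cluster the reference line's reads into RAD loci, assemble each locus's
# 80 bp mates into a contig, and screen against a (synthetic) plastid
# database.

source("analysis/00_config.R")
stores <- readRDS(file.path(SCRATCH, "stores.rds"))
ref_line <- names(stores)[1]

cl <- cluster_loci(stores[[ref_line]], min_depth = 50, max_depth = 750)
cat(sprintf("%s: %d clusters, %d kept (%d below 50x, %d above 750x)\n",
            ref_line, cl$report$n_clusters, cl$report$n_kept,
            cl$report$n_below_min, cl$report$n_above_max))

asm <- assemble_rad_loci(cl$loci, k = 31, coverage_cutoff = 3,
                         min_contig_len = 200)
cat(sprintf("assembled %d contigs (%d retained, %d too short, %d secondary)\n",
            asm$report$n_assembled, asm$report$n_retained,
            asm$report$n_too_short, asm$report$n_secondary))

# synthetic plastid stand-in: high-copy contaminant screening is part of
# the pipeline even though this clean simulation plants no plastid loci
set.seed(STUDY_SEED + 1L)
plastid_synthetic <- paste(sample(c("A", "C", "G", "T"), 20000,
                                  replace = TRUE,
                                  prob = c(.31, .19, .19, .31)),
                           collapse = "")
scr <- plastid_screen(asm$contigs, plastid_synthetic)
cat(sprintf("plastid screen: %d of %d retained contigs flagged\n",
            scr$report$n_flagged, scr$report$n_screened))

st <- assembly_stats(scr$contigs)
print(st)

retained <- scr$contigs[scr$contigs$flag == "retained", ]
write_reference_fasta(retained, file.path(SCRATCH, "reference.fasta"))
saveRDS(scr$contigs, file.path(SCRATCH, "contigs.rds"))

write_tsv(data.frame(
  feature = c("contigs_assembled", "contigs_plastid_removed",
              "contigs_retained", "total_assembly_bp", "min_contig_bp",
              "max_contig_bp", "gc_percent", "n50_bp", "n90_bp"),
  value = c(asm$report$n_assembled + 0, scr$report$n_flagged,
            st$n_contigs, st$total_length, st$min_len, st$max_len,
            round(st$gc_percent, 1), st$n50, st$n90)),
  "03_assembly_stats.tsv")
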