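# Align every line's 80 bp mates to the assembled reference (<= 3
# mismatches, unique placements only), build per-line pileups and call
# bi-allelic SNPs.

source("analysis/00_config.R")
stores <- readRDS(file.path(SCRATCH, "stores.rds"))
contigs <- readRDS(file.path(SCRATCH, "contigs.rds"))
retained <- contigs[contigs$flag == "retained", ]

index <- build_index(retained, seed_len = 20)
aligned <- lapply(names(stores), function(l)
  align_reads(stores[[l]], index, l, max_mismatches = 3))
names(aligned) <- names(stores)

rep <- do.call(rbind, lapply(names(aligned), function(l) {
  r <- aligned[[l]]$report
  data.frame(line_id = l, reads = r$n_reads, accepted = r$n_accepted,
             unmapped = r$n_unmapped, multi = r$n_multi,
             ambiguous = r$n_ambiguous)
}))
print(rep)
write_tsv(rep, "04_alignment_report.tsv")

pileups <- lapply(aligned, function(a)
  build_pileups(a$alignments, retained, min_base_qual = 13))
variants <- call_variants(pileups, retained, min_depth = 4,
                          hom_fraction = 0.90, het_minor_fraction = 0.25)
print(variants)

write_vcf(variants, retained, file.path(SCRATCH, "variants.vcf"))
saveRDS(list(pileups = pileups, variants = variants),
        file.path(SCRATCH, "calls.rds"))
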