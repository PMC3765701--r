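# Apply the marker filter cascade, summarise the panel, and score the run
# against the planted truth.

source("analysis/00_config.R")
contigs <- readRDS(file.path(SCRATCH, "contigs.rds"))
calls <- readRDS(file.path(SCRATCH, "calls.rds"))
retained <- contigs[contigs$flag == "retained", ]
clen <- setNames(nchar(retained$sequence), retained$contig_id)

casc <- filter_cascade(calls$variants, clen, max_missing_lines = 3,
                       flank_len = 50)
print(casc$ledger)
write_tsv(casc$ledger, "05_filter_ledger.tsv")

summ <- snp_summary(calls$variants, n_contigs = nrow(retained))
print(summ)
write_tsv(data.frame(
  feature = c("transitions", "transversions", "tstv",
              "contigs_with_snp", "frac_contigs_with_snp", "panel_snps"),
  value = c(summ$transitions, summ$transversions, round(summ$tstv, 2),
            summ$n_contigs_with_snp,
            round(summ$frac_contigs_with_snp, 3),
            nrow(casc$panel$sites))),
  "05_snp_summary.tsv")

write_vcf(casc$panel, retained, file.path(SCRATCH, "panel.vcf"))
if (nrow(casc$panel$sites) > 0)
  write_panel_fasta(casc$panel, retained,
                    file.path(SCRATCH, "panel_flanks.fasta"))

# full-pipeline truth scoring uses the orchestrated run (identical seed)
run <- run_pipeline(study_config())
ev <- evaluate_against_truth(run)
cat(sprintf(
  "truth scoring: precision %.3f, recall %.3f (%d eligible of %d planted)\n",
  ev$precision, ev$recall, ev$n_eligible, ev$n_truth))
write_tsv(data.frame(
  metric = c("precision", "recall", "n_truth", "n_in_contig",
             "n_eligible", "n_found", "panel_snps"),
  value = c(ev$precision, ev$recall, ev$n_truth, ev$n_in_contig,
            ev$n_eligible, ev$n_found, nrow(run$panel$sites))),
  "05_truth_evaluation.tsv")
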