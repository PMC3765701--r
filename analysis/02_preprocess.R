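# Demultiplex the pooled library by inline barcode and apply the Q20
# tail-quality filter.

source("analysis/00_config.R")
sim <- readRDS(file.path(SCRATCH, "sim.rds"))

dm <- demultiplex(sim$reads, sim$config$barcodes)
cat(sprintf("demultiplexed %d pairs: %d assigned, %d unassigned\n",
            dm$report$n_input, dm$report$n_assigned,
            dm$report$n_unassigned))

filtered <- lapply(dm$stores, quality_filter)
stores <- lapply(filtered, `[[`, "kept")
disc <- vapply(filtered, `[[`, integer(1), "n_discarded")
cat(sprintf("quality filter discarded %d pairs in total\n", sum(disc)))

saveRDS(stores, file.path(SCRATCH, "stores.rds"))
write_tsv(cbind(dm$report$per_line, quality_discarded = unname(disc),
                kept = vapply(stores, nrow, integer(1))),
          "02_demux_report.tsv")
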