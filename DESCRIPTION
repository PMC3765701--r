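Package: radsnp
Title: Paired-End RAD-Seq Simulation, Assembly and SNP Panel Design
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Simulates restriction site associated DNA (RAD) sequencing
    libraries from multi-line inbred plant genomes and re-implements the
    downstream paired-end RAD-Seq discovery pipeline: inline-barcode
    demultiplexing, tail-quality filtering, exact-identity RAD locus
    clustering with coverage gates, per-locus de Bruijn contig assembly,
    contaminant (plastid) screening, seed-and-extend ungapped read
    alignment, per-line pileup genotyping, and the marker filter cascade
    used to select bi-allelic SNPs with clean flanking sequence for
    Infinium-style array design. Every stage is driven by a seeded
    configuration so planted variants can be recovered and scored against
    truth files.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    S4Vectors,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    vcfR
Config/testthat/edition: 3
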