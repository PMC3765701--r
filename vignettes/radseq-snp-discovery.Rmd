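---
title: "Paired-end RAD-Seq SNP discovery: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Paired-end RAD-Seq SNP discovery: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

# The problem

Reduced-representation sequencing makes SNP discovery tractable in large,
repeat-rich plant genomes by sequencing only the neighbourhoods of
restriction-enzyme cut sites. In the paired-end RAD-Seq design implemented
here, genomic DNA from several inbred lines is digested with PstI
(CTGCA/G), ligated to barcoded adapters at the cut site, pooled, randomly
sheared, and size-selected. Each molecule is then sequenced asymmetrically:
a 40 bp read anchored at the restriction site (4 nt inline barcode followed
by the site remnant) and an 80 bp mate starting at the random shear point.
Because all molecules of one locus share the anchored end while their
sheared ends vary, the 80 bp mates tile a several-hundred-bp contig around
each cut site. Assembling those contigs for one line yields a framework
reference; aligning every line's mates to it and genotyping the pileups
yields SNPs; a filter cascade then selects bi-allelic markers with clean
flanking sequence suitable for Infinium-style array design.

`radsnp` implements the whole chain — including the simulator that
generates libraries with known truth — so that every stage, and the
pipeline end to end, can be validated by recovering planted variants.

# The synthetic-data generator

The generator emulates the study conditions of a six-line inbred sunflower
panel:

* **Ancestral genome** — i.i.d. bases at 36.1% GC. (Two GC values are in
  circulation for such assemblies, 36.1 and 36.2; the tabulated assembly
  value 36.1 is used as the default.)
* **Line genomes** — each line receives Binomial(L, 1/143) variant
  positions against the ancestor, substitutions drawn to an expected
  transition/transversion ratio of 1.72 (a transition with probability
  1.72/2.72, else one of the two transversions uniformly).
* **Heterozygosity** — inbred lines are modelled fully homozygous by
  default (`het_rate = 0`). Real panels retain residual heterozygosity
  (about a tenth of genotype calls), so `het_rate` can be raised; a het
  site places the derived allele on haplotype 1 only.
* **Digestion** — cuts at every unmasked CTGCAG occurrence, at offset 5 on
  the top strand. A configurable fraction of sites can be masked,
  emulating 5-methylcytosine blocking, which in real plant genomes biases
  RAD sampling toward hypomethylated, gene-rich DNA.
* **Shearing and size selection** — molecule lengths follow a
  Normal(500, 100) truncated to the 300–700 bp gel window, further
  truncated to the parent fragment; molecules below 300 bp are discarded.
  Only the final gel window is modelled (the intermediate 300–800 bp
  isolation cannot constrain sequenced fragments further).
* **Reads** — PstI leaves a 4 nt 3' overhang, so reads from either flank
  of a cut begin with the same remnant, TGCAG; the simulator anchors each
  locus 4 bp into the overhang and emits read 1 as barcode + remnant +
  sequence, read 2 as the reverse complement of the molecule's last 80 bp.
  The default six 4-nt barcodes have pairwise Hamming distance at least 2.
* **Errors and qualities** — substitutions are applied uniformly per base;
  erroneous bases carry a low phred symbol (2), correct bases a high one
  (40). This two-symbol model captures the essential coupling between
  miscalls and low base quality without modelling cycle-dependent decay.

What the generator deliberately does **not** emulate: PCR duplicates,
indels, structural variants, adapter read-through, repeat families, or
quality decay along the read. Passing tests on this generator therefore
demonstrate the correctness of the pipeline's logic and bookkeeping —
cluster gating, assembly, alignment rules, genotype thresholds, cascade
arithmetic — not robustness to every artefact of real instruments.

# Pipeline stages and their parameters

| Stage | Parameter | Default | Rationale |
|---|---|---|---|
| demultiplex | barcode mismatches | 0 | distance-≥2 barcode sets make exact matching safe |
| quality filter | mean phred over last 5 bp | ≥ 20 | discard decaying tails; a mean of exactly 20 is kept |
| clustering | depth gates | 50–750 | under 50x the mates give only ~10x contig coverage ((80×50)/400); far deeper clusters are suspect high-copy DNA |
| assembly | k; k-mer coverage cutoff; min contig | 31; 3; 200 bp | per-locus graphs are tiny; cutoff 3 removes error k-mers at RAD depths |
| plastid screen | identity over span | ≥ 90% over ≥ 100 bp | quantifies "significant homology"; seeded Smith-Waterman after a shared 15-mer prefilter |
| alignment | mismatches; uniqueness | ≤ 3 per 80 bp (>96% identity); unique contig | multi-contig hits discarded; equal-best same-contig placements discarded as ambiguous |
| pileup | min base quality | phred 13 | the conventional pileup floor; drops error-flagged bases |
| genotyping | depth; hom fraction; het minor fraction | ≥ 4; ≥ 0.90; ≥ 0.25 | deterministic threshold model standing in for likelihood callers |
| cascade | missing lines; flank | < 3 of 6; ≥ 50 bp | array probe design needs clean 50 bp flanks and genotype data in most lines |

Decisions worth recording where the design was genuinely open:

* **Q20 filter scope.** The tail filter is applied to all lines uniformly
  and to both mates, discarding the whole pair when either mate fails
  (downstream clustering needs both mates).
* **Cluster gate.** The operative upper gate is 750x (not the looser
  "greater than 500" sometimes quoted as its rationale); gates act per
  line before any cross-line pooling.
* **Single-end key.** The 36 nt post-barcode sequence, including the
  restriction remnant, is the cluster key — the remnant is genomic
  sequence and participates in identity.
* **One contig per locus.** When several contigs of a locus pass the
  length threshold, the longest is retained (ties: higher mean k-mer
  coverage); the rest are flagged `secondary`.
* **Aligned reads.** Only the 80 bp mates are aligned and genotyped; the
  36 nt single-end reads define loci but are too short for confident
  placement at 3 mismatches.
* **Overhanging reads** are discarded rather than clipped, which keeps
  depth conservation exact (pileup bases = 80 × accepted alignments when
  no base-quality masking applies).
* **Reference line.** The line whose reads build the reference also
  participates in the genotype matrix, so a panel of six lines yields
  6 × sites possible genotypes.
* **Multi-allelic sites** (more than two alleles across lines, reference
  included) are excluded and counted — bead-array assays are bi-allelic.
* **Neighbour interference.** The nearby-polymorphism stage tests each
  flank-passing site against *all* stage-1 survivors within 50 bp (not
  only other finalists), and removes both members of a close pair.
  Low-confidence (stage-1-failing) variants do not interfere.
* **Heterozygous candidates** remain eligible for the final panel; the
  cascade removes nothing on het status.
* **Percentages** in ledger reports are printed to one decimal with
  half-up rounding, matching how such tables are conventionally typeset.

# Numerical and degenerate-input choices

* Coordinates are 0-based half-open everywhere internally; only emitted
  VCF is 1-based.
* Greedy contig extension breaks ties by higher k-mer count, then base
  order (A < C < G < T); a k-mer and its reverse complement are retired
  together, and each contig is reported in canonical (lexicographically
  smaller) orientation. `k` must be odd so no k-mer is its own reverse
  complement.
* Zero restriction sites yield one fragment spanning the genome; an empty
  size-selection window yields an empty library with a warning; a
  transversion-free variant set reports an undefined (NA) Ts/Tv rather
  than infinity.
* Every stage derives its RNG stream from the single configuration seed,
  so identical configurations produce byte-identical FASTQ, VCF and
  truth files.

# Problem sizes used in validation

The packaged checks run on desk-scale simulations chosen to exercise every
gate while completing quickly: a 200 kb ancestral genome (about 44 RAD
loci) with six lines at 60 pairs per locus for the end-to-end
precision/recall and null false-positive runs; 1.43 Mb for density and
Ts/Tv recovery (≥ 10,000 planted variants); 1,000 small random genomes for
digestion-conservation and read round-trip properties; 500 random length
multisets for the N50/N90 oracle comparison. At these scales the planted
per-line density of 1/143 bp makes the pooled six-line SNP landscape dense
enough that the 50 bp neighbour rule removes most candidates — as it does
in real panels — so final-panel precision and recall are evaluated on the
eligible subset: planted SNPs at least 50 bp inside a retained contig,
with no planted neighbour within 50 bp, at most two alleles, and
genotyping depth in at least four of six lines.

# Known limitations

* The assembler, aligner and caller are deterministic threshold methods
  built for clarity and testability; they do not model base-quality
  likelihoods, indels or gapped alignment.
* Exact-identity clustering fragments loci whose single-end read carries a
  sequencing error; at the simulated error rates this only trims cluster
  depth slightly, but at high error rates it would bias locus recovery.
* Contig-to-genome truth mapping relies on exact substring search and is
  meaningful only for error-free simulations.
* The plastid screen's seeded local alignment is quadratic per candidate
  pair and intended for the small contaminant databases typical of
  organelle screening.
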