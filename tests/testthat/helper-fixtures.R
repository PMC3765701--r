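# Shared fixtures: everything is generated in code at test time.

random_dna <- function(n, seed = NULL, gc = 0.5) {
  if (!is.null(seed)) set.seed(seed)
  p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  paste(sample(names(p), n, replace = TRUE, prob = p), collapse = "")
}

# a small-genome config that keeps unit tests fast
tiny_config <- function(...) {
  sim_config(genome_length = 60000, seed = 42, ...)
}

# random genome guaranteed to contain PstI sites at known-ish density
genome_with_sites <- function(n, n_sites, seed) {
  set.seed(seed)
  g <- random_dna(n, gc = 0.4)
  pos <- sort(sample.int(n - 6L, n_sites))
  pos <- pos[c(TRUE, diff(pos) > 10)]   # keep sites apart
  for (p in pos) substr(g, p, p + 5L) <- "CTGCAG"
  g
}

# reads tiling a template at a fixed step, replicated `copies` times
tiling_reads <- function(template, read_len = 80L, step = 40L, copies = 60L) {
  n <- nchar(template)
  starts <- unique(c(seq(1L, n - read_len + 1L, by = step),
                     n - read_len + 1L))
  rep(substring(template, starts, starts + read_len - 1L), copies)
}

# brute-force Nx oracle: largest length L with sum(lengths >= L) covering
# at least frac of the total (independent of the cumulative-scan route)
brute_nx <- function(lengths, frac) {
  total <- sum(as.numeric(lengths))
  for (L in sort(unique(lengths), decreasing = TRUE)) {
    if (sum(as.numeric(lengths[lengths >= L])) >= frac * total) return(L)
  }
  min(lengths)
}

# minimal read-pair table for preprocess tests
pair_table <- function(seq1, qual1, seq2, qual2, id = NULL) {
  n <- length(seq1)
  data.frame(read_id = if (is.null(id)) sprintf("r%03d", seq_len(n)) else id,
             seq1 = seq1, qual1 = qual1, seq2 = seq2, qual2 = qual2,
             stringsAsFactors = FALSE)
}

qstr <- function(phreds) intToUtf8(phreds + 33L)
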