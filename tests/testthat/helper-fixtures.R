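# Shared fixtures, built in code and memoized for the test session.

suppressMessages({
  library(data.table)
  library(Biostrings)
  library(GenomicRanges)
  library(IRanges)
})

.fixture_cache <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, builder(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# tiny deterministic genome for unit tests of digestion/capture
toy_genome <- function() {
  Biostrings::DNAStringSet(c(
    chrA = "AACCGGTTACGTACCGGAACGCGTTCCGGAT",
    chrB = "TTTTACGTCCGGACGTACGTTTTT"))
}

# a larger random genome with a fixed seed, for simulation tests
rand_genome <- function(len = 30000L, gc = 0.45, seed = 42L) {
  withr::with_seed(seed, {
    bases <- c("A", "C", "G", "T")
    p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
    Biostrings::DNAStringSet(c(chr1 = paste(
      sample(bases, len, replace = TRUE, prob = p), collapse = "")))
  })
}

# genome of A's with CCGG planted at given 0-based starts
planted_genome <- function(len, starts0, name = "chr1") {
  v <- rep("A", len)
  for (s0 in starts0) v[(s0 + 1):(s0 + 4)] <- c("C", "C", "G", "G")
  Biostrings::DNAStringSet(stats::setNames(paste(v, collapse = ""), name))
}

# small reference system: 4 cell types, 30 markers each, ~240 kb genome.
# Shared by marker-recovery, deconvolution and classifier tests.
small_system <- function() {
  memo("small_system", function() {
    suppressWarnings(simulate_reference_system(
      cell_types = c("Bcell", "Tcell", "Monocyte", "Neutrophil"),
      markers_per_type = 30L,
      chrom_lengths = c(chr1 = 120000L, chr2 = 120000L),
      mix_pool_size = 6e4, ref_pool_size = 4e4, seed = 11L))
  })
}

# full-scale system at the study conditions of the titration experiments:
# 7 cell types, 250 markers per type, 1.8 Mb genome, 3e5/2e5 fragment pools.
big_system <- function() {
  memo("big_system", function() suppressWarnings(simulate_reference_system(seed = 101L)))
}

# the seven-level titration series shared by the RMSE and detection-floor tests
titration_series <- function() {
  memo("titration_t1", function()
    run_titration(big_system(), "LungAlveolar",
                  c(0, 0.003, 0.01, 0.03, 0.10, 0.40, 1),
                  n_fragments = 2e5, seed = 202L))
}
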