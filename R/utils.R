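# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed (restoring the caller's RNG state),
# or directly when seed is NULL.
with_seed_ <- function(seed, code) {
  if (is.null(seed)) code else withr::with_seed(as.integer(seed), code)
}

clamp01 <- function(x) pmin(1, pmax(0, x))

`%||%` <- function(a, b) if (is.null(a)) b else a

# GRanges of the C base of each CpG (width 1, 1-based).
cpg_granges <- function(cpgs) {
  GenomicRanges::GRanges(cpgs$chrom, IRanges::IRanges(cpgs$pos + 1L, width = 1L))
}

stop_if_not_pat <- function(pat) {
  need <- c("chrom", "first_idx", "pattern", "count")
  if (!is.data.frame(pat) || !all(need %in% names(pat)))
    stop("expected a PAT table with columns: ", paste(need, collapse = ", "))
  invisible(TRUE)
}
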