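test_that("capture logic keeps terminal pieces for one-cut and internal for two-cut", {
  g <- planted_genome(100L, c(20L, 40L, 60L))   # cuts at 21, 41, 61
  s <- scan_motif_sites(g, "CCGG")
  frag <- data.table(chrom = "chr1", start = 0L, end = 100L,
                     cell_type = NA_character_, frag_id = 1L)
  flex <- apply_capture(frag, s, "flexseq")
  expect_equal(flex$start, c(0L, 61L))
  expect_equal(flex$end, c(21L, 100L))
  expect_setequal(flex$cut_end, c("right", "left"))

  rr <- apply_capture(frag, s, "rrbs")
  expect_equal(rr$start, c(21L, 41L))
  expect_equal(rr$end, c(41L, 61L))
  expect_true(all(rr$cut_end == "both"))

  wg <- apply_capture(frag, s, "wgbs")
  expect_equal(wg[, .(chrom, start, end)], frag[, .(chrom, start, end)])

  # uncut fragment (A+A adapters): excluded by the one-cut protocol
  far <- data.table(chrom = "chr1", start = 70L, end = 95L,
                    cell_type = NA_character_, frag_id = 1L)
  expect_equal(nrow(apply_capture(far, s, "flexseq")), 0L)

  # cut exactly on the boundary is not internal
  onb <- data.table(chrom = "chr1", start = 21L, end = 41L,
                    cell_type = NA_character_, frag_id = 1L)
  expect_equal(nrow(apply_capture(onb, s, "flexseq")), 0L)
})

test_that("one-cut and two-cut pieces exactly partition every cut fragment", {
  g <- rand_genome(30000L, seed = 5L)
  s <- scan_motif_sites(g, "CCGG")
  frags <- fragment_genome(g, "FFPE", 300L, seed = 8L)
  flex <- apply_capture(frags, s, "flexseq")
  rr <- apply_capture(frags, s, "rrbs")
  pieces <- rbind(flex, rr)
  cut_ids <- unique(flex$frag_id)
  for (id in cut_ids) {
    p <- pieces[frag_id == id][order(start)]
    f <- frags[frag_id == id]
    expect_equal(p$start[1], f$start)
    expect_equal(p$end[nrow(p)], f$end)
    if (nrow(p) > 1L) expect_equal(p$start[-1], p$end[-nrow(p)])
  }
  # two-cut pieces only occur in fragments that the one-cut protocol captured
  expect_true(all(rr$frag_id %in% cut_ids))
})

test_that("fragment generation respects the length model, bounds, and seed", {
  g <- rand_genome(30000L)
  expect_equal(nrow(fragment_genome(g, "cfDNA", 0L)), 0L)
  a <- fragment_genome(g, "cfDNA", 500L, seed = 3L)
  b <- fragment_genome(g, "cfDNA", 500L, seed = 3L)
  expect_identical(a, b)
  big <- fragment_genome(g, "cfDNA", 10000L, seed = 4L)
  len <- big$end - big$start
  expect_true(all(len >= 30L))
  expect_lt(abs(mean(len) - 170), 3 * 20 / sqrt(10000))
  expect_error(fragment_genome(Biostrings::DNAStringSet(c(chr1 = "ACGT")),
                               "cfDNA", 10L),
               "shorter than the minimum")
})

test_that("read simulation honors the methylome and conversion extremes", {
  g <- rand_genome(20000L, seed = 12L)
  s <- scan_motif_sites(g, "CCGG")
  cpgs <- cpg_index_map(g)
  frags <- fragment_genome(g, "cfDNA", 400L, seed = 13L)
  pieces <- apply_capture(frags, s, "flexseq")
  conv0 <- conversion_model(0, 0)
  r1 <- simulate_reads(pieces, g, cpgs, rep(1, nrow(cpgs)), conv = conv0, seed = 1L)
  expect_true(all(grepl("^C*$", r1$pattern)))
  r0 <- simulate_reads(pieces, g, cpgs, rep(0, nrow(cpgs)), conv = conv0, seed = 1L)
  expect_true(all(grepl("^T*$", r0$pattern)))
  expect_error(simulate_reads(pieces, g, cpgs, rep(1.5, nrow(cpgs))), "0, 1")
  # cut-anchored reads are on-target by construction
  expect_equal(on_target_rate(r1[n_cpg > 0]), 1.0)
  r_err <- simulate_reads(pieces, g, cpgs, rep(0.5, nrow(cpgs)),
                          conv = conversion_model(0.01, 0.01), seed = 2L)
  expect_equal(on_target_rate(r_err), 1.0)
  # two-cut pieces are cut-anchored too
  rrp <- apply_capture(frags, s, "rrbs")
  rr_reads <- simulate_reads(rrp, g, cpgs, rep(1, nrow(cpgs)), conv = conv0,
                             seed = 3L)
  expect_equal(on_target_rate(rr_reads), 1.0)
})

test_that("free-end reads are on-target at the genomic C/TGG prefix frequency", {
  g <- rand_genome(30000L, seed = 21L)
  cpgs <- cpg_index_map(g)
  frags <- fragment_genome(g, "cfDNA", 6000L, seed = 22L)
  wg <- apply_capture(frags, scan_motif_sites(g, "CCGG"), "wgbs")
  reads <- simulate_reads(wg, g, cpgs, rep(0.5, nrow(cpgs)),
                          conv = conversion_model(0, 0), seed = 23L)
  rate <- on_target_rate(reads)
  # exhaustive prefix count: a converted read starts C/TGG iff the genomic
  # trinucleotide at the fragment start is CGG (either call) or TGG
  s <- as.character(g[[1]])
  L <- nchar(s)
  tri <- substring(s, 1:(L - 2), 3:L)
  expected <- mean(tri %in% c("CGG", "TGG"))
  se <- sqrt(expected * (1 - expected) / nrow(reads))
  expect_lt(abs(rate - expected), 4 * se + 0.005)
  # reads with no C/TGG anchor never count
  fake <- data.table(prefix = c("AAA", "AAT"))
  expect_equal(on_target_rate(fake), 0)
})

test_that("non-conversion filter removes reads above the unconverted-C threshold", {
  reads <- data.table(chrom = "chr1", n_unconv = c(0L, 3L, 4L, 5L))
  out <- filter_non_conversion(reads, max_unconverted = 3L)
  expect_equal(out$n_unconv, c(0L, 3L))
  expect_equal(attr(out, "filter_rate"), 0.5)
  empty <- filter_non_conversion(reads[0])
  expect_equal(nrow(empty), 0L)
})

test_that("per-CpG betas converge to the methylome under error-free conversion", {
  g <- rand_genome(5000L, seed = 31L)
  cpgs <- cpg_index_map(g)
  meth <- withr::with_seed(32L, runif(nrow(cpgs)))
  frags <- fragment_genome(g, "sheared", 4000L, seed = 33L)
  wg <- apply_capture(frags, scan_motif_sites(g, "CCGG"), "wgbs")
  reads <- simulate_reads(wg, g, cpgs, meth, read_len = 500L,
                          conv = conversion_model(0, 0), seed = 34L)
  beta <- pat_to_beta(reads_to_pat(reads, cpgs, min_cpg = 1L))
  hi <- beta[total >= 100]
  expect_gt(nrow(hi), 50L)
  dev <- abs(hi$beta - meth[hi$idx])
  expect_lt(mean(dev), 0.05)
  expect_lt(max(dev / (sqrt(meth[hi$idx] * (1 - meth[hi$idx]) / hi$total) + 1e-3)),
            6)
})

test_that("enrichment comparison is 1 for identical sets and favors capture on-target", {
  g <- rand_genome(30000L, seed = 41L)
  s <- scan_motif_sites(g, "CCGG")
  cpgs <- cpg_index_map(g)
  targets <- flank_regions(s, 100)
  meth <- rep(0.5, nrow(cpgs))
  frags <- fragment_genome(g, "cfDNA", 5000L, seed = 42L)
  flex <- simulate_reads(apply_capture(frags, s, "flexseq"), g, cpgs, meth,
                         seed = 43L)
  wg <- simulate_reads(apply_capture(frags, s, "wgbs"), g, cpgs, meth,
                       seed = 44L)
  budget <- 1e5
  same <- enrichment_stats(flex, flex, targets, cpgs, min_cov = 5,
                           budget_bases = budget, seed = 45L)
  expect_equal(same$fold_requirement, 1)
  es <- enrichment_stats(flex, wg, targets, cpgs, min_cov = 5,
                         budget_bases = budget, seed = 46L)
  expect_gt(es$cpgs_ge_cov[["A"]], es$cpgs_ge_cov[["B"]])
  expect_gt(es$fold_requirement, 1)
  expect_error(enrichment_stats(flex, wg, targets, cpgs,
                                budget_bases = 1e9),
               "budget exceeds")
})
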