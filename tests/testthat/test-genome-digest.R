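test_that("motif scan finds exact occurrences and handles palindromes", {
  g <- Biostrings::DNAStringSet(c(chr1 = "ACCGGT"))
  s <- scan_motif_sites(g, "CCGG")
  expect_equal(start(s$sites), 2L)             # 0-based start 1
  expect_equal(start(s$sites) - 1L + s$cut_offset, 2L)  # cut coordinate

  empty <- scan_motif_sites(Biostrings::DNAStringSet(c(chr1 = "AAAATTTT")), "CCGG")
  expect_length(empty$sites, 0L)

  # CCGG is its own reverse complement: scanning the reverse-complemented
  # genome gives the mirrored site set
  g2 <- rand_genome(5000L, seed = 7L)
  fwd <- scan_motif_sites(g2, "CCGG")
  rc <- Biostrings::reverseComplement(g2)
  names(rc) <- names(g2)
  rev <- scan_motif_sites(rc, "CCGG")
  L <- Biostrings::width(g2)[1]
  expect_setequal(start(fwd$sites), L - (start(rev$sites) + 3L) + 1L)

  bad <- Biostrings::DNAStringSet(c(chr1 = "ACGTRYACGT"))
  expect_error(scan_motif_sites(bad, "CCGG"), "non-ACGTN")
})

test_that("motif scan agrees with a naive substring oracle on random genomes", {
  for (seed in 1:100) {
    g <- rand_genome(10000L, seed = seed)
    s <- as.character(g[[1]])
    L <- nchar(s)
    naive <- which(substring(s, 1:(L - 3), 4:L) == "CCGG")
    expect_equal(start(scan_motif_sites(g, "CCGG")$sites), naive)
  }
})

test_that("flank regions expand, clip, and merge like bedtools slop", {
  g <- planted_genome(20L, 1L)
  s <- scan_motif_sites(g, "CCGG")
  f <- flank_regions(s, 50)
  expect_equal(c(start(f), end(f)), c(1L, 20L))   # clipped to [0, 20)

  g2 <- planted_genome(400L, c(100L, 160L))
  s2 <- scan_motif_sites(g2, "CCGG")
  f2 <- flank_regions(s2, 50)
  expect_equal(length(f2), 1L)
  expect_equal(c(start(f2), end(f2)), c(51L, 214L))  # 0-based [50, 214)

  f0 <- flank_regions(s2, 0)
  expect_equal(start(f0), start(s2$sites))
  expect_equal(width(f0), c(4L, 4L))
})

test_that("flank regions are monotone in b", {
  g <- rand_genome(20000L, seed = 3L)
  s <- scan_motif_sites(g, "CCGG")
  f1 <- flank_regions(s, 20)
  f2 <- flank_regions(s, 80)
  expect_equal(sum(width(GenomicRanges::setdiff(f1, f2))), 0L)
  st <- coverage_stats(f1, cpg_index_map(g), genome_len = 20000)
  st2 <- coverage_stats(f2, cpg_index_map(g), genome_len = 20000)
  expect_gte(st2$genome_fraction, st$genome_fraction)
})

test_that("rrbs regions merge within d and drop short regions", {
  g <- planted_genome(200L, c(10L, 60L))
  s <- scan_motif_sites(g, "CCGG")
  r <- rrbs_regions(s, d = 50)                    # gap 46 <= 50
  expect_equal(c(start(r), end(r), width(r)), c(11L, 64L, 54L))

  iso <- rrbs_regions(scan_motif_sites(planted_genome(100L, 40L), "CCGG"), d = 50)
  expect_length(iso, 0L)                          # single motif: 4 bp < 30

  adj <- rrbs_regions(scan_motif_sites(planted_genome(100L, c(10L, 14L)), "CCGG"),
                      d = 0)
  expect_length(adj, 0L)                          # merged 8 bp < 30
  adj2 <- rrbs_regions(scan_motif_sites(planted_genome(100L, c(10L, 14L)), "CCGG"),
                       d = 0, min_len = 0)
  expect_equal(width(adj2), 8L)
})

test_that("two-cut regions are a subset of one-cut flanks at equal distance", {
  g <- rand_genome(20000L, seed = 9L)
  s <- scan_motif_sites(g, "CCGG")
  for (d in c(50, 150)) {
    rr <- rrbs_regions(s, d = d, min_len = 0)
    fl <- flank_regions(s, b = d)
    expect_equal(sum(width(GenomicRanges::setdiff(rr, fl))), 0L)
  }
  tc <- theoretical_coverage(s, cpg_index_map(g), fragment_len = 100,
                             genome_len = 20000)
  expect_gte(tc$one_cut$genome_fraction, tc$two_cut$genome_fraction)
})

test_that("coverage statistics count each CpG once and handle degenerate input", {
  g <- Biostrings::DNAStringSet(c(chr1 = "AACGTT"))
  cpgs <- cpg_index_map(g)
  expect_equal(cpgs$pos, 2L)
  region <- GenomicRanges::GRanges("chr1", IRanges::IRanges(3, 4))  # 0-based [2,4)
  st <- coverage_stats(region, cpgs, genome_len = 6)
  expect_equal(st$n_cpgs_in_regions, 1L)

  whole <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 6))
  st2 <- coverage_stats(whole, cpgs, genome_len = 6)
  expect_equal(st2$frac_of_all_cpgs, 1)
  expect_equal(st2$genome_fraction, 1)

  # markers holding CpGs but disjoint from the regions: coverage 0
  g2 <- Biostrings::DNAStringSet(c(chr1 = "AACGTTACGT"))
  cpgs2 <- cpg_index_map(g2)
  far <- GenomicRanges::GRanges("chr1", IRanges::IRanges(8, 9))
  st3 <- coverage_stats(region, cpgs2, markers = far, genome_len = 10)
  expect_equal(st3$frac_marker_cpgs_covered, 0)

  none <- cpg_index_map(Biostrings::DNAStringSet(c(chr1 = "AATTAA")))
  st4 <- coverage_stats(region, none, genome_len = 6)
  expect_true(is.na(st4$frac_of_all_cpgs))
})

test_that("context annotation applies island distances and promoter-first precedence", {
  # CpGs at 0-based 100 (in island), 2600 (shore: 500 bp), 5000 (shelf: 2.9 kb),
  # 9000 (open sea)
  v <- rep("A", 10000)
  for (p in c(100, 2600, 5000, 9000)) v[(p + 1):(p + 2)] <- c("C", "G")
  g <- Biostrings::DNAStringSet(c(chr1 = paste(v, collapse = "")))
  cpgs <- cpg_index_map(g)
  islands <- GenomicRanges::GRanges("chr1", IRanges::IRanges(51, 2100))
  promoter <- GenomicRanges::GRanges("chr1", IRanges::IRanges(1, 3000))
  enhancer <- GenomicRanges::GRanges("chr1", IRanges::IRanges(2000, 6000))
  ann <- annotate_contexts(cpgs, islands,
                           list(promoter = promoter, enhancer = enhancer))
  expect_equal(ann$cpg_context, c("island", "shore", "shelf", "open_sea"))
  # CpG 2600 overlaps promoter and enhancer: promoter wins
  expect_equal(ann$functional_context,
               c("promoter", "promoter", "enhancer", "intergenic"))
  # each CpG in exactly one functional category
  expect_equal(sum(table(ann$functional_context)), nrow(cpgs))
})
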