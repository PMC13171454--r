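# Constructed beta tracks over a fake CpG map: two groups, a planted
# hypomethylated stretch in one.
fake_cpgs <- function(n, spacing = 20L) {
  data.table(chrom = "chr1", pos = seq(0L, by = spacing, length.out = n),
             idx = seq_len(n))
}

flat_track <- function(n, beta, cov = 30L) {
  data.table(idx = seq_len(n), meth = round(beta * cov), total = cov,
             beta = beta)
}

test_that("segmentation splits at methylation change points and respects max_bp", {
  n <- 60L
  cpgs <- fake_cpgs(n)
  # group A drops from 0.9 to 0.1 at CpG 31
  a <- flat_track(n, 0.9)
  a[idx >= 31L, `:=`(meth = 3L, beta = 0.1)]
  b <- flat_track(n, 0.9)
  blocks <- segment_blocks(list(a, a, b, b), c("A", "A", "B", "B"), cpgs,
                           len_range = NULL, max_bp = 10000L)
  expect_true(31L %in% blocks$idx_start)         # boundary right before the step

  # uniform methylomes: blocks bounded only by max_bp (span <= max_bp)
  u <- segment_blocks(list(flat_track(n, 0.5)), "A", cpgs, max_bp = 300L,
                      len_range = NULL)
  expect_true(all(u$end - u$start <= 300L))
  expect_gt(nrow(u), 1L)

  # fewer CpGs than min_cpg: nothing survives
  tiny <- fake_cpgs(2L)
  expect_equal(nrow(segment_blocks(list(flat_track(2L, 0.5)), "A", tiny,
                                   min_cpg = 3L)), 0L)
})

test_that("block averages pool counts and flag zero coverage as undefined", {
  blocks <- data.table(block_id = 1:2, idx_start = c(1L, 3L), idx_end = c(2L, 4L))
  track <- data.table(idx = 1:2, meth = c(3, 0), total = c(3, 3))
  ab <- block_average_beta(blocks, track, n_cpg = 4L)
  expect_equal(ab$beta[1], 0.5)                   # (3+0)/(3+3)
  expect_true(is.na(ab$beta[2]))                  # no coverage
  full <- block_average_beta(blocks[1], data.table(idx = 1:2, meth = c(3, 3),
                                                   total = c(3, 3)), 4L)
  expect_equal(full$beta, 1)
})

test_that("planted markers are recovered and a shared-methylome null yields none", {
  sys <- small_system()
  truth <- sys$methylomes$truth
  found <- sys$markers
  # recovery: a top-k marker of the right type overlaps each planted block
  hit <- vapply(seq_len(nrow(truth)), function(i) {
    f <- found[type == truth$type[i]]
    any(f$idx_start <= truth$idx_end[i] & f$idx_end >= truth$idx_start[i])
  }, logical(1))
  expect_gte(mean(hit), 0.95)
  expect_true(all(found$direction == "hypo"))

  # filter audit: every returned marker satisfies the printed thresholds
  expect_true(all(found$delta >= 0.3))
  expect_true(all(found$coverage >= 10))
  expect_true(all(found$p_value < 0.05))
  expect_true(all(found$n_cpgs >= 4L))
  expect_true(all(found$end - found$start >= 10 & found$end - found$start <= 2000))
  expect_true(all(found$mean_target < 0.33 & found$mean_background >= 0.66))

  # null: all groups share one methylome -> no markers at any group size
  null_m <- sys$methylomes
  null_m$M[] <- 0.95
  null_refs <- make_reference_betas(null_m, seed = 77L)
  null_blocks <- segment_blocks(null_refs$betas, null_refs$groups,
                                sys$genome$cpgs)
  null_found <- find_markers(null_blocks, null_refs$betas, null_refs$groups,
                             sys$genome$cpgs)
  expect_equal(nrow(null_found), 0L)
})

test_that("raising delta_means never adds markers", {
  sys <- small_system()
  loose <- sys$markers
  strict <- find_markers(sys$blocks, sys$refs$betas, sys$refs$groups,
                         sys$genome$cpgs, delta_means = 0.6, top_k = 30L)
  expect_lte(nrow(strict), nrow(loose))
  key <- function(m) paste(m$type, m$idx_start, m$idx_end)
  expect_true(all(key(strict) %in% key(loose)))
})

test_that("DMR calling is symmetric-null and enforces the 1500 bp length cap", {
  n <- 200L
  cpgs <- fake_cpgs(n, spacing = 15L)
  base <- flat_track(n, 0.8)
  mk <- function(track) lapply(1:3, function(i) copy(track))
  # identical groups: no DMRs
  blocks <- segment_blocks(c(mk(base), mk(base)),
                           rep(c("case", "ctrl"), each = 3), cpgs,
                           len_range = NULL)
  none <- find_dmrs(blocks, c(mk(base), mk(base)),
                    rep(c("case", "ctrl"), each = 3), cpgs,
                    case_group = "case")
  expect_equal(nrow(none), 0L)
  # planted promoter-sized DMR: case hypomethylated over CpGs 50..70
  dm <- copy(base)
  dm[idx %in% 50:70, `:=`(meth = round(0.1 * 30), beta = 0.1)]
  betas <- c(mk(dm), mk(base))
  groups <- rep(c("case", "ctrl"), each = 3)
  blocks2 <- segment_blocks(betas, groups, cpgs, len_range = NULL)
  dmr <- find_dmrs(blocks2, betas, groups, cpgs, case_group = "case")
  expect_gte(nrow(dmr), 1L)
  expect_true(any(dmr$idx_start <= 70L & dmr$idx_end >= 50L))
  expect_equal(dmr$direction[1], "hypo")
  # a 1600 bp block is excluded by the DMR length filter even if it differs
  wide <- data.table(block_id = 1L, chrom = "chr1", start = 0L, end = 1600L,
                     idx_start = 1L, idx_end = 100L, n_cpgs = 100L)
  dm2 <- flat_track(n, 0.1)
  out <- find_dmrs(wide, c(mk(dm2), mk(base)), groups, cpgs,
                   case_group = "case")
  expect_equal(nrow(out), 0L)
})
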