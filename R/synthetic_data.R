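# Synthetic genomes, cell-type methylomes with planted markers, fragment
# pools, and cohorts with known truth.

#' Specification for a synthetic genome
#'
#' Describes a genome of i.i.d. background sequence with CpG islands placed
#' on an evenly spaced, jittered grid. Inside islands, extra CG dinucleotides
#' and CCGG motifs are planted at elevated rates to emulate the CpG/CCGG
#' clustering of real islands; background CCGG motifs are planted genome-wide
#' at `ccgg_rate` (spontaneous motifs arising from the i.i.d. background add
#' a further ~(gc/2)^4 per bp to both strata).
#'
#' @param chrom_lengths Named integer vector of chromosome lengths.
#' @param gc GC fraction of the background sequence.
#' @param n_islands Total number of islands across the genome.
#' @param island_len Island length in bp.
#' @param island_cpg_rate Planted CpGs per bp inside islands (default 1/8).
#' @param ccgg_rate Background planted CCGG motifs per bp (default 1/300).
#' @param island_ccgg_factor Island CCGG rate as a multiple of the background
#'   rate (default 5).
#' @param seed Integer seed; the genome is byte-identical under a fixed seed.
#' @return List of class `"fc_genome_spec"`.
#' @export
synthetic_genome_spec <- function(chrom_lengths = c(chr1 = 450000L, chr2 = 450000L,
                                                    chr3 = 450000L, chr4 = 450000L),
                                  gc = 0.4, n_islands = 1850L, island_len = 160L,
                                  island_cpg_rate = 1 / 8, ccgg_rate = 1 / 300,
                                  island_ccgg_factor = 5, seed = 1L) {
  if (is.null(names(chrom_lengths)))
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  if (ccgg_rate * island_ccgg_factor > 1 / 4)
    stop("infeasible motif density: expected motifs exceed length / 4")
  structure(list(chrom_lengths = as.integer(chrom_lengths),
                 chrom_names = names(chrom_lengths), gc = gc,
                 n_islands = as.integer(n_islands),
                 island_len = as.integer(island_len),
                 island_cpg_rate = island_cpg_rate, ccgg_rate = ccgg_rate,
                 island_ccgg_factor = island_ccgg_factor,
                 seed = as.integer(seed)),
            class = "fc_genome_spec")
}

#' Generate a synthetic genome with CpG islands
#'
#' Builds the sequence described by a [synthetic_genome_spec()], scans it for
#' CpGs and CCGG motifs, and returns everything downstream stages need.
#'
#' @param spec A `fc_genome_spec`.
#' @return List of class `"fc_genome"`: `seqs` ([Biostrings::DNAStringSet]),
#'   `cpgs` (CpG map), `islands` ([GenomicRanges::GRanges]), `sites`
#'   (`fc_sites` for CCGG), and `spec`.
#' @export
make_genome <- function(spec) {
  stopifnot(inherits(spec, "fc_genome_spec"))
  bases <- c("A", "C", "G", "T")
  pb <- c((1 - spec$gc) / 2, spec$gc / 2, spec$gc / 2, (1 - spec$gc) / 2)
  n_chrom <- length(spec$chrom_lengths)
  isl_per_chrom <- diff(round(seq(0, spec$n_islands, length.out = n_chrom + 1)))
  seqs <- character(n_chrom)
  isl_list <- vector("list", n_chrom)
  with_seed_(spec$seed, {
    for (ci in seq_len(n_chrom)) {
      L <- spec$chrom_lengths[ci]
      v <- sample(bases, L, replace = TRUE, prob = pb)
      ni <- isl_per_chrom[ci]
      if (ni > 0L) {
        slot <- L %/% ni
        if (slot <= spec$island_len)
          stop("islands do not fit: increase chromosome length or reduce islands")
        jit <- floor(runif(ni) * (slot - spec$island_len))
        ist <- (seq_len(ni) - 1L) * slot + as.integer(jit)  # 0-based starts
        for (s0 in ist) {
          # plant CpGs on a 2-bp grid inside the island
          grid <- seq(0L, spec$island_len - 2L, by = 2L)
          ncg <- min(length(grid), round(spec$island_len * spec$island_cpg_rate))
          at <- s0 + sort(sample(grid, ncg))
          v[at + 1L] <- "C"
          v[at + 2L] <- "G"
          # plant extra CCGG motifs
          nmot <- rpois(1L, spec$island_len * spec$ccgg_rate *
                          (spec$island_ccgg_factor - 1))
          if (nmot > 0L) {
            mp <- sort(sample.int(spec$island_len - 4L, min(nmot, spec$island_len %/% 5L)))
            mp <- mp[c(TRUE, diff(mp) >= 4L)]
            for (m0 in s0 + mp) v[(m0 + 1L):(m0 + 4L)] <- c("C", "C", "G", "G")
          }
        }
        isl_list[[ci]] <- data.table(chrom = spec$chrom_names[ci],
                                     start = ist, end = ist + spec$island_len)
      }
      # background CCGG motifs genome-wide
      nbg <- rpois(1L, L * spec$ccgg_rate)
      if (nbg > 0L) {
        mp <- sort(sample.int(L - 4L, nbg))
        mp <- mp[c(TRUE, diff(mp) >= 4L)]
        for (m0 in mp) v[(m0 + 1L):(m0 + 4L)] <- c("C", "C", "G", "G")
      }
      seqs[ci] <- paste(v, collapse = "")
    }
  })
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- spec$chrom_names
  isl <- rbindlist(isl_list[!vapply(isl_list, is.null, logical(1))])
  islands <- GenomicRanges::GRanges(
    isl$chrom, IRanges::IRanges(isl$start + 1L, isl$end),
    seqlengths = stats::setNames(spec$chrom_lengths, spec$chrom_names))
  structure(list(seqs = genome, cpgs = cpg_index_map(genome), islands = islands,
                 sites = scan_motif_sites(genome, "CCGG"), spec = spec),
            class = "fc_genome")
}

#' @export
print.fc_genome <- function(x, ...) {
  cat(sprintf("<fc_genome> %d chromosome(s), %s bp, %d CpGs, %d CCGG sites, %d islands\n",
              length(x$seqs), format(sum(Biostrings::width(x$seqs)), big.mark = ","),
              nrow(x$cpgs), length(x$sites$sites), length(x$islands)))
  invisible(x)
}

#' Specification for synthetic cell-type methylomes
#'
#' @param cell_types Character vector of cell-type labels.
#' @param markers_per_type Planted marker blocks per cell type.
#' @param marker_beta Methylation probability of a marker block in its target
#'   type (default 0.05, a hypomethylated-marker design).
#' @param background_beta Methylation probability everywhere else (default
#'   0.95).
#' @param min_marker_cpgs Minimum CpGs an island must contain to host a
#'   marker (default 5).
#' @param sample_noise_sd Per-sample beta noise used by
#'   [make_reference_betas()] (default 0.04).
#' @param seed Integer seed for marker placement.
#' @return List of class `"fc_methylome_spec"`.
#' @export
synthetic_methylome_spec <- function(cell_types, markers_per_type = 250L,
                                     marker_beta = 0.05, background_beta = 0.95,
                                     min_marker_cpgs = 5L, sample_noise_sd = 0.04,
                                     seed = 1L) {
  structure(list(cell_types = cell_types,
                 markers_per_type = as.integer(markers_per_type),
                 marker_beta = marker_beta, background_beta = background_beta,
                 min_marker_cpgs = as.integer(min_marker_cpgs),
                 sample_noise_sd = sample_noise_sd, seed = as.integer(seed)),
            class = "fc_methylome_spec")
}

#' Plant cell-type-specific marker blocks into island methylomes
#'
#' Each marker occupies the CpG span of one island and is set to
#' `marker_beta` in exactly one cell type (direction `hypo` under the default
#' beta configuration); all other positions carry `background_beta`. By
#' construction every planted marker satisfies the 0.66/0.33 categorical
#' marker criterion and has delta near
#' `background_beta - marker_beta`.
#'
#' @param spec A `fc_methylome_spec`.
#' @param genome A `fc_genome` from [make_genome()].
#' @return List of class `"fc_methylomes"`: `M` (CpG x cell-type probability
#'   matrix) and `truth` (marker truth table with coordinates, CpG spans,
#'   `type`, `direction`).
#' @export
make_methylomes <- function(spec, genome) {
  stopifnot(inherits(spec, "fc_methylome_spec"), inherits(genome, "fc_genome"))
  cpgs <- genome$cpgs
  gr <- cpg_granges(cpgs)
  ov <- GenomicRanges::findOverlaps(gr, genome$islands)
  tab <- data.table(idx = cpgs$idx[S4Vectors::queryHits(ov)],
                    island_id = S4Vectors::subjectHits(ov))
  isl <- tab[, .(idx_start = min(idx), idx_end = max(idx), n_cpgs = .N),
             by = island_id]
  isl <- isl[n_cpgs >= spec$min_marker_cpgs]
  need <- length(spec$cell_types) * spec$markers_per_type
  if (nrow(isl) < need)
    stop("not enough eligible islands (", nrow(isl), ") to host ", need,
         " markers")
  M <- matrix(spec$background_beta, nrow(cpgs), length(spec$cell_types),
              dimnames = list(NULL, spec$cell_types))
  truth <- with_seed_(spec$seed, {
    pick <- isl[sample.int(nrow(isl), need)]
    pick[, type := rep(spec$cell_types, each = spec$markers_per_type)]
    pick
  })
  for (i in seq_len(nrow(truth)))
    M[truth$idx_start[i]:truth$idx_end[i], truth$type[i]] <- spec$marker_beta
  direction <- if (spec$marker_beta < spec$background_beta) "hypo" else "hyper"
  truth[, direction := direction]
  truth <- merge(truth, cpgs[, .(idx, chrom, pos)],
                 by.x = "idx_start", by.y = "idx")
  truth[, start := pos][, pos := NULL]
  truth <- merge(truth, cpgs[, .(idx, pos)], by.x = "idx_end", by.y = "idx")
  truth[, end := pos + 2L][, pos := NULL]
  setorder(truth, idx_start)
  truth[, marker_id := seq_len(.N)]
  setcolorder(truth, c("marker_id", "chrom", "start", "end", "idx_start",
                       "idx_end", "n_cpgs", "type", "direction"))
  structure(list(M = M, truth = truth[], spec = spec), class = "fc_methylomes")
}

#' Simulate per-sample reference beta tracks
#'
#' Emulates sequencing `n_per_type` purified reference samples per cell type:
#' per CpG the coverage is Poisson(`mean_coverage`) and methylated calls are
#' binomial around the cell type's methylome probability jittered by
#' `noise_sd` (truncated to \[0, 1\]).
#'
#' @param methylomes A `fc_methylomes`.
#' @param n_per_type Samples per cell type (default 3).
#' @param mean_coverage Mean per-CpG coverage (default 30).
#' @param noise_sd Per-sample beta noise; defaults to the methylome spec's
#'   `sample_noise_sd`.
#' @param seed Integer seed.
#' @return List with `betas` (list of beta tracks), `groups` (cell type per
#'   sample), `sample_ids`.
#' @export
make_reference_betas <- function(methylomes, n_per_type = 3L, mean_coverage = 30,
                                 noise_sd = NULL, seed = 1L) {
  stopifnot(inherits(methylomes, "fc_methylomes"))
  noise_sd <- noise_sd %||% methylomes$spec$sample_noise_sd
  types <- colnames(methylomes$M)
  n_cpg <- nrow(methylomes$M)
  with_seed_(seed, {
    betas <- list()
    groups <- character(0)
    ids <- character(0)
    for (ty in types) {
      for (r in seq_len(n_per_type)) {
        p <- clamp01(methylomes$M[, ty] + rnorm(n_cpg, 0, noise_sd))
        cov <- rpois(n_cpg, mean_coverage)
        m <- rbinom(n_cpg, cov, p)
        keep <- cov > 0L
        betas[[length(betas) + 1L]] <-
          data.table(idx = which(keep), meth = m[keep], total = cov[keep],
                     beta = m[keep] / cov[keep])
        groups <- c(groups, ty)
        ids <- c(ids, paste0(ty, "_rep", r))
      }
    }
    list(betas = betas, groups = groups, sample_ids = ids)
  })
}

#' Simulate a PAT fragment pool for one cell type
#'
#' Repeatedly draws fragments, applies the capture protocol, simulates reads,
#' applies the non-conversion read filter, and converts to PAT until the pool
#' holds at least `n_fragments` fragment instances (then trims to exactly
#' that many). Deterministic under `seed`.
#'
#' @param genome A `fc_genome`.
#' @param methylome Numeric per-CpG methylation probability vector (one
#'   column of `fc_methylomes$M`).
#' @param n_fragments Target pool size in fragment instances.
#' @param protocol,length_model,conv,read_len,min_cpg Simulation parameters
#'   (see [apply_capture()], [fragment_genome()], [simulate_reads()],
#'   [reads_to_pat()]).
#' @param seed Integer seed.
#' @param cell_type Label stored with the fragments.
#' @param max_batches Safety bound on the batch loop.
#' @return A collapsed, sorted PAT table holding exactly `n_fragments`
#'   instances.
#' @export
simulate_pat_pool <- function(genome, methylome, n_fragments,
                              protocol = "flexseq", length_model = "cfDNA",
                              conv = conversion_model(), read_len = 100L,
                              min_cpg = 3L, seed = 1L,
                              cell_type = NA_character_, max_batches = 40L) {
  got <- 0L
  acc <- list()
  yield <- 0.5
  batch <- 0L
  while (got < n_fragments) {
    batch <- batch + 1L
    if (batch > max_batches)
      stop("pool did not reach ", n_fragments, " fragments after ",
           max_batches, " batches (yield ~", signif(yield, 2), ")")
    n_in <- max(5e4L, as.integer(ceiling((n_fragments - got) / yield * 1.2)))
    bseed <- seed + 7L * batch
    frags <- fragment_genome(genome$seqs, length_model, n_in, seed = bseed,
                             cell_type = cell_type)
    pieces <- apply_capture(frags, genome$sites, protocol)
    reads <- simulate_reads(pieces, genome$seqs, genome$cpgs, methylome,
                            read_len = read_len, conv = conv,
                            seed = bseed + 1L)
    reads <- filter_non_conversion(reads)
    pat <- reads_to_pat(reads, genome$cpgs, min_cpg = min_cpg)
    acc[[batch]] <- pat
    got <- got + sum(pat$count)
    yield <- max(got / (batch * n_in), 1e-3)
  }
  pool <- collapse_pat(rbindlist(acc))
  # downsample uniformly (not positionally) to exactly n_fragments instances
  if (got > n_fragments)
    pool <- mix_pat(list(pool), 1, n_fragments, seed = seed + 999L)
  pool
}

#' Simulate a cohort of mixed samples with known truth
#'
#' For each sample, input fragments are allocated multinomially across the
#' composition, simulated per cell type through capture and read simulation,
#' and converted to a PAT table. `n_fragments` counts input fragments before
#' capture; the captured yield depends on the protocol.
#'
#' @param compositions Matrix (samples x cell types, rows summing to 1) or a
#'   list of named composition vectors.
#' @param n_fragments Input fragments per sample.
#' @param genome A `fc_genome`.
#' @param methylomes A `fc_methylomes`.
#' @param protocol,length_model,conv,read_len,min_cpg Simulation parameters.
#' @param seed Integer seed.
#' @return List with `pats` (list of PAT tables) and `truth` (the composition
#'   matrix).
#' @export
make_cohort <- function(compositions, n_fragments, genome, methylomes,
                        protocol = "flexseq", length_model = "cfDNA",
                        conv = conversion_model(), read_len = 100L,
                        min_cpg = 3L, seed = 1L) {
  if (is.list(compositions) && !is.matrix(compositions))
    compositions <- do.call(rbind, compositions)
  types <- colnames(compositions)
  stopifnot(all(types %in% colnames(methylomes$M)),
            all(abs(rowSums(compositions) - 1) < 1e-8))
  pats <- vector("list", nrow(compositions))
  for (s in seq_len(nrow(compositions))) {
    sseed <- seed + 97L * s
    counts <- with_seed_(sseed,
                         as.vector(rmultinom(1L, n_fragments, compositions[s, ])))
    parts <- list()
    for (ti in seq_along(types)) {
      if (counts[ti] == 0L) next
      frags <- fragment_genome(genome$seqs, length_model, counts[ti],
                               seed = sseed + ti, cell_type = types[ti])
      pieces <- apply_capture(frags, genome$sites, protocol)
      reads <- simulate_reads(pieces, genome$seqs, genome$cpgs,
                              methylomes$M[, types[ti]], read_len = read_len,
                              conv = conv, seed = sseed + 211L * ti)
      reads <- filter_non_conversion(reads)
      parts[[length(parts) + 1L]] <- reads_to_pat(reads, genome$cpgs, min_cpg)
    }
    pats[[s]] <- collapse_pat(rbindlist(parts))
  }
  list(pats = pats, truth = compositions)
}
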