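# Genome segmentation into methylation-homogeneous blocks and one-vs-all
# identification of cell-type-specific markers and DMRs.

# Per-group pooled beta matrix (n_cpg x n_groups) from per-sample beta tracks.
group_beta_matrix <- function(betas, groups, n_cpg) {
  G <- unique(groups)
  B <- matrix(NA_real_, nrow = n_cpg, ncol = length(G),
              dimnames = list(NULL, G))
  for (g in G) {
    agg <- rbindlist(betas[groups == g])[, .(m = sum(meth), t = sum(total)), by = idx]
    B[agg$idx, g] <- agg$m / agg$t
  }
  B
}

#' Segment the genome into methylation-homogeneous blocks
#'
#' Greedy left-to-right segmentation over the CpG index: a block grows while
#' (a) its bp span stays within `max_bp` and (b) for every reference group the
#' within-block range of pooled per-CpG beta values stays within the
#' homogeneity tolerance `tau`. Blocks never cross chromosome boundaries.
#' Blocks with fewer than `min_cpg` CpGs are discarded, and blocks are then
#' restricted to `len_range` bp.
#'
#' @param betas List of per-sample beta tracks (from [pat_to_beta()] or
#'   [make_reference_betas()]).
#' @param groups Character vector of reference group labels, one per sample.
#' @param cpgs CpG map.
#' @param min_cpg Minimum CpGs per block (default 3).
#' @param max_bp Maximum block span in bp (default 5000).
#' @param tau Homogeneity tolerance on the per-group beta range (default
#'   0.25).
#' @param len_range Keep blocks whose bp length lies in this closed interval
#'   (default 10--2000); `NULL` disables the filter.
#' @return `data.table` of blocks: `block_id`, `chrom`, `start`, `end`
#'   (0-based half-open, spanning first CpG C to last CpG G), `idx_start`,
#'   `idx_end`, `n_cpgs`.
#' @export
segment_blocks <- function(betas, groups, cpgs, min_cpg = 3L, max_bp = 5000L,
                           tau = 0.25, len_range = c(10L, 2000L)) {
  stopifnot(length(betas) >= 1L, length(betas) == length(groups))
  n <- nrow(cpgs)
  if (n == 0L)
    return(data.table(block_id = integer(0), chrom = character(0),
                      start = integer(0), end = integer(0),
                      idx_start = integer(0), idx_end = integer(0),
                      n_cpgs = integer(0)))
  B <- group_beta_matrix(betas, groups, n)
  chr <- cpgs$chrom
  pos <- cpgs$pos
  starts <- .segment_greedy(B, as.integer(pos),
                            as.integer(factor(chr, levels = unique(chr))),
                            as.integer(max_bp), tau)
  idx_start <- starts
  idx_end <- c(starts[-1L] - 1L, n)
  out <- data.table(chrom = chr[idx_start], start = pos[idx_start],
                    end = pos[idx_end] + 2L, idx_start = idx_start,
                    idx_end = idx_end, n_cpgs = idx_end - idx_start + 1L)
  out <- out[n_cpgs >= min_cpg]
  if (!is.null(len_range))
    out <- out[end - start >= len_range[1] & end - start <= len_range[2]]
  out[, block_id := seq_len(.N)]
  setcolorder(out, c("block_id"))
  out[]
}

#' Average beta of blocks in one sample
#'
#' Pools methylated and total calls across each block's CpGs and reports a
#' single beta per block; beta is `NA` (undefined) where the block has zero
#' coverage.
#'
#' @param blocks Block table from [segment_blocks()] (or a marker table with
#'   `idx_start`/`idx_end`).
#' @param beta A per-sample beta track.
#' @param n_cpg Total number of CpGs in the index (defaults to the largest
#'   index seen).
#' @return `data.table` with `block_id`, `meth`, `total`, `beta`.
#' @export
block_average_beta <- function(blocks, beta, n_cpg = NULL) {
  n_cpg <- n_cpg %||% max(blocks$idx_end, beta$idx)
  mv <- numeric(n_cpg)
  tv <- numeric(n_cpg)
  mv[beta$idx] <- beta$meth
  tv[beta$idx] <- beta$total
  cm <- c(0, cumsum(mv))
  ct <- c(0, cumsum(tv))
  m <- cm[blocks$idx_end + 1L] - cm[blocks$idx_start]
  t <- ct[blocks$idx_end + 1L] - ct[blocks$idx_start]
  data.table(block_id = blocks$block_id, meth = m, total = t,
             beta = ifelse(t > 0, m / t, NA_real_))
}

#' One-vs-all cell-type marker discovery
#'
#' For each group, candidate blocks must pass, in order: minimum CpGs, bp
#' length range, mean per-CpG coverage of at least `min_cov` (averaged over
#' samples), an absolute difference between the target-group and pooled
#' background mean beta of at least `delta_means`, a two-sample test p-value
#' below `alpha` across per-sample block betas, and the categorical criterion
#' that the target group mean is below `meth_lo` while every other group mean
#' is at least `meth_hi` (hypomethylated marker) or vice versa. Markers are
#' scored by a percentile gap -- for hypomethylated markers the 2.5th
#' percentile of the background minus the 75th percentile of the target; for
#' hypermethylated markers the 25th percentile of the target minus the 97.5th
#' percentile of the background -- ranked by delta (ties by gap, then genomic
#' coordinate), and the top `top_k` per group are returned. When a group
#' yields more than `max_candidates` candidates, the stricter
#' `strict_delta`/`strict_quants` cutoffs are additionally applied.
#'
#' @param blocks Block table from [segment_blocks()].
#' @param betas List of per-sample beta tracks.
#' @param groups Group label per sample (at least 2 groups, each with at
#'   least 1 sample).
#' @param cpgs CpG map (used only for its size).
#' @param min_cpg,min_cov,delta_means,alpha,len_range,top_k Marker filters;
#'   defaults 4, 10, 0.3, 0.05, 10--2000 bp, 30.
#' @param meth_hi,meth_lo Categorical thresholds (default 0.66 / 0.33).
#' @param test `"wilcoxon"` (Mann-Whitney U, default) or `"welch"`.
#' @param max_candidates,strict_delta,strict_quants Large-set tightening
#'   (defaults 1000, 0.4, 0.1).
#' @return `data.table` of markers: block coordinates plus `type`,
#'   `direction` (`hypo`/`hyper`), `delta`, `gap`, `p_value`, `coverage`,
#'   `mean_target`, `mean_background`, `marker_id`.
#' @export
find_markers <- function(blocks, betas, groups, cpgs, min_cpg = 4L,
                         min_cov = 10, delta_means = 0.3, alpha = 0.05,
                         len_range = c(10L, 2000L), top_k = 30L,
                         meth_hi = 0.66, meth_lo = 0.33,
                         test = c("wilcoxon", "welch"),
                         max_candidates = 1000L, strict_delta = 0.4,
                         strict_quants = 0.1) {
  test <- match.arg(test)
  stopifnot(length(unique(groups)) >= 2L)
  n_cpg <- nrow(cpgs)
  S <- length(betas)
  cand <- blocks[n_cpgs >= min_cpg & end - start >= len_range[1] &
                   end - start <= len_range[2]]
  if (nrow(cand) == 0L) return(empty_markers())
  betaM <- matrix(NA_real_, nrow(cand), S)
  covM <- matrix(0, nrow(cand), S)
  for (s in seq_len(S)) {
    ab <- block_average_beta(cand, betas[[s]], n_cpg)
    betaM[, s] <- ab$beta
    covM[, s] <- ab$total / cand$n_cpgs
  }
  all_undef <- vapply(unique(groups), function(g)
    all(is.na(betaM[, groups == g])), logical(1))
  if (any(all_undef)) {
    warning("group(s) with all-undefined betas excluded: ",
            paste(unique(groups)[all_undef], collapse = ", "))
    keep_g <- !(groups %in% unique(groups)[all_undef])
    betaM <- betaM[, keep_g, drop = FALSE]
    covM <- covM[, keep_g, drop = FALSE]
    groups <- groups[keep_g]
  }
  G <- unique(groups)
  GM <- vapply(G, function(g) rowMeans(betaM[, groups == g, drop = FALSE],
                                       na.rm = TRUE), numeric(nrow(cand)))
  GM <- matrix(GM, nrow = nrow(cand), dimnames = list(NULL, G))
  mean_cov <- rowMeans(covM)
  res <- vector("list", length(G))
  for (gi in seq_along(G)) {
    g <- G[gi]
    tcols <- which(groups == g)
    bcols <- which(groups != g)
    mean_t <- GM[, gi]
    mean_bg <- rowMeans(betaM[, bcols, drop = FALSE], na.rm = TRUE)
    delta <- abs(mean_t - mean_bg)
    others <- GM[, -gi, drop = FALSE]
    hypo <- mean_t < meth_lo & apply(others >= meth_hi, 1, all)
    hyper <- mean_t >= meth_hi & apply(others < meth_lo, 1, all)
    sel <- which(mean_cov >= min_cov & delta >= delta_means & (hypo | hyper) &
                   !is.na(mean_t) & !is.na(mean_bg))
    if (length(sel) == 0L) { res[[gi]] <- NULL; next }
    pv <- vapply(sel, function(b) {
      x <- betaM[b, tcols]; y <- betaM[b, bcols]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (length(x) < 1L || length(y) < 1L) return(NA_real_)
      suppressWarnings(
        if (test == "wilcoxon") wilcox.test(x, y)$p.value
        else t.test(x, y)$p.value)
    }, numeric(1))
    keep_p <- !is.na(pv) & pv < alpha
    sel <- sel[keep_p]
    pv <- pv[keep_p]
    if (length(sel) == 0L) { res[[gi]] <- NULL; next }
    gap <- vapply(seq_along(sel), function(j) {
      b <- sel[j]
      x <- betaM[b, tcols]; y <- betaM[b, bcols]
      x <- x[!is.na(x)]; y <- y[!is.na(y)]
      if (hypo[b]) quantile(y, 0.025, names = FALSE) - quantile(x, 0.75, names = FALSE)
      else quantile(x, 0.25, names = FALSE) - quantile(y, 0.975, names = FALSE)
    }, numeric(1))
    m <- data.table(cand[sel],
                    type = g,
                    direction = ifelse(hypo[sel], "hypo", "hyper"),
                    delta = delta[sel], gap = gap, p_value = pv,
                    coverage = mean_cov[sel],
                    mean_target = mean_t[sel], mean_background = mean_bg[sel])
    if (nrow(m) > max_candidates)
      m <- m[delta > strict_delta & gap > strict_quants]
    setorder(m, -delta, -gap, chrom, start)
    res[[gi]] <- head(m, top_k)
  }
  out <- rbindlist(res[!vapply(res, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L) return(empty_markers())
  out[, marker_id := seq_len(.N)]
  out[]
}

empty_markers <- function() {
  data.table(block_id = integer(0), chrom = character(0), start = integer(0),
             end = integer(0), idx_start = integer(0), idx_end = integer(0),
             n_cpgs = integer(0), type = character(0), direction = character(0),
             delta = numeric(0), gap = numeric(0), p_value = numeric(0),
             coverage = numeric(0), mean_target = numeric(0),
             mean_background = numeric(0), marker_id = integer(0))
}

#' Differentially methylated regions between two groups
#'
#' Two-group special case of [find_markers()] with the DMR defaults: minimum
#' 3 CpGs, coverage 8, delta 0.3, p < 0.05, length 10--1500 bp, top 100 by
#' delta. Returns the markers called for `case_group`.
#'
#' @param blocks,betas,groups,cpgs As in [find_markers()]; `groups` must have
#'   exactly two levels.
#' @param case_group The group whose DMRs are reported (default: first level).
#' @param ... Overrides passed to [find_markers()].
#' @export
find_dmrs <- function(blocks, betas, groups, cpgs,
                      case_group = unique(groups)[1], ...) {
  stopifnot(length(unique(groups)) == 2L)
  args <- list(blocks = blocks, betas = betas, groups = groups, cpgs = cpgs,
               min_cpg = 3L, min_cov = 8, delta_means = 0.3, alpha = 0.05,
               len_range = c(10L, 1500L), top_k = 100L)
  over <- list(...)
  args[names(over)] <- over
  m <- do.call(find_markers, args)
  m[type == case_group]
}

#' Write markers as extended BED
#'
#' BED6+ with extra columns group, direction, delta, coverage.
#'
#' @param markers Marker table from [find_markers()].
#' @param path Output path.
#' @export
write_markers_bed <- function(markers, path) {
  out <- markers[, .(chrom, start, end,
                     name = paste0(type, "_", marker_id),
                     score = round(1000 * pmin(1, delta)),
                     strand = ".", group = type, direction, delta, coverage)]
  fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}
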