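# Fragment-level (UXM-style) and CpG-level mixture estimation of cell-type
# proportions against a marker reference atlas.

#' Classify fragments as U / X / M
#'
#' A fragment with at least `min_cpgs` called CpGs is mostly Unmethylated (U)
#' when its methylated fraction f is at most `u_max`, mostly Methylated (M)
#' when f is at least `m_min`, and miXed (X) otherwise; fragments with fewer
#' calls are unclassifiable.
#'
#' @param patterns Character vector of PAT patterns over `{C,T,.}`.
#' @param min_cpgs Minimum called (non-dot) CpGs (default 3).
#' @param u_max,m_min Methylated-fraction thresholds (defaults 0.25 / 0.75).
#' @return Character vector over `{"U","X","M","unclassifiable"}`.
#' @export
classify_fragment_uxm <- function(patterns, min_cpgs = 3L, u_max = 0.25,
                                  m_min = 0.75) {
  nC <- stri_count_fixed(patterns, "C")
  nT <- stri_count_fixed(patterns, "T")
  n <- nC + nT
  f <- ifelse(n > 0L, nC / n, NA_real_)
  out <- rep("unclassifiable", length(patterns))
  out[n >= min_cpgs & f <= u_max] <- "U"
  out[n >= min_cpgs & f >= m_min] <- "M"
  out[n >= min_cpgs & f > u_max & f < m_min] <- "X"
  out
}

# Overlap-join PAT fragments with marker CpG spans, classify the in-marker
# portion of each fragment, and tally U/X/M counts per marker.
marker_uxm_counts <- function(pat, markers, min_cpgs = 3L, u_max = 0.25,
                              m_min = 0.75) {
  if (nrow(pat) == 0L || nrow(markers) == 0L)
    return(data.table(marker_id = integer(0), class_uxm = character(0),
                      count = integer(0)))
  x <- pat[, .(first_idx, last_idx = first_idx + nchar(pattern) - 1L,
               pattern, count)]
  y <- markers[, .(marker_id, idx_start, idx_end)]
  setkey(y, idx_start, idx_end)
  ov <- foverlaps(x, y, by.x = c("first_idx", "last_idx"),
                  by.y = c("idx_start", "idx_end"), nomatch = NULL)
  if (nrow(ov) == 0L)
    return(data.table(marker_id = integer(0), class_uxm = character(0),
                      count = integer(0)))
  ov[, sub_pattern := stri_sub(pattern,
                               pmax(1L, idx_start - first_idx + 1L),
                               pmin(last_idx, idx_end) - first_idx + 1L)]
  ov[, class_uxm := classify_fragment_uxm(sub_pattern, min_cpgs, u_max, m_min)]
  ov[class_uxm != "unclassifiable",
     .(count = sum(count)), by = .(marker_id, class_uxm)]
}

# Direction-aware informative fraction per marker: U-fraction on
# hypomethylated markers, M-fraction on hypermethylated ones.
marker_signal <- function(uxm, markers) {
  if (nrow(uxm) == 0L)
    return(data.table(marker_id = markers$marker_id, value = NA_real_,
                      n_frag = 0L))
  wide <- dcast(uxm, marker_id ~ class_uxm, value.var = "count", fill = 0L)
  for (cl in c("U", "X", "M")) if (is.null(wide[[cl]])) wide[, (cl) := 0L]
  m <- merge(markers[, .(marker_id, direction)], wide, by = "marker_id",
             all.x = TRUE)
  for (cl in c("U", "X", "M")) m[is.na(get(cl)), (cl) := 0L]
  m[, n_frag := U + X + M]
  m[, value := ifelse(n_frag > 0L,
                      ifelse(direction == "hypo", U / n_frag, M / n_frag),
                      NA_real_)]
  m[, .(marker_id, value, n_frag)]
}

#' Build a reference atlas from per-cell-type PAT sets
#'
#' In fragment mode the atlas entry A\[marker, cell type\] is the
#' direction-aware fraction of classifiable fragments (U-fraction on
#' hypomethylated markers, M-fraction on hypermethylated ones) of that cell
#' type on that marker. In beta mode the entry is the block-average beta.
#' Entries for which a cell type has no fragments are imputed with the
#' marker's cross-type median and flagged; markers with no signal in any type
#' are dropped with a warning.
#'
#' @param ref_pats Named list (cell type -> PAT table) of reference fragment
#'   sets.
#' @param markers Marker table from [find_markers()] (needs `marker_id`,
#'   `idx_start`, `idx_end`, `direction`).
#' @param min_cpgs,u_max,m_min Fragment classification parameters.
#' @param mode `"fragment"` (default) or `"beta"`.
#' @return Object of class `"fc_atlas"`: list with `A` (markers x cell types
#'   matrix), `markers` (rows aligned with `A`), `cell_types`, `mode`,
#'   `imputed` (logical matrix), and the classification parameters.
#' @export
build_atlas <- function(ref_pats, markers, min_cpgs = 3L, u_max = 0.25,
                        m_min = 0.75, mode = c("fragment", "beta")) {
  mode <- match.arg(mode)
  stopifnot(!is.null(names(ref_pats)), nrow(markers) > 0L)
  types <- names(ref_pats)
  A <- matrix(NA_real_, nrow(markers), length(types),
              dimnames = list(markers$marker_id, types))
  for (ty in types) {
    if (mode == "fragment") {
      sig <- marker_signal(marker_uxm_counts(ref_pats[[ty]], markers,
                                             min_cpgs, u_max, m_min), markers)
      A[match(sig$marker_id, markers$marker_id), ty] <- sig$value
    } else {
      bt <- pat_to_beta(ref_pats[[ty]])
      blocks <- markers[, .(block_id = marker_id, idx_start, idx_end)]
      ab <- block_average_beta(blocks, bt)
      A[match(ab$block_id, markers$marker_id), ty] <- ab$beta
    }
  }
  all_missing <- rowSums(!is.na(A)) == 0L
  if (any(all_missing)) {
    warning(sum(all_missing), " marker(s) with no classifiable fragments in ",
            "any reference dropped")
    A <- A[!all_missing, , drop = FALSE]
    markers <- markers[!all_missing]
  }
  imputed <- is.na(A)
  if (any(imputed)) {
    med <- apply(A, 1, stats::median, na.rm = TRUE)
    for (j in seq_len(ncol(A))) A[imputed[, j], j] <- med[imputed[, j]]
  }
  structure(list(A = A, markers = markers, cell_types = types, mode = mode,
                 imputed = imputed,
                 params = list(min_cpgs = min_cpgs, u_max = u_max,
                               m_min = m_min)),
            class = "fc_atlas")
}

#' @export
print.fc_atlas <- function(x, ...) {
  cat(sprintf("<fc_atlas> %s mode: %d markers x %d cell types (%.1f%% imputed)\n",
              x$mode, nrow(x$A), ncol(x$A), 100 * mean(x$imputed)))
  invisible(x)
}

# non-negative least squares followed by simplex renormalization
nnls_proportions <- function(A, b, w = NULL) {
  if (!is.null(w)) {
    A <- A * w
    b <- b * w
  }
  fit <- pracma::lsqnonneg(A, b)
  p <- fit$x
  if (sum(p) <= 0) stop("degenerate fit: all proportions zero")
  names(p) <- colnames(A)
  p / sum(p)
}

#' Fragment-level deconvolution of a sample against an atlas
#'
#' Computes the sample's direction-aware informative fragment fraction on
#' every atlas marker, solves `min || A p - b ||` subject to `p >= 0`
#' (non-negative least squares), and renormalizes `p` to sum to 1. Markers
#' with no sample fragments are excluded from the fit. Rows are weighted by
#' the square root of the sample fragment count per marker (heteroscedasticity
#' of the binomial fractions); set `weighting = "none"` to disable.
#'
#' @param pat Sample PAT table.
#' @param atlas An `fc_atlas` in fragment mode.
#' @param weighting `"sqrt"` (default) or `"none"`.
#' @return Object of class `"fc_deconv"`: list with `proportions` (named,
#'   sums to 1), `residual` (unweighted residual norm), `n_markers_used`, and
#'   `marker_fragments` (per-marker fragment counts).
#' @export
deconvolve_fragments <- function(pat, atlas, weighting = c("sqrt", "none")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(atlas, "fc_atlas"), atlas$mode == "fragment")
  sig <- marker_signal(
    marker_uxm_counts(pat, atlas$markers, atlas$params$min_cpgs,
                      atlas$params$u_max, atlas$params$m_min),
    atlas$markers)
  sig <- sig[match(atlas$markers$marker_id, marker_id)]
  use <- which(sig$n_frag > 0L)
  if (length(use) == 0L)
    stop("sample has no classifiable fragments on any atlas marker")
  A <- atlas$A[use, , drop = FALSE]
  b <- sig$value[use]
  w <- if (weighting == "sqrt") sqrt(sig$n_frag[use]) else NULL
  p <- nnls_proportions(A, b, w)
  structure(list(proportions = p,
                 residual = sqrt(sum((A %*% p - b)^2)),
                 n_markers_used = length(use),
                 marker_fragments = sig[, .(marker_id, n_frag)]),
            class = "fc_deconv")
}

#' CpG-level deconvolution of a beta track against a beta-mode atlas
#'
#' The sample signal per marker is its block-average beta; since beta values
#' mix linearly in the cell-type proportions, non-negative least squares on
#' the beta-mode atlas recovers the mixture. Markers with zero sample
#' coverage are excluded.
#'
#' @param beta Sample beta track from [pat_to_beta()].
#' @param atlas An `fc_atlas` in beta mode.
#' @param weighting `"sqrt"` (by total block coverage) or `"none"`.
#' @return An `fc_deconv` object.
#' @export
deconvolve_cpg <- function(beta, atlas, weighting = c("sqrt", "none")) {
  weighting <- match.arg(weighting)
  stopifnot(inherits(atlas, "fc_atlas"), atlas$mode == "beta")
  blocks <- atlas$markers[, .(block_id = marker_id, idx_start, idx_end)]
  ab <- block_average_beta(blocks, beta,
                           n_cpg = max(atlas$markers$idx_end, beta$idx))
  use <- which(ab$total > 0)
  if (length(use) == 0L) stop("sample covers no atlas marker")
  A <- atlas$A[use, , drop = FALSE]
  b <- ab$beta[use]
  w <- if (weighting == "sqrt") sqrt(ab$total[use]) else NULL
  p <- nnls_proportions(A, b, w)
  structure(list(proportions = p,
                 residual = sqrt(sum((A %*% p - b)^2)),
                 n_markers_used = length(use),
                 marker_fragments = data.table(marker_id = ab$block_id[use],
                                               n_frag = ab$total[use])),
            class = "fc_deconv")
}

#' @export
print.fc_deconv <- function(x, ...) {
  cat("<fc_deconv> proportions:\n")
  print(round(sort(x$proportions, decreasing = TRUE), 4))
  cat(sprintf("residual %.4g over %d markers\n", x$residual, x$n_markers_used))
  invisible(x)
}

#' Root-mean-square error between two proportion vectors
#'
#' @param pred,truth Equal-length numeric vectors.
#' @return `sqrt(mean((pred - truth)^2))`.
#' @export
rmse <- function(pred, truth) {
  if (length(pred) != length(truth)) stop("length mismatch")
  sqrt(mean((pred - truth)^2))
}
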