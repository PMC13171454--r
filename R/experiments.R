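# End-to-end workflows tying the modules together: reference system
# construction, titration series, flank-restriction comparison, and the
# synthetic classification cohort. These are the entry points used by the
# reproducibility script and the heavier tests.

#' Build a complete synthetic reference system
#'
#' Generates a genome with CpG islands, plants cell-type-specific
#' hypomethylated markers, simulates reference samples, discovers markers by
#' segmentation + one-vs-all selection, builds a fragment-mode reference
#' atlas from independent reference fragment pools, and simulates independent
#' mixing pools per cell type (so atlas and mixtures never share fragments).
#'
#' @param cell_types Cell-type labels (default: seven types spanning immune,
#'   epithelial, hepatic and neural lineages).
#' @param markers_per_type Planted markers per type (default 250).
#' @param chrom_lengths Chromosome lengths (default 4 x 450 kb).
#' @param mix_pool_size Fragment instances per cell type available for
#'   mixing (default 3e5).
#' @param ref_pool_size Fragment instances per cell type behind the atlas
#'   (default 2e5).
#' @param top_k Markers retained per type in the atlas (default 250).
#' @param n_ref_samples Reference samples per type for marker discovery
#'   (default 3).
#' @param conv Conversion error model.
#' @param protocol,length_model Capture protocol and fragment length model
#'   for the pools.
#' @param seed Integer master seed; all stages derive sub-seeds from it.
#' @return List of class `"fc_system"` with the genome, methylomes, reference
#'   betas, discovered `markers`, `atlas`, `ref_pools`, and `mix_pools`.
#' @export
simulate_reference_system <- function(cell_types = c("Bcell", "Tcell", "Monocyte",
                                                     "Neutrophil", "Hepatocyte",
                                                     "LungAlveolar", "Neuron"),
                                      markers_per_type = 250L,
                                      chrom_lengths = c(chr1 = 450000L, chr2 = 450000L,
                                                        chr3 = 450000L, chr4 = 450000L),
                                      mix_pool_size = 3e5, ref_pool_size = 2e5,
                                      top_k = markers_per_type,
                                      n_ref_samples = 3L,
                                      conv = conversion_model(),
                                      protocol = "flexseq",
                                      length_model = "cfDNA", seed = 1L) {
  n_islands <- as.integer(ceiling(length(cell_types) * markers_per_type * 1.08))
  gspec <- synthetic_genome_spec(chrom_lengths = chrom_lengths,
                                 n_islands = n_islands, seed = seed)
  genome <- make_genome(gspec)
  mspec <- synthetic_methylome_spec(cell_types, markers_per_type,
                                    seed = seed + 1L)
  methylomes <- make_methylomes(mspec, genome)
  refs <- make_reference_betas(methylomes, n_per_type = n_ref_samples,
                               mean_coverage = 30, seed = seed + 2L)
  blocks <- segment_blocks(refs$betas, refs$groups, genome$cpgs)
  markers <- find_markers(blocks, refs$betas, refs$groups, genome$cpgs,
                          min_cpg = 4L, min_cov = 10, delta_means = 0.3,
                          alpha = 0.05, top_k = top_k)
  ref_pools <- list()
  mix_pools <- list()
  for (ti in seq_along(cell_types)) {
    ty <- cell_types[ti]
    ref_pools[[ty]] <- simulate_pat_pool(genome, methylomes$M[, ty],
                                         ref_pool_size, protocol = protocol,
                                         length_model = length_model,
                                         conv = conv, seed = seed + 1000L + ti,
                                         cell_type = ty)
    mix_pools[[ty]] <- simulate_pat_pool(genome, methylomes$M[, ty],
                                         mix_pool_size, protocol = protocol,
                                         length_model = length_model,
                                         conv = conv, seed = seed + 2000L + ti,
                                         cell_type = ty)
  }
  atlas <- build_atlas(ref_pools, markers)
  structure(list(genome = genome, methylomes = methylomes, refs = refs,
                 blocks = blocks, markers = markers, ref_pools = ref_pools,
                 mix_pools = mix_pools, atlas = atlas,
                 cell_types = cell_types, conv = conv, seed = seed),
            class = "fc_system")
}

#' Run a titration series through fragment-level deconvolution
#'
#' Mixes the target cell type into a background composition at the requested
#' proportions (one mixture per level, drawn from the system's mixing pools),
#' deconvolves each mixture against the system atlas, and reports the
#' estimated target proportion per level.
#'
#' @param system An `fc_system`.
#' @param target_type Cell type being titrated.
#' @param proportions Target proportions, e.g.
#'   `c(0, 0.003, 0.01, 0.03, 0.10, 0.40, 1)`.
#' @param n_fragments Fragments per mixture (default 2e5).
#' @param background_weights Optional named weights over the non-target
#'   types (default: equal). They are rescaled by `1 - level` at each level.
#' @param seed Integer seed.
#' @return `data.table` with `level`, `estimate`, and the full proportion
#'   vectors as a list column `proportions`.
#' @export
run_titration <- function(system, target_type, proportions,
                          n_fragments = 2e5, background_weights = NULL,
                          seed = 1L) {
  stopifnot(target_type %in% system$cell_types)
  others <- setdiff(system$cell_types, target_type)
  if (is.null(background_weights))
    background_weights <- stats::setNames(rep(1 / length(others), length(others)),
                                          others)
  stopifnot(all(names(background_weights) %in% others))
  bw <- stats::setNames(numeric(length(others)), others)
  bw[names(background_weights)] <- background_weights
  background_weights <- bw / sum(bw)
  res <- vector("list", length(proportions))
  for (i in seq_along(proportions)) {
    lev <- proportions[i]
    w <- c(stats::setNames(lev, target_type), background_weights * (1 - lev))
    w <- w[system$cell_types]
    w[is.na(w)] <- 0
    names(w) <- system$cell_types
    mixed <- mix_pat(system$mix_pools[system$cell_types], w, n_fragments,
                     seed = seed + 11L * i)
    dec <- deconvolve_fragments(mixed, system$atlas)
    res[[i]] <- data.table(level = lev,
                           estimate = unname(dec$proportions[target_type]),
                           proportions = list(dec$proportions))
  }
  rbindlist(res)
}

#' Detection floor of a titration series
#'
#' The smallest nonzero titration level whose estimate is positive and within
#' a factor of two of the truth.
#'
#' @param titration Output of [run_titration()].
#' @return The qualifying level (same units as `level`), or `NA` if no level
#'   qualifies.
#' @export
detection_floor <- function(titration) {
  ok <- titration[level > 0 & estimate > 0 &
                    estimate >= level / 2 & estimate <= level * 2]
  if (nrow(ok) == 0L) NA_real_ else min(ok$level)
}

#' Compare deconvolution from all fragments vs motif-flank-restricted data
#'
#' Simulates a whole-genome (uncaptured) plasma-like sample at the given
#' composition, deconvolves it once from all fragments and once after
#' masking all CpGs outside the CCGG +/- `b` bp flank regions (sample and
#' reference atlas alike), and reports the RMSE between the two proportion
#' vectors.
#'
#' @param system An `fc_system`.
#' @param composition Named proportions over the system cell types (sums
#'   to 1).
#' @param n_fragments Whole-genome fragments for the sample (default 5e5).
#' @param b Flank half-width in bp (default 100).
#' @param ref_pool_size Whole-genome reference fragments per type for the
#'   two atlases (default 1.5e5).
#' @param seed Integer seed.
#' @return List with `p_full`, `p_flank`, `rmse`, and the flank regions.
#' @export
flank_restriction_experiment <- function(system, composition, n_fragments = 5e5,
                                         b = 100L, ref_pool_size = 1.5e5,
                                         seed = 1L) {
  types <- system$cell_types
  stopifnot(all(names(composition) %in% types),
            abs(sum(composition) - 1) < 1e-8)
  comp <- stats::setNames(numeric(length(types)), types)
  comp[names(composition)] <- composition
  # whole-genome reference pools and sample
  wg_pools <- lapply(types, function(ty)
    simulate_pat_pool(system$genome, system$methylomes$M[, ty], ref_pool_size,
                      protocol = "wgbs", length_model = "cfDNA",
                      conv = system$conv, seed = seed + 3000L + match(ty, types),
                      cell_type = ty))
  names(wg_pools) <- types
  cohort <- make_cohort(matrix(comp, nrow = 1, dimnames = list(NULL, types)),
                        n_fragments, system$genome, system$methylomes,
                        protocol = "wgbs", length_model = "cfDNA",
                        conv = system$conv, seed = seed + 4000L)
  sample_pat <- cohort$pats[[1]]
  atlas_full <- build_atlas(wg_pools, system$markers)
  p_full <- deconvolve_fragments(sample_pat, atlas_full)$proportions

  flanks <- flank_regions(system$genome$sites, b = b)
  keep <- cpgs_in_regions(system$genome$cpgs, flanks)
  sample_flank <- restrict_pat(sample_pat, keep)
  flank_pools <- lapply(wg_pools, restrict_pat, keep_idx = keep)
  atlas_flank <- build_atlas(flank_pools, system$markers)
  p_flank <- deconvolve_fragments(sample_flank, atlas_flank)$proportions

  common <- intersect(names(p_full), names(p_flank))
  list(p_full = p_full, p_flank = p_flank,
       rmse = rmse(p_full[common], p_flank[common]), flanks = flanks)
}

# Dirichlet-style jitter of a base composition: gamma draws with shapes
# proportional to the base weights times `concentration`.
jitter_composition <- function(base, concentration = 200) {
  g <- rgamma(length(base), shape = base * concentration)
  stats::setNames(g / sum(g), names(base))
}

#' Simulate and classify a tumor / negative-control cohort
#'
#' Builds a cohort of negative controls (immune-background compositions with
#' Dirichlet jitter) and tumor samples in which a cell of origin is elevated
#' by a purity drawn from `purity_range`; deconvolves every sample from the
#' mixing pools; z-scores each sample against the negative controls
#' (dropping extreme-low outliers per cell type); classifies tumors by
#' leading z-score; and evaluates accuracy and per-class AUC.
#'
#' @param system An `fc_system`.
#' @param tumor_map Named character vector: cell of origin -> tumor type,
#'   e.g. `c(LungAlveolar = "LUAD", Bcell = "DLBC")`.
#' @param n_per_group Samples per tumor type and negative controls (default
#'   20).
#' @param n_fragments Fragments per sample (default 2e4).
#' @param purity_range Tumor purity range (default 0.05--0.2).
#' @param background Named base composition of the immune background
#'   (defaults to B/T/monocyte/neutrophil at 0.2/0.3/0.2/0.3).
#' @param z_threshold Classification threshold (default 2).
#' @param concentration Dirichlet concentration of the jitter (default 200).
#' @param seed Integer seed.
#' @return List with `calls`, `metrics` (from [evaluate_calls()]),
#'   `proportions` (samples x cell types), `zmat` (z of each tumor class's
#'   cell of origin), and `truth`.
#' @export
simulate_classification_cohort <- function(system,
                                           tumor_map = c(LungAlveolar = "LUAD",
                                                         Bcell = "DLBC"),
                                           n_per_group = 20L, n_fragments = 2e4,
                                           purity_range = c(0.05, 0.2),
                                           background = c(Bcell = 0.2, Tcell = 0.3,
                                                          Monocyte = 0.2,
                                                          Neutrophil = 0.3),
                                           z_threshold = 2, concentration = 200,
                                           seed = 1L) {
  types <- system$cell_types
  stopifnot(all(names(tumor_map) %in% types), all(names(background) %in% types))
  full <- function(w) {
    out <- stats::setNames(numeric(length(types)), types)
    out[names(w)] <- w
    out
  }
  compositions <- list()
  gold <- character(0)
  with_seed_(seed, {
    for (i in seq_len(n_per_group)) {
      compositions[[length(compositions) + 1L]] <-
        full(jitter_composition(background, concentration))
      gold <- c(gold, NA_character_)
    }
    for (tt in seq_along(tumor_map)) {
      coo <- names(tumor_map)[tt]
      for (i in seq_len(n_per_group)) {
        u <- runif(1, purity_range[1], purity_range[2])
        bg <- jitter_composition(background, concentration) * (1 - u)
        w <- full(bg)
        w[coo] <- w[coo] + u
        compositions[[length(compositions) + 1L]] <- w
        gold <- c(gold, unname(tumor_map[tt]))
      }
    }
  })
  n_samp <- length(compositions)
  P <- matrix(0, n_samp, length(types), dimnames = list(NULL, types))
  for (s in seq_len(n_samp)) {
    mixed <- mix_pat(system$mix_pools[types], compositions[[s]], n_fragments,
                     seed = seed + 37L * s)
    P[s, ] <- deconvolve_fragments(mixed, system$atlas)$proportions[types]
  }
  is_neg <- is.na(gold)
  ref <- P[is_neg, , drop = FALSE]
  # drop negative controls that are extreme-low outliers for any COO type
  drop <- rep(FALSE, nrow(ref))
  for (coo in names(tumor_map))
    drop <- drop | flag_extreme_low(ref[, coo])
  ref_use <- ref[!drop, , drop = FALSE]
  calls <- vector("list", n_samp)
  zmat <- matrix(NA_real_, n_samp, length(tumor_map),
                 dimnames = list(NULL, unname(tumor_map)))
  for (s in seq_len(n_samp)) {
    zp <- zscores(P[s, ], ref_use)
    zmat[s, ] <- zp$z[match(names(tumor_map), zp$cell_type)]
    calls[[s]] <- classify_coo(zp, tumor_map, gold[s],
                               z_threshold = z_threshold,
                               indeterminate_types = character(0),
                               is_reference = is_neg[s])
  }
  calls <- rbindlist(calls)
  tumor_rows <- which(!is_neg)
  metrics <- evaluate_calls(calls[tumor_rows], tumor_map,
                            scores = zmat[tumor_rows, , drop = FALSE])
  list(calls = calls, metrics = metrics, proportions = P, zmat = zmat,
       truth = list(gold = gold, compositions = compositions,
                    dropped_negatives = which(is_neg)[drop]))
}

#' Z-score of the injected cell of origin as a function of tumor purity
#'
#' Titrates a target cell type over the immune background at the given
#' purities, deconvolves, and z-scores the target against a simulated
#' negative-control reference.
#'
#' @param system An `fc_system`.
#' @param target_type Injected cell of origin.
#' @param purities Increasing purity levels.
#' @param n_fragments Fragments per sample (default 2e4).
#' @param n_negatives Negative controls for the reference (default 12).
#' @param background Immune background composition.
#' @param concentration Dirichlet concentration.
#' @param seed Integer seed.
#' @return `data.table` with `purity` and `z`.
#' @export
purity_zscore_curve <- function(system, target_type,
                                purities = c(0.05, 0.1, 0.2, 0.4),
                                n_fragments = 2e4, n_negatives = 12L,
                                background = c(Bcell = 0.2, Tcell = 0.3,
                                               Monocyte = 0.2, Neutrophil = 0.3),
                                concentration = 200, seed = 1L) {
  types <- system$cell_types
  full <- function(w) {
    out <- stats::setNames(numeric(length(types)), types)
    out[names(w)] <- w
    out
  }
  negs <- with_seed_(seed, lapply(seq_len(n_negatives), function(i)
    full(jitter_composition(background, concentration))))
  ref <- t(vapply(seq_along(negs), function(i) {
    mixed <- mix_pat(system$mix_pools[types], negs[[i]], n_fragments,
                     seed = seed + 51L * i)
    deconvolve_fragments(mixed, system$atlas)$proportions[types]
  }, numeric(length(types))))
  colnames(ref) <- types
  res <- vector("list", length(purities))
  for (i in seq_along(purities)) {
    u <- purities[i]
    w <- with_seed_(seed + 500L + i,
                    full(jitter_composition(background, concentration) * (1 - u)))
    w[target_type] <- w[target_type] + u
    mixed <- mix_pat(system$mix_pools[types], w, n_fragments,
                     seed = seed + 900L + i)
    p <- deconvolve_fragments(mixed, system$atlas)$proportions[types]
    zp <- zscores(p, ref)
    res[[i]] <- data.table(purity = u,
                           z = zp$z[zp$cell_type == target_type])
  }
  rbindlist(res)
}
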