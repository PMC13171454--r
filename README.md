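# flankcapture

Design analysis, simulation, and deconvolution for restriction-flank
methylation capture — the family of assays that sequence the DNA fragments
flanking MspI (CCGG) cut sites to profile a methylome cheaply from
low-input, fragmented DNA such as cell-free DNA or FFPE tissue extracts.

The assay logic: every input molecule is ligated on its natural ends with a
semi-permissive adapter **A**, cut with MspI (methylation-insensitive), and
the fresh cut ends receive adapter **B**. Only A+B molecules amplify — uncut
(A+A) and fully internal (B+B) pieces drop out — so every read is anchored
at a cut site (it starts `C/TGG` after conversion) and sequencing
concentrates on CCGG flanks, which are rich in CpG islands, promoters, and
cell-type-specific markers. Classic RRBS is the B+B complement and needs
two cuts on one short fragment; whole-genome methylome sequencing captures
everything and spends most of its depth on uninformative loci.

The package is for computational biologists who want to (i) explore where a
cut-anchored capture can reach on a genome, (ii) simulate such data with
known truth, and (iii) run the downstream methylation analyses that the
assay enables:

- **In silico digestion and design** — `scan_motif_sites()`,
  `flank_regions()` (bedtools-slop semantics), `rrbs_regions()`
  (bedtools-merge semantics), `coverage_stats()`, `annotate_contexts()`
  (island/shore/shelf/open sea; promoter-first functional precedence),
  `theoretical_coverage()`.
- **Capture simulation** — `fragment_genome()` (cfDNA ~N(170, 20); FFPE
  ~U(100, 500); sheared ~N(450, 50)), `apply_capture()` (the A/B adapter
  algebra), `simulate_reads()` with a conversion-error model,
  `filter_non_conversion()`, `on_target_rate()`.
- **Fragment-level methylation data** — PAT records
  (chrom, first CpG index, C/T/. pattern, count): `reads_to_pat()`,
  `pat_to_beta()`, `read_pat()`/`write_pat()`, `restrict_pat()`, and the
  titration mixer `mix_pat()`.
- **Marker discovery** — `segment_blocks()` (greedy homogeneity
  segmentation), `find_markers()` (one-vs-all: delta ≥ 0.3, p < 0.05,
  the 0.66/0.33 categorical rule, percentile-gap scoring, top-k by delta),
  `find_dmrs()`.
- **Deconvolution** — `classify_fragment_uxm()` (U/X/M fragments),
  `build_atlas()`, and non-negative least squares mixture estimation:
  solve min ‖A·p − b‖₂ s.t. p ≥ 0, then renormalize p to the simplex,
  where A[m, c] is the reference U-fraction of cell type c on marker m and
  b the sample's U-fractions (`deconvolve_fragments()`, `deconvolve_cpg()`,
  `rmse()`).
- **Cell-of-origin classification** — z = (x − μ)/σ against a
  negative-control reference population, top-ranked z > 2 with a
  COO association → Matched / Misleading profile / Indeterminate
  (`zscores()`, `classify_coo()`, `flag_extreme_low()`,
  `evaluate_calls()`).
- **Synthetic truth** — genomes with CpG/CCGG-enriched islands, planted
  cell-type markers, reference samples, fragment pools, and cohorts:
  `make_genome()`, `make_methylomes()`, `make_cohort()`,
  `simulate_reference_system()`, `run_titration()`,
  `simulate_classification_cohort()`.

## Worked example

Build a complete synthetic reference system (1.8 Mb genome, seven cell
types, 250 planted markers each, discovered de novo from simulated
reference samples, with a fragment-level atlas), then titrate one cell type
through a seven-level dilution series of 200,000 fragments per mixture:

```r
library(flankcapture)

system <- simulate_reference_system(seed = 1)   # ~1 minute
tit <- run_titration(system, "LungAlveolar",
                     c(0, 0.003, 0.01, 0.03, 0.10, 0.40, 1),
                     n_fragments = 2e5, seed = 2)
tit[, .(level, estimate)]
#>    level    estimate
#> 1: 0.000 0.000000000
#> 2: 0.003 0.003804876
#> 3: 0.010 0.012338003
#> 4: 0.030 0.032232635
#> 5: 0.100 0.099616526
#> 6: 0.400 0.397891162
#> 7: 1.000 0.999709258
rmse(tit$estimate, tit$level)
#> [1] 0.00150131
detection_floor(tit)
#> [1] 0.003
```

The estimated target proportion tracks the truth with RMSE ≈ 0.0015 over
the series, and the lowest dilution still recovered within twofold of truth
is the 0.3% level — the fragment-level detection floor. Deconvolving an
immune-dominated mixture shows the full proportion vector:

```r
p <- deconvolve_fragments(
  mix_pat(system$mix_pools,
          c(Bcell = 0.2, Tcell = 0.3, Monocyte = 0.2, Neutrophil = 0.25,
            Hepatocyte = 0.05, LungAlveolar = 0, Neuron = 0),
          1e5, seed = 3),
  system$atlas)
p
#> <fc_deconv> proportions:
#>        Tcell   Neutrophil     Monocyte        Bcell   Hepatocyte LungAlveolar
#>       0.3011       0.2495       0.2010       0.2003       0.0481       0.0000
#>       Neuron
#>       0.0000
#> residual 3.183 over 1728 markers
```

Each number is the estimated fraction of fragments from that cell type; the
absent types are correctly pushed to zero and the 5% hepatocyte spike is
recovered at 4.8%.

The methods vignette (`vignettes/flankcapture-methods.Rmd`) documents the
models, parameter choices, and the limits of what synthetic data can show.

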