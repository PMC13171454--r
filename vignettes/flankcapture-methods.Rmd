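---
title: "Restriction-flank methylation capture: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Restriction-flank methylation capture: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The assay being modeled

Methylation profiling of clinical specimens — cell-free DNA from body
fluids, fragmented DNA from FFPE tissue — must work with little, short DNA.
Whole-genome approaches spend most of their depth on uninformative loci;
classic reduced-representation (RRBS) requires a fragment to carry *two*
MspI cut ends, which short fragments rarely do. The capture scheme this
package models takes the middle road: every input molecule is first ligated
on both natural ends with a semi-permissive adapter (A), then cut with MspI
at CCGG (methylation-insensitive), and the freshly exposed cut ends receive
a second adapter (B). Only molecules carrying one A and one B end amplify:
uncut molecules (A+A) and fully internal restriction pieces (B+B) are
excluded. Every sequenced read is therefore anchored at a cut site — its
first trinucleotide after cytosine conversion is `CGG` or `TGG` — and reads
interrogate the flanks of CCGG motifs, which are enriched for CpG islands,
promoters and cell-type-specific methylation markers.

`flankcapture` implements the computational side of this design end to end:
the in silico pre-design analysis (where could such an assay reach?), a
capture and read simulator with a conversion-error model, the
fragment-level methylation data model (PAT records), marker discovery,
mixture deconvolution, and a z-score classifier for the cell of origin of a
tumor — plus a synthetic-data module so the full pipeline runs and is
tested without any external downloads.

## Coordinates and data model

Region-level objects are `GRanges` (1-based closed intervals, the
Bioconductor convention); the simulator and BED-style arithmetic use
0-based half-open `[start, end)` integers inside `data.table`s, matching
bedtools semantics: `flank_regions()` reproduces `bedtools slop -b` with
clipping at chromosome bounds, and `rrbs_regions()` reproduces
`bedtools merge -d` (two intervals merge when their gap is at most `d`).

CpGs are numbered by a single global 1-based index over all `CG`
dinucleotides in genome order. A PAT record is
`(chrom, first CpG index, pattern, count)` with pattern characters `C`
(methylated), `T` (unmethylated) and `.` (missing); a beta track tallies
patterns into per-CpG methylated/total counts. Methylation calls are
duplex-level: the simulator emits one call per CpG dinucleotide, standing
in for the strand-merging step that real pipelines perform on top/bottom
strand calls staggered by 1 bp.

## The capture model

`apply_capture()` implements the adapter algebra exactly. A fragment with
`k` cuts strictly inside `(start, end)` splits into `k + 1` pieces:

* one-cut protocol (`"flexseq"`): the two terminal pieces survive (one
  free A end, one cut B end); `k = 0` fragments and the `k - 1` internal
  pieces are lost;
* two-cut protocol (`"rrbs"`): exactly the internal pieces survive;
* `"wgbs"`: the whole fragment survives.

The two captured sets partition each cut fragment — a conservation law the
test suite asserts on random fragment populations. Chromosome ends count as
free ends. MspI cuts C^CGG, so the cut coordinate is motif start + 1 and
both daughter pieces abut the motif-internal CpG; reads from a cut end
start on that CpG, which is why the on-target prefix is `C/TGG` and why the
simulator's one-cut reads are on-target with rate exactly 1. Pieces too
short to yield a CpG call still read through the cut site, so their prefix
is drawn from the motif CpG's methylation state directly.

Fragment lengths come from three named models: `cfDNA` (normal, 170 ± 20
bp), `FFPE` (uniform 100–500 bp), and `sheared` (normal, 450 ± 50 bp), all
truncated at 30 bp. Reads cover up to `read_len` bp from the anchored end;
the default of 100 bp stands in for the span a short paired-end read pair
covers after merging — the simulator does not emit paired reads.

## Conversion error and read filtering

`conversion_model()` has two parameters: `p_nonconversion`, the chance an
unmethylated cytosine escapes conversion (reads C), and
`p_overconversion`, the chance a methylated cytosine converts anyway
(reads T). Both default to 0.005, typical of fresh enzymatic conversions.
Because incomplete conversion affects whole molecules, real pipelines drop
reads with several unconverted non-CpG cytosines;
`filter_non_conversion()` mirrors that with a default threshold of 3
unconverted non-CpG cytosines per read (the Bismark default; the upstream
tooling names the filter but not its threshold, so it is a flag).

## Segmentation and marker discovery

`segment_blocks()` segments the genome into methylation-homogeneous blocks
by a greedy left-to-right rule: a block grows while its span stays within
`max_bp` (default 5000) and, for every reference group, the within-block
range of pooled per-CpG betas stays within a homogeneity tolerance `tau`
(default 0.25, flag-tunable). The upstream block-segmentation tool this
emulates does not document its algorithm, so the greedy rule is this
package's own, chosen to be simple and auditable; blocks are then
restricted to 3+ CpGs and 10–2000 bp. The greedy kernel is compiled (Rcpp)
because it is the one genuinely serial loop in the pipeline.

`find_markers()` applies the one-vs-all criteria in the order printed by
its flags: minimum CpGs (4), length 10–2000 bp, mean per-CpG coverage at
least `min_cov`, |mean(target) − mean(background)| ≥ 0.3, a two-sample
test p < 0.05, and the categorical rule that the target group's mean beta
is < 0.33 while every other group's is ≥ 0.66 (hypomethylated marker), or
vice versa. The test behind the p-value is unnamed upstream; Mann–Whitney U
across per-sample block betas is the default with Welch's t as a flag.
"Coverage of the marker" is interpreted as mean per-CpG coverage averaged
over samples (minimum per-CpG coverage is the stricter alternative; the
choice is exposed through the inputs rather than a flag). Markers are
scored by the percentile gap (for hypomethylated markers, the background's
2.5th percentile minus the target's 75th; for hypermethylated, the
target's 25th minus the background's 97.5th), ranked by delta with ties
broken by gap then coordinate, and the top `k` per group are kept. No
multiple-testing correction is applied at this step, deliberately: the
marker list is a ranked candidate set validated downstream by
deconvolution, not an inferential result. `find_dmrs()` is the two-group
special case (3+ CpGs, coverage 8, length 10–1500 bp, top 100).

## Fragment-level deconvolution

`classify_fragment_uxm()` labels each fragment mostly-Unmethylated, miXed,
or mostly-Methylated from its methylated fraction over called CpGs within
a marker; at least 3 called CpGs are required, and the U/M thresholds are
0.25/0.75. The cited fragment-level method leaves these numeric choices to
the implementation, so all three are flags.

The reference atlas entry `A[m, c]` is the direction-aware informative
fraction of cell type `c` on marker `m`: the U-fraction on hypomethylated
markers and the M-fraction on hypermethylated ones, among U/X/M-classified
fragments. Entries with no fragments are imputed by the marker's
cross-type median and flagged; markers empty in every type are dropped
with a warning. Deconvolution solves non-negative least squares
`min ||A p − b||, p ≥ 0` on the sample's per-marker fractions and
renormalizes `p` to the simplex, reporting the residual so poor fits are
visible. Rows are weighted by the square root of the sample fragment count
per marker — the fractions are binomial, so their variance scales as 1/n —
with unweighted fitting available as a flag. NNLS-then-renormalize was
chosen over a constrained simplex solver for transparency; on every tested
mixture the renormalization correction is small.

`deconvolve_cpg()` is the CpG-level counterpart: block-average betas mix
linearly in the proportions, so the same NNLS applies with a beta-mode
atlas. It stands in for EM-based CpG-level deconvolution tools; no EM is
implemented, and on linear noiseless mixtures the NNLS solution is exact.

## The z-score classifier

`zscores()` normalizes a sample's deconvolved proportions against a
reference population (negative controls or non-target cases):
z = (x − μ)/σ with σ the sample standard deviation (n − 1 denominator; the
convention is not dictated upstream, so it is stated here). Cell types
with σ = 0 are excluded from ranking, as are configured background types.
`classify_coo()` requires the top-ranked eligible cell type to exceed z = 2
(strictly) and to map to a tumor type: a match with the gold standard is
`Matched`, a different tumor type `Misleading profile`, anything else —
including a leading cell type on the indeterminate list, e.g.
oligodendrocyte in brain specimens — `Indeterminate`. Ties at the top rank
break by raw proportion, then name. `flag_extreme_low()` implements the
extreme lower fence Q1 − 3·IQR with type-7 (linear interpolation)
quartiles, used to drop aberrant negative controls before normalization.
Accuracy is Matched/(Matched + Misleading); per-class AUC uses the
rank-statistic estimator with ties averaged (cross-checked against pROC in
the tests).

## What the synthetic data emulates — and what it does not

`make_genome()` builds i.i.d. background sequence (GC 0.4) with CpG
islands on an evenly spaced, jittered grid; islands carry planted CpGs
(one per 8 bp) and CCGG motifs at 5× the background planting rate of
1/300 bp. Spontaneous CCGGs from the background composition add
≈ (GC/2)⁴ per bp to both strata, so realized island enrichment is somewhat
below the nominal factor; the generator tests account for that dilution
explicitly. Defaults give a 1.8 Mb genome in four chromosomes with ~1850
islands — enough to host 250 markers for each of seven cell types.

`make_methylomes()` plants one marker per island: beta 0.05 in the owning
cell type, 0.95 everywhere else, which satisfies the 0.66/0.33 marker
criterion with delta 0.9 by construction. Reference samples add N(0, 0.04)
per-sample beta noise and Poisson(30) coverage. Titration mixtures are
drawn with `mix_pat()`: a single multinomial split across sources followed
by uniform sampling without replacement within each source (without
replacement matches the physics of mixing finite DNA aliquots; the
upstream mixer does not document its choice). Cohort samples jitter their
composition with a Dirichlet of concentration 200 so that negative
controls have nonzero variance for the z-score denominator.

The generator deliberately omits repeats, SNPs, copy-number events,
fragment-end biases, PCR duplication and sequencing error beyond the
conversion model. Passing tests therefore demonstrate that the algorithms
are correct and well-calibrated under clean, known truth — not that the
assay achieves any particular performance on real tissue. Real-data
headline figures (correlation with WGBS, clinical cohort accuracy) are out
of reach of a synthetic desk-scale run and are represented only by their
structural analogues (titration RMSE, detection floors, classifier
accuracy on synthetic cohorts).

## Problem sizes and reproducibility

The bundled experiments run at the study conditions: seven cell types ×
250 markers on the 1.8 Mb genome; mixing pools of 3 × 10⁵ and atlas pools
of 2 × 10⁵ captured fragments per type; titration mixtures of 2 × 10⁵
fragments at 0/0.3/1/3/10/40/100% target proportions; a plasma-like
whole-genome sample of 5 × 10⁵ fragments for the flank-restriction
comparison; and a 20/20/20 cohort of 2 × 10⁴-fragment samples. Every
stochastic step takes an explicit seed and derives sub-seeds from it, so
`simulate_reference_system(seed = s)` is fully reproducible, including
byte-identical PAT files.

```{r example}
library(flankcapture)
system <- simulate_reference_system(seed = 1)
tit <- run_titration(system, "LungAlveolar",
                     c(0, 0.003, 0.01, 0.03, 0.10, 0.40, 1),
                     n_fragments = 2e5, seed = 2)
rmse(tit$estimate, tit$level)
detection_floor(tit)
```

## Known limitations

* The atlas and the sample must share the capture protocol; mixing
  protocols shifts the U/X/M composition slightly (the X class absorbs
  most of it).
* Deconvolution of cell types without planted markers rests entirely on
  their M-signal on other types' markers; with very low fragment counts
  the NNLS can push such types to zero.
* The greedy segmentation is order-dependent (left-to-right); change
  points are found within one CpG of the truth in the tests, but an exact
  optimal segmentation is not attempted.
* `theoretical_coverage()` reports reachable-space fractions for a supplied
  genome; the shipped synthetic genomes are far smaller than a mammalian
  genome, so those fractions are illustrative, not comparable to
  genome-scale figures.
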