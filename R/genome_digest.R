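# In silico restriction digestion, flank/RRBS region construction, CpG
# enumeration, and theoretical-coverage statistics.

#' Read a genome from a FASTA file
#'
#' Thin wrapper around [Biostrings::readDNAStringSet()] that uppercases the
#' sequences and strips FASTA description text from the names. Gzipped files
#' are handled transparently.
#'
#' @param path Path to a (optionally gzipped) FASTA file.
#' @return A [Biostrings::DNAStringSet] named by chromosome.
#' @export
read_genome_fasta <- function(path) {
  seqs <- Biostrings::readDNAStringSet(path)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  Biostrings::DNAStringSet(toupper(seqs))
}

# Reject genomes containing characters outside {A,C,G,T,N}.
check_genome_alphabet <- function(genome) {
  af <- Biostrings::alphabetFrequency(genome)
  other <- setdiff(colnames(af), c("A", "C", "G", "T", "N"))
  bad <- rowSums(af[, other, drop = FALSE])
  if (any(bad > 0))
    stop("genome contains non-ACGTN characters in sequence(s): ",
         paste(names(genome)[bad > 0], collapse = ", "))
  invisible(TRUE)
}

# Convert an MIndex from vmatchPattern into a sorted GRanges carrying the
# genome's seqinfo.
mindex_to_granges <- function(hits, genome, width) {
  ir <- unlist(hits)
  sl <- stats::setNames(Biostrings::width(genome), names(genome))
  if (length(ir) == 0L) {
    gr <- GenomicRanges::GRanges(seqlengths = sl)
  } else {
    gr <- GenomicRanges::GRanges(
      factor(names(ir), levels = names(genome)),
      IRanges::IRanges(IRanges::start(ir), width = width),
      seqlengths = sl)
  }
  GenomicRanges::sort(gr)
}

#' Locate all occurrences of a restriction motif
#'
#' Scans each chromosome for exact occurrences of a 4-bp restriction motif.
#' CCGG (MspI) and TCGA (TaqI) are reverse-complement palindromes, so a
#' single-strand scan reports every cut site on the duplex. Windows containing
#' `N` never match.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param motif 4-character uppercase motif, default `"CCGG"`.
#' @param cut_offset 0-based offset of the cut within the motif; both MspI
#'   (C^CGG) and TaqI (T^CGA) cut after the first base, hence the default 1.
#' @return An object of class `"fc_sites"`: a list with elements `motif`,
#'   `cut_offset`, and `sites` (a sorted [GenomicRanges::GRanges] of motif
#'   occurrences, 1-based).
#' @export
scan_motif_sites <- function(genome, motif = "CCGG", cut_offset = 1L) {
  if (nchar(motif) != 4L) stop("motif must be a 4-mer")
  motif <- toupper(motif)
  check_genome_alphabet(genome)
  hits <- Biostrings::vmatchPattern(motif, genome, fixed = TRUE)
  gr <- mindex_to_granges(hits, genome, width = 4L)
  structure(list(motif = motif, cut_offset = as.integer(cut_offset), sites = gr),
            class = "fc_sites")
}

#' @export
print.fc_sites <- function(x, ...) {
  cat(sprintf("<fc_sites> motif %s (cut offset %d): %d occurrences on %d sequence(s)\n",
              x$motif, x$cut_offset, length(x$sites),
              length(unique(as.character(GenomicRanges::seqnames(x$sites))))))
  invisible(x)
}

# 0-based cut coordinates per chromosome, as a data.table(chrom, cut).
cut_table <- function(sites) {
  gr <- sites$sites
  data.table(chrom = as.character(GenomicRanges::seqnames(gr)),
             cut = IRanges::start(gr) - 1L + sites$cut_offset)
}

#' Expand motif sites into flank regions
#'
#' Each 4-bp motif interval is expanded by `b` bp on both sides (the
#' `bedtools slop -b` operation), clipped to chromosome bounds, and merged
#' into disjoint intervals. These flanks are the assay's target space.
#'
#' @param sites An `fc_sites` object from [scan_motif_sites()].
#' @param b Non-negative expansion in bp on each side.
#' @return A reduced (disjoint, sorted) [GenomicRanges::GRanges].
#' @export
flank_regions <- function(sites, b) {
  stopifnot(b >= 0)
  gr <- sites$sites
  ex <- suppressWarnings(GenomicRanges::trim(gr + as.integer(b)))
  GenomicRanges::reduce(ex)
}

#' Construct RRBS-style two-cut regions
#'
#' Merges motif intervals whose gap is at most `d` bp (the `bedtools merge -d`
#' semantics) and drops merged regions shorter than `min_len`. A fragment must
#' carry two cut ends to be captured by classic reduced-representation
#' protocols, so these regions approximate that assay's reachable space.
#'
#' @param sites An `fc_sites` object.
#' @param d Maximum gap (bp) between motifs to merge.
#' @param min_len Regions shorter than this are dropped (default 30 bp).
#' @return A [GenomicRanges::GRanges] of disjoint regions.
#' @export
rrbs_regions <- function(sites, d, min_len = 30) {
  stopifnot(d >= 0)
  gr <- GenomicRanges::reduce(sites$sites, min.gapwidth = as.integer(d) + 1L)
  gr[IRanges::width(gr) >= min_len]
}

#' Enumerate CpG sites and assign the global CpG index
#'
#' Finds every CG dinucleotide and numbers them 1..N in genome order
#' (chromosomes in the order of `names(genome)`, then position). This index is
#' the coordinate system of PAT records and beta tracks.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @return A `data.table` with columns `chrom`, `pos` (0-based position of the
#'   C), and `idx` (global 1-based CpG index).
#' @export
cpg_index_map <- function(genome) {
  hits <- Biostrings::vmatchPattern("CG", genome, fixed = TRUE)
  ir <- unlist(hits)
  dt <- data.table(chrom = if (length(ir)) names(ir) else character(0),
                   pos = IRanges::start(ir) - 1L)
  dt[, chrom := as.character(chrom)]
  dt <- dt[order(factor(chrom, levels = names(genome)), pos)]
  dt[, idx := seq_len(.N)]
  dt[]
}

#' Global CpG indices falling inside a region set
#'
#' @param cpgs CpG map from [cpg_index_map()].
#' @param regions A [GenomicRanges::GRanges].
#' @return Integer vector of global CpG indices whose C base lies in `regions`.
#' @export
cpgs_in_regions <- function(cpgs, regions) {
  if (nrow(cpgs) == 0L) return(integer(0))
  cpgs$idx[IRanges::overlapsAny(cpg_granges(cpgs), regions)]
}

#' Coverage statistics of a region set
#'
#' Counts each CpG once and reports what fraction of all CpGs, of
#' marker-region CpGs, and of the genome the regions cover. With an empty CpG
#' map the fractions are `NA` (undefined), not zero.
#'
#' @param regions Disjoint [GenomicRanges::GRanges] (reduced if not).
#' @param cpgs CpG map from [cpg_index_map()].
#' @param markers Optional [GenomicRanges::GRanges] of marker regions.
#' @param genome_len Total genome length in bp.
#' @return A list with `n_cpgs_in_regions`, `frac_of_all_cpgs`,
#'   `frac_marker_cpgs_covered`, and `genome_fraction`.
#' @export
coverage_stats <- function(regions, cpgs, markers = NULL, genome_len) {
  regions <- GenomicRanges::reduce(regions)
  n_total <- nrow(cpgs)
  covered <- cpgs_in_regions(cpgs, regions)
  frac_marker <- NA_real_
  if (!is.null(markers)) {
    m_idx <- cpgs_in_regions(cpgs, markers)
    frac_marker <- if (length(m_idx)) length(intersect(covered, m_idx)) / length(m_idx)
                   else NA_real_
  }
  list(n_cpgs_in_regions = length(covered),
       frac_of_all_cpgs = if (n_total > 0L) length(covered) / n_total else NA_real_,
       frac_marker_cpgs_covered = frac_marker,
       genome_fraction = sum(IRanges::width(regions)) / genome_len)
}

#' Annotate CpGs by island distance and functional context
#'
#' Assigns each CpG one island-distance category (`island` if it overlaps an
#' island, `shore` within 2 kb, `shelf` within 2--4 kb, else `open_sea`) and
#' one functional category. Functional annotation uses first-match precedence
#' over the ordered list `functional` (promoters first by convention);
#' unmatched CpGs are `intergenic`.
#'
#' @param cpgs CpG map from [cpg_index_map()].
#' @param islands [GenomicRanges::GRanges] of CpG islands.
#' @param functional Named ordered list of [GenomicRanges::GRanges]
#'   (e.g. `list(promoter = ..., enhancer = ..., CDS = ...)`).
#' @return `data.table` with columns `idx`, `cpg_context`,
#'   `functional_context`.
#' @export
annotate_contexts <- function(cpgs, islands, functional = list()) {
  gr <- cpg_granges(cpgs)
  n <- nrow(cpgs)
  in_island <- IRanges::overlapsAny(gr, islands)
  d <- rep(NA_real_, n)
  if (length(islands)) {
    h <- GenomicRanges::distanceToNearest(gr, islands)
    d[S4Vectors::queryHits(h)] <- S4Vectors::mcols(h)$distance
  }
  cpg_context <- rep("open_sea", n)
  cpg_context[!is.na(d) & d <= 4000] <- "shelf"
  cpg_context[!is.na(d) & d <= 2000] <- "shore"
  cpg_context[in_island] <- "island"

  functional_context <- rep("intergenic", n)
  assigned <- logical(n)
  for (nm in names(functional)) {
    hit <- IRanges::overlapsAny(gr, functional[[nm]]) & !assigned
    functional_context[hit] <- nm
    assigned <- assigned | hit
  }
  data.table(idx = cpgs$idx, cpg_context = cpg_context,
             functional_context = functional_context)
}

#' Theoretical reachable coverage for one-cut and two-cut capture
#'
#' For fragments of a given length, a one-cut protocol can in principle reach
#' any base within `fragment_len` bp of a cut site, whereas a two-cut protocol
#' is confined to stretches where two motifs lie within `fragment_len` of each
#' other. Reports the genome fraction and CpG fraction reachable by each mode.
#'
#' @param sites An `fc_sites` object.
#' @param cpgs CpG map.
#' @param fragment_len Fragment length in bp (e.g. 100 for highly fragmented
#'   tissue DNA).
#' @param genome_len Total genome length.
#' @param min_len Minimum region length for the two-cut mode (default 30).
#' @return List with components `one_cut` and `two_cut`, each a list of
#'   `genome_fraction` and `frac_of_all_cpgs`.
#' @export
theoretical_coverage <- function(sites, cpgs, fragment_len, genome_len,
                                 min_len = 30) {
  one <- flank_regions(sites, b = fragment_len)
  two <- rrbs_regions(sites, d = fragment_len, min_len = min_len)
  s1 <- coverage_stats(one, cpgs, genome_len = genome_len)
  s2 <- coverage_stats(two, cpgs, genome_len = genome_len)
  list(one_cut = list(genome_fraction = s1$genome_fraction,
                      frac_of_all_cpgs = s1$frac_of_all_cpgs),
       two_cut = list(genome_fraction = s2$genome_fraction,
                      frac_of_all_cpgs = s2$frac_of_all_cpgs))
}

#' Read/write BED files
#'
#' Wrappers around [rtracklayer::import()]/[rtracklayer::export()]; BED is
#' 0-based half-open on disk, `GRanges` 1-based in memory, and rtracklayer
#' performs the shift.
#'
#' @param path File path ending in `.bed`.
#' @param gr A [GenomicRanges::GRanges].
#' @return `read_bed()` returns a `GRanges`; `write_bed()` returns `path`
#'   invisibly.
#' @export
read_bed <- function(path) rtracklayer::import(path, format = "BED")

#' @rdname read_bed
#' @export
write_bed <- function(gr, path) {
  rtracklayer::export(gr, path, format = "BED")
  invisible(path)
}
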