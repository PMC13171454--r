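# Fragment-level methylation data model: PAT read/write, beta tracks, and the
# titration mixer.
#
# A PAT record is (chrom, first CpG index, pattern over {C,T,.}, count): C =
# methylated call, T = unmethylated, '.' = missing. The CpG index is the
# global 1-based numbering from cpg_index_map(); because that index increases
# along the genome, sorting by (first_idx, pattern) is also sorted by
# chromosome.

pat_sorted <- function(pat) {
  !is.unsorted(pat$first_idx) &&
    !any(pat$first_idx == shift(pat$first_idx) &
           pat$pattern < shift(pat$pattern), na.rm = TRUE)
}

sort_pat <- function(pat) {
  setorder(pat, first_idx, pattern)
  pat
}

# collapse identical (chrom, first_idx, pattern) records, summing counts
collapse_pat <- function(pat) {
  out <- pat[, .(count = sum(count)), by = .(chrom, first_idx, pattern)]
  sort_pat(out)
  out[, .(chrom, first_idx, pattern, count)]
}

#' Convert simulated reads to PAT records
#'
#' Reads covering fewer than `min_cpg` CpGs are dropped; identical records are
#' collapsed with summed counts; output is sorted by CpG index then pattern.
#'
#' @param reads Read table from [simulate_reads()] (columns `chrom`,
#'   `first_idx`, `n_cpg`, `pattern`, `count`).
#' @param cpgs Optional CpG map; when supplied, read coordinates are checked
#'   against it and a mismatch is an error.
#' @param min_cpg Minimum number of called CpGs per read (default 3).
#' @return A sorted PAT `data.table` (`chrom`, `first_idx`, `pattern`,
#'   `count`).
#' @export
reads_to_pat <- function(reads, cpgs = NULL, min_cpg = 3L) {
  keep <- reads[n_cpg >= min_cpg]
  if (!is.null(cpgs) && nrow(keep)) {
    last <- keep$first_idx + keep$n_cpg - 1L
    if (any(is.na(keep$first_idx)) || min(keep$first_idx) < 1L ||
        max(last) > nrow(cpgs))
      stop("read CpG positions fall outside the CpG index map")
  }
  if (nrow(keep) == 0L)
    return(data.table(chrom = character(0), first_idx = integer(0),
                      pattern = character(0), count = integer(0)))
  collapse_pat(keep[, .(chrom, first_idx, pattern, count)])
}

#' Tally a PAT table into a per-CpG beta track
#'
#' Each non-dot pattern character contributes `count` observations to its CpG
#' index; `.` contributes nothing. Beta is methylated/total.
#'
#' @param pat A PAT table.
#' @return `data.table` with columns `idx`, `meth`, `total`, `beta`, keyed by
#'   `idx`.
#' @export
pat_to_beta <- function(pat) {
  stop_if_not_pat(pat)
  if (nrow(pat) == 0L)
    return(data.table(idx = integer(0), meth = numeric(0), total = numeric(0),
                      beta = numeric(0), key = "idx"))
  len <- nchar(pat$pattern)
  big <- paste(pat$pattern, collapse = "")
  chars <- strsplit(big, "", fixed = TRUE)[[1]]
  cg <- rep(pat$first_idx, len) + sequence(len) - 1L
  w <- rep(pat$count, len)
  dt <- data.table(cg = cg, ch = chars, w = w)[ch != "."]
  out <- dt[, .(meth = sum(w * (ch == "C")), total = sum(w)), by = .(idx = cg)]
  out[, beta := meth / total]
  setkey(out, idx)
  out[]
}

#' Mix PAT sources at given proportions
#'
#' Draws `n_fragments` fragment instances: the per-source counts come from a
#' single multinomial draw with the given weights, then instances are sampled
#' uniformly without replacement within each source (records are expanded by
#' their multiplicity `count`). Deterministic under `seed`.
#'
#' @param sources List of PAT tables.
#' @param weights Non-negative weights summing to 1 (one per source).
#' @param n_fragments Total fragments to draw.
#' @param seed Optional seed.
#' @return A collapsed, sorted PAT table; the realized per-source counts are
#'   attached as `attr(, "source_counts")`.
#' @export
mix_pat <- function(sources, weights, n_fragments, seed = NULL) {
  stopifnot(length(sources) == length(weights), all(weights >= 0))
  if (abs(sum(weights) - 1) > 1e-8) stop("weights must sum to 1")
  for (i in seq_along(sources)) {
    if (weights[i] > 0 && nrow(sources[[i]]) == 0L)
      stop("source ", i, " is empty but has positive weight")
  }
  with_seed_(seed, {
    k <- as.vector(rmultinom(1L, n_fragments, weights))
    picked <- vector("list", length(sources))
    for (i in seq_along(sources)) {
      if (k[i] == 0L) next
      src <- sources[[i]]
      cum <- cumsum(src$count)
      N <- cum[length(cum)]
      if (k[i] > N)
        stop("source ", i, " holds ", N, " fragment instances, ",
             k[i], " requested")
      inst <- sample.int(N, k[i])
      rec <- findInterval(inst - 1L, cum) + 1L
      picked[[i]] <- src[rec, .(chrom, first_idx, pattern)][, count := 1L]
    }
    out <- collapse_pat(rbindlist(picked[!vapply(picked, is.null, logical(1))]))
    setattr(out, "source_counts", k)
    out
  })
}

#' Read and write PAT files
#'
#' PAT files are headerless 4-column tab-separated text (chromosome, first CpG
#' index, pattern, count), optionally gzipped. `read_pat()` validates the
#' pattern alphabet and counts, reporting offending line numbers, and warns +
#' sorts if the file is unsorted. `write_pat()` writes (gzip when the path
#' ends in `.gz`) and round-trips exactly.
#'
#' @param path File path; `.gz` suffix toggles compression.
#' @param pat A PAT table.
#' @return `read_pat()` returns a PAT `data.table`; `write_pat()` returns
#'   `path` invisibly.
#' @export
read_pat <- function(path) {
  dt <- tryCatch({
    if (grepl("\\.gz$", path)) {
      con <- gzfile(path, "rt")
      on.exit(close(con), add = TRUE)
      txt <- readLines(con)
      fread(text = txt, header = FALSE, sep = "\t",
            colClasses = list(character = c(1, 3)), fill = FALSE)
    } else {
      fread(path, header = FALSE, sep = "\t",
            colClasses = list(character = c(1, 3)), fill = FALSE)
    }
  }, error = function(e) stop("malformed PAT file: ", conditionMessage(e)))
  if (ncol(dt) != 4L)
    stop("malformed PAT file: expected 4 columns, found ", ncol(dt))
  setnames(dt, c("chrom", "first_idx", "pattern", "count"))
  bad <- which(!grepl("^[CT.]+$", dt$pattern))
  if (length(bad))
    stop("malformed PAT pattern at line ", bad[1])
  bad <- which(!is.finite(dt$count) | dt$count < 1 | dt$count != round(dt$count))
  if (length(bad))
    stop("invalid PAT count at line ", bad[1])
  dt[, first_idx := as.integer(first_idx)]
  dt[, count := as.integer(count)]
  if (!pat_sorted(dt)) {
    warning("PAT file is unsorted; sorting in memory")
    sort_pat(dt)
  }
  dt[]
}

#' @rdname read_pat
#' @export
write_pat <- function(pat, path) {
  stop_if_not_pat(pat)
  fwrite(pat[, .(chrom, first_idx, pattern, count)], path, sep = "\t",
         col.names = FALSE,
         compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Write a beta track as bedGraph-like text
#'
#' Emits `chrom`, `start`, `end` (the CG dinucleotide, 0-based half-open),
#' `beta`, `coverage` for every covered CpG.
#'
#' @param beta Beta track from [pat_to_beta()].
#' @param cpgs CpG map.
#' @param path Output path (gzip when ending in `.gz`).
#' @export
write_beta_bedgraph <- function(beta, cpgs, path) {
  m <- merge(beta, cpgs, by = "idx")
  out <- m[, .(chrom, start = pos, end = pos + 2L, beta, coverage = total)]
  setorder(out, chrom, start)
  fwrite(out, path, sep = "\t", col.names = FALSE,
         compress = if (grepl("\\.gz$", path)) "gzip" else "none")
  invisible(path)
}

#' Restrict PAT records to a set of CpG indices
#'
#' Calls at CpGs outside `keep_idx` are masked to `.`, leading/trailing dots
#' are trimmed (adjusting the start index), and records left with fewer than
#' `min_cpg` informative calls are dropped. Used to confine whole-genome data
#' to the motif-flank target space.
#'
#' @param pat A PAT table.
#' @param keep_idx Integer vector of global CpG indices to retain.
#' @param min_cpg Minimum informative calls per record after masking.
#' @return A collapsed, sorted PAT table.
#' @export
restrict_pat <- function(pat, keep_idx, min_cpg = 3L) {
  stop_if_not_pat(pat)
  if (nrow(pat) == 0L) return(pat)
  keep_l <- logical(max(keep_idx, pat$first_idx + nchar(pat$pattern)))
  keep_l[keep_idx] <- TRUE
  len <- nchar(pat$pattern)
  big <- paste(pat$pattern, collapse = "")
  chars <- strsplit(big, "", fixed = TRUE)[[1]]
  cg <- rep(pat$first_idx, len) + sequence(len) - 1L
  chars[!keep_l[cg]] <- "."
  ends <- cumsum(len)
  starts <- ends - len + 1L
  masked <- stri_sub(paste(chars, collapse = ""), starts, ends)
  first_rel <- stri_locate_first_regex(masked, "[CT]")[, 1]
  last_rel <- stri_locate_last_regex(masked, "[CT]")[, 1]
  ok <- !is.na(first_rel)
  dt <- data.table(chrom = pat$chrom[ok],
                   first_idx = pat$first_idx[ok] + first_rel[ok] - 1L,
                   pattern = stri_sub(masked[ok], first_rel[ok], last_rel[ok]),
                   count = pat$count[ok])
  dt <- dt[stri_count_fixed(pattern, "C") + stri_count_fixed(pattern, "T") >= min_cpg]
  if (nrow(dt) == 0L)
    return(data.table(chrom = character(0), first_idx = integer(0),
                      pattern = character(0), count = integer(0)))
  collapse_pat(dt)
}
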