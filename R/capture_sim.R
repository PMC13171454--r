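# Fragmentation, two-adapter capture logic, read-level methylation simulation
# with conversion error, and enrichment statistics.

#' Conversion error model
#'
#' @param p_nonconversion Probability that an unmethylated cytosine escapes
#'   conversion and reads as methylated (C).
#' @param p_overconversion Probability that a methylated cytosine is converted
#'   and reads as unmethylated (T).
#' @return A list of class `"fc_conv"`.
#' @export
conversion_model <- function(p_nonconversion = 0.005, p_overconversion = 0.005) {
  stopifnot(p_nonconversion >= 0, p_nonconversion <= 1,
            p_overconversion >= 0, p_overconversion <= 1)
  structure(list(p_nonconversion = p_nonconversion,
                 p_overconversion = p_overconversion), class = "fc_conv")
}

#' Draw random genomic fragments
#'
#' Samples `n` fragments with lengths from a named model: `cfDNA`
#' (normal, mean 170 sd 20 bp), `FFPE` (uniform 100--500 bp), `sheared`
#' (normal, mean 450 sd 50 bp), or `custom` (normal with `len_mean`,
#' `len_sd`). Lengths are truncated to at least `min_len` and to chromosome
#' bounds; chromosomes are sampled proportional to length. Deterministic under
#' a fixed `seed`.
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param length_model One of `"cfDNA"`, `"FFPE"`, `"sheared"`, `"custom"`.
#' @param n Number of fragments.
#' @param seed Optional integer seed.
#' @param len_mean,len_sd Parameters for `length_model = "custom"`.
#' @param min_len Minimum fragment length (default 30 bp).
#' @param cell_type Optional source label stored with each fragment.
#' @return `data.table` with columns `chrom`, `start`, `end` (0-based
#'   half-open), `cell_type`, `frag_id`.
#' @export
fragment_genome <- function(genome, length_model = c("cfDNA", "FFPE", "sheared", "custom"),
                            n, seed = NULL, len_mean = 400, len_sd = 50,
                            min_len = 30L, cell_type = NA_character_) {
  length_model <- match.arg(length_model)
  stopifnot(n >= 0)
  empty <- data.table(chrom = character(0), start = integer(0), end = integer(0),
                      cell_type = character(0), frag_id = integer(0))
  if (n == 0L) return(empty)
  chrom_len <- Biostrings::width(genome)
  if (max(chrom_len) < min_len)
    stop("genome shorter than the minimum fragment length (", min_len, " bp)")
  draw_len <- switch(length_model,
    cfDNA   = function(k) rnorm(k, 170, 20),
    FFPE    = function(k) runif(k, 100, 500),
    sheared = function(k) rnorm(k, 450, 50),
    custom  = function(k) rnorm(k, len_mean, len_sd))
  with_seed_(seed, {
    len <- pmax(as.integer(min_len), as.integer(round(draw_len(n))))
    ok <- which(chrom_len >= min_len)
    ci <- ok[sample.int(length(ok), n, replace = TRUE, prob = chrom_len[ok])]
    L <- chrom_len[ci]
    len <- pmin(len, L)
    start <- as.integer(floor(runif(n) * (L - len + 1)))
    data.table(chrom = names(genome)[ci], start = start,
               end = start + len, cell_type = cell_type, frag_id = seq_len(n))
  })
}

#' Apply the two-adapter capture logic to fragments
#'
#' With `k` restriction cuts strictly inside a fragment, the fragment splits
#' into `k + 1` pieces. Under the one-cut (`"flexseq"`) protocol only the two
#' terminal pieces survive: each carries one free (A-adapter) end and one cut
#' (B-adapter) end; fully internal pieces have two cut ends (B+B) and uncut
#' fragments have two free ends (A+A), and both are excluded from sequencing.
#' Under `"rrbs"` exactly the opposite pieces are captured: those with two cut
#' ends. `"wgbs"` captures the intact fragment. Chromosome ends count as free
#' ends.
#'
#' @param frags Fragment table from [fragment_genome()].
#' @param sites An `fc_sites` object from [scan_motif_sites()].
#' @param protocol `"flexseq"`, `"rrbs"`, or `"wgbs"`.
#' @return `data.table` of pieces with columns `chrom`, `start`, `end`
#'   (0-based half-open), `cut_end` (which piece boundary is a cut:
#'   `"left"`, `"right"`, `"both"`, `"none"`), `cell_type`, `frag_id`.
#' @export
apply_capture <- function(frags, sites, protocol = c("flexseq", "rrbs", "wgbs")) {
  protocol <- match.arg(protocol)
  cols <- c("chrom", "start", "end", "cell_type", "frag_id")
  if (nrow(frags) == 0L ||  protocol == "wgbs") {
    out <- frags[, ..cols]
    out[, cut_end := "none"]
    return(out[])
  }
  cuts <- cut_table(sites)
  pieces <- vector("list", length(unique(frags$chrom)))
  i <- 0L
  for (ch in unique(frags$chrom)) {
    f <- frags[chrom == ch]
    cv <- sort(cuts[chrom == ch, cut])
    # number of cuts c with start < c < end  <=>  start + 1 <= c <= end - 1
    lo <- findInterval(f$start, cv)
    hi <- findInterval(f$end - 1L, cv)
    k <- hi - lo
    i <- i + 1L
    if (protocol == "flexseq") {
      f2 <- f[k >= 1L]
      l2 <- lo[k >= 1L]; h2 <- hi[k >= 1L]
      if (nrow(f2) == 0L) { pieces[[i]] <- NULL; next }
      left <- data.table(chrom = ch, start = f2$start, end = cv[l2 + 1L],
                         cut_end = "right", cell_type = f2$cell_type,
                         frag_id = f2$frag_id)
      right <- data.table(chrom = ch, start = cv[h2], end = f2$end,
                          cut_end = "left", cell_type = f2$cell_type,
                          frag_id = f2$frag_id)
      pieces[[i]] <- rbind(left, right)
    } else { # rrbs: internal pieces between consecutive cuts, k >= 2
      selr <- which(k >= 2L)
      if (length(selr) == 0L) { pieces[[i]] <- NULL; next }
      m <- k[selr] - 1L
      rep_i <- rep(selr, m)
      off <- sequence(m)
      ci <- lo[rep_i] + off
      pieces[[i]] <- data.table(chrom = ch, start = cv[ci], end = cv[ci + 1L],
                                cut_end = "both",
                                cell_type = f$cell_type[rep_i],
                                frag_id = f$frag_id[rep_i])
    }
  }
  out <- rbindlist(pieces[!vapply(pieces, is.null, logical(1))])
  if (is.null(out) || nrow(out) == 0L)
    return(data.table(chrom = character(0), start = integer(0), end = integer(0),
                      cut_end = character(0), cell_type = character(0),
                      frag_id = integer(0)))
  setorder(out, frag_id, start)
  out[]
}

# Per-chromosome CpG lookup: list(chrom -> list(pos = <0-based>, idx = <global>)).
cpg_split <- function(cpgs) {
  sp <- split(seq_len(nrow(cpgs)), cpgs$chrom)
  lapply(sp, function(rows) list(pos = cpgs$pos[rows], idx = cpgs$idx[rows]))
}

#' Simulate methylation reads from captured pieces
#'
#' Each captured piece yields one read of up to `read_len` bp starting at its
#' cut end (or, for whole-genome pieces, at the fragment's free end). Every
#' CpG whose CG dinucleotide lies in the read span receives a call drawn
#' Bernoulli from the methylome probability at that CpG, then flipped
#' according to the conversion model. Calls are duplex-level: the pattern is
#' recorded in genome orientation regardless of strand. The read's first
#' trinucleotide after conversion is recorded so that the on-target fraction
#' (reads starting C/TGG) can be computed; cut-anchored reads start at the
#' motif-internal CpG, so their prefix is `CGG` when that CpG reads methylated
#' and `TGG` otherwise.
#'
#' @param pieces Piece table from [apply_capture()].
#' @param genome A [Biostrings::DNAStringSet].
#' @param cpgs CpG map from [cpg_index_map()].
#' @param methylome Numeric vector over the global CpG index with methylation
#'   probabilities in \[0, 1\].
#' @param read_len Maximum read span in bp (default 100, roughly the span
#'   covered by a short paired-end read pair).
#' @param conv A [conversion_model()].
#' @param seed Optional integer seed.
#' @return `data.table` of reads: `chrom`, `start`, `end` (read span),
#'   `first_idx` (global index of the first called CpG; `NA` when no CpG is
#'   covered), `n_cpg`, `pattern` (string over C/T), `n_unconv` (unconverted
#'   non-CpG cytosines), `prefix` (first trinucleotide after conversion),
#'   `cell_type`, `count`.
#' @export
simulate_reads <- function(pieces, genome, cpgs, methylome, read_len = 100L,
                           conv = conversion_model(), seed = NULL) {
  stopifnot(read_len >= 1)
  if (any(!is.finite(methylome)) || any(methylome < 0 | methylome > 1))
    stop("methylome probabilities must lie in [0, 1]")
  if (nrow(pieces) == 0L)
    return(data.table(chrom = character(0), start = integer(0), end = integer(0),
                      first_idx = integer(0), n_cpg = integer(0),
                      pattern = character(0), n_unconv = integer(0),
                      prefix = character(0), cell_type = character(0),
                      count = integer(0)))
  with_seed_(seed, {
    p <- copy(pieces)
    read_len <- as.integer(read_len)
    # read span: anchored at the cut end when there is one, else at the start
    p[, `:=`(rs = start, re = end)]
    p[cut_end %in% c("left", "both"), re := pmin(end, start + read_len)]
    p[cut_end == "right", rs := pmax(start, end - read_len)]
    p[cut_end == "none", re := pmin(end, start + read_len)]

    cs <- cpg_split(cpgs)
    p[, c("lo", "hi") := {
      lk <- cs[[chrom[1]]]
      if (is.null(lk)) list(rep(1L, .N), rep(0L, .N))
      else list(findInterval(rs - 1L, lk$pos) + 1L,   # first CpG with pos >= rs
                findInterval(re - 2L, lk$pos))        # last CpG with pos <= re-2
    }, by = chrom]
    p[, n_cpg := pmax(0L, hi - lo + 1L)]
    p[, gfirst := NA_integer_]
    p[n_cpg > 0L, gfirst := {
      lk <- cs[[chrom[1]]]
      lk$idx[lo]
    }, by = chrom]

    # draw all calls at once
    n_calls <- p$n_cpg
    tot <- sum(n_calls)
    rows <- rep(seq_len(nrow(p)), n_calls)
    cg <- rep(p$gfirst, n_calls) + sequence(n_calls) - 1L
    pm <- methylome[cg]
    true_call <- rbinom(tot, 1L, pm)
    obs <- true_call
    if (conv$p_overconversion > 0)
      obs[true_call == 1L] <- 1L - rbinom(sum(true_call == 1L), 1L, conv$p_overconversion)
    if (conv$p_nonconversion > 0)
      obs[true_call == 0L] <- rbinom(sum(true_call == 0L), 1L, conv$p_nonconversion)
    chars <- c("T", "C")[obs + 1L]
    big <- paste(chars, collapse = "")
    ends <- cumsum(n_calls)
    starts <- ends - n_calls + 1L
    pat <- character(nrow(p))
    has <- n_calls > 0L
    pat[has] <- stri_sub(big, starts[has], ends[has])
    p[, pattern := pat]

    # unconverted non-CpG cytosines: total C in span minus CpG-context Cs
    p[, n_unconv := 0L]
    for (ch in unique(p$chrom)) {
      sel <- which(p$chrom == ch)
      sq <- genome[[ch]]
      v <- Biostrings::Views(sq, start = p$rs[sel] + 1L, end = p$re[sel])
      totC <- as.integer(Biostrings::letterFrequency(v, "C"))
      lk <- cs[[ch]]
      ncg <- if (is.null(lk)) 0L else
        findInterval(p$re[sel] - 1L, lk$pos) - findInterval(p$rs[sel] - 1L, lk$pos)
      non <- pmax(0L, totC - ncg)
      p$n_unconv[sel] <- rbinom(length(sel), non, conv$p_nonconversion)
    }

    p[, prefix := "NNN"]
    # cut at the left read end: first call is the motif-internal CpG
    p[cut_end %in% c("left", "both") & n_cpg > 0L,
      prefix := ifelse(stri_sub(pattern, 1L, 1L) == "C", "CGG", "TGG")]
    # pieces too short to cover a full CpG call still read through the cut
    # site: draw the motif CpG state directly
    sel <- which(p$cut_end %in% c("left", "both") & p$n_cpg == 0L)
    if (length(sel)) {
      pr <- numeric(length(sel))
      for (ch in unique(p$chrom[sel])) {
        ss <- which(p$chrom[sel] == ch)
        lk <- cs[[ch]]
        if (is.null(lk)) next
        at <- p$rs[sel][ss]
        k <- pmax(findInterval(at, lk$pos), 1L)
        hit <- lk$pos[k] == at
        pr[ss[hit]] <- methylome[lk$idx[k[hit]]]
      }
      obs_s <- rbinom(length(sel), 1L, pr)
      flip1 <- rbinom(length(sel), 1L, conv$p_overconversion)
      flip0 <- rbinom(length(sel), 1L, conv$p_nonconversion)
      obs_s <- ifelse(obs_s == 1L, 1L - flip1, flip0)
      p$prefix[sel] <- c("TGG", "CGG")[obs_s + 1L]
    }
    # cut at the right: the motif CpG sits just outside the piece; draw its state
    sel <- which(p$cut_end == "right")
    if (length(sel)) {
      pr <- numeric(length(sel))
      for (ch in unique(p$chrom[sel])) {
        ss <- which(p$chrom[sel] == ch)
        lk <- cs[[ch]]
        if (is.null(lk)) next
        at <- p$re[sel][ss]
        k <- pmax(findInterval(at, lk$pos), 1L)
        hit <- lk$pos[k] == at
        pr[ss[hit]] <- methylome[lk$idx[k[hit]]]
      }
      state <- rbinom(length(sel), 1L, pr)
      ov <- rbinom(length(sel), 1L, conv$p_overconversion)
      nc <- rbinom(length(sel), 1L, conv$p_nonconversion)
      obs_s <- ifelse(state == 1L, 1L - ov, nc)
      p$prefix[sel] <- c("TGG", "CGG")[obs_s + 1L]
    }
    # free-end reads: take the genomic trinucleotide and convert it
    sel <- which(p$cut_end == "none")
    if (length(sel)) p$prefix[sel] <- converted_prefix(p[sel], genome, cs, methylome, conv)

    out <- p[, .(chrom, start = rs, end = re, first_idx = gfirst, n_cpg,
                 pattern, n_unconv, prefix, cell_type, count = 1L)]
    out[]
  })
}

# First trinucleotide of free-end reads after conversion, fully vectorized.
# Position 1 reuses the read's first CpG call when the read starts on a CpG;
# other cytosines convert to T unless they sit on a CpG, in which case their
# state is drawn from the methylome; non-CpG cytosines survive conversion
# with probability p_nonconversion.
converted_prefix <- function(pp, genome, cs, methylome, conv) {
  n <- nrow(pp)
  res_k <- matrix("", n, 3L)
  for (ch in unique(pp$chrom)) {
    sel <- which(pp$chrom == ch)
    sq <- genome[[ch]]
    L <- length(sq)
    e3 <- pmin(pp$rs[sel] + 3L, L)
    tri <- as.character(Biostrings::Views(sq, start = pp$rs[sel] + 1L, end = e3))
    lk <- cs[[ch]]
    poss <- if (is.null(lk)) integer(0) else lk$pos
    for (k in 1:3) {
      b <- stri_sub(tri, k, k)
      isC <- b == "C" & !is.na(b)
      if (any(isC)) {
        at <- pp$rs[sel[isC]] + k - 1L
        if (length(poss)) {
          ii <- pmax(findInterval(at, poss), 1L)
          is_cpg <- poss[ii] == at
        } else {
          ii <- rep(1L, length(at))
          is_cpg <- rep(FALSE, length(at))
        }
        pmeth <- ifelse(is_cpg, methylome[lk$idx[ii]], conv$p_nonconversion)
        call <- c("T", "C")[rbinom(length(at), 1L, pmeth) + 1L]
        if (k == 1L) {
          # reuse the recorded first call where the read starts on a CpG
          own <- is_cpg & pp$n_cpg[sel[isC]] > 0L
          call[own] <- stri_sub(pp$pattern[sel[isC]][own], 1L, 1L)
        }
        b[isC] <- call
      }
      res_k[sel, k] <- ifelse(is.na(b), "", b)
    }
  }
  paste0(res_k[, 1], res_k[, 2], res_k[, 3])
}

#' On-target rate of a read set
#'
#' Fraction of reads whose first three bases after conversion are `CGG` or
#' `TGG`, i.e. reads anchored at a cut site.
#'
#' @param reads Read table from [simulate_reads()].
#' @return A single fraction; `NA` with a message for an empty read set.
#' @export
on_target_rate <- function(reads) {
  if (nrow(reads) == 0L) {
    message("on_target_rate: empty read set, rate undefined")
    return(NA_real_)
  }
  mean(reads$prefix %in% c("CGG", "TGG"))
}

#' Filter reads with too many unconverted non-CpG cytosines
#'
#' Incomplete conversion affects whole molecules, so reads carrying more than
#' `max_unconverted` unconverted cytosines outside CpG context are removed.
#'
#' @param reads Read table.
#' @param max_unconverted Maximum tolerated unconverted non-CpG cytosines
#'   (default 3).
#' @return Filtered read table; the removed fraction is attached as
#'   `attr(, "filter_rate")`.
#' @export
filter_non_conversion <- function(reads, max_unconverted = 3L) {
  stopifnot(max_unconverted >= 0)
  keep <- reads$n_unconv <= max_unconverted
  out <- reads[keep]
  setattr(out, "filter_rate", if (nrow(reads)) mean(!keep) else 0)
  out
}

# per-CpG call coverage of a read/PAT-like table, restricted to `target_idx`
call_coverage <- function(tbl, target_idx) {
  t2 <- tbl[n_cpg > 0L]
  if (nrow(t2) == 0L) return(integer(0))
  cg <- rep(t2$first_idx, t2$n_cpg) + sequence(t2$n_cpg) - 1L
  w <- rep(t2$count, t2$n_cpg)
  agg <- data.table(cg = cg, w = w)[cg %in% target_idx, .(cov = sum(w)), by = cg]
  stats::setNames(agg$cov, agg$cg)
}

#' Compare target enrichment of two read sets at a fixed base budget
#'
#' Both read sets are subsampled (uniformly, without replacement, seeded) to
#' the same number of sequenced bases; CpGs inside `targets` with call
#' coverage at least `min_cov` are counted for each. The fold requirement is
#' the ratio of base budgets the two methods need to reach the same covered
#' CpG count, interpolated from nested subsampling curves.
#'
#' @param readsA,readsB Read tables from [simulate_reads()].
#' @param targets Target [GenomicRanges::GRanges].
#' @param cpgs CpG map.
#' @param min_cov Minimum per-CpG coverage (default 10).
#' @param budget_bases Base budget applied to both sets.
#' @param seed Optional seed for the subsampling permutation.
#' @param fractions Subsample fractions for the coverage curves.
#' @return List with `cpgs_ge_cov` (named counts for A and B) and
#'   `fold_requirement` (bases B needs / bases A needs).
#' @export
enrichment_stats <- function(readsA, readsB, targets, cpgs, min_cov = 10,
                             budget_bases, seed = NULL,
                             fractions = seq(0.1, 1, by = 0.1)) {
  target_idx <- cpgs_in_regions(cpgs, targets)
  curve <- function(reads, perm_seed) {
    bases <- reads$end - reads$start
    if (sum(bases) < budget_bases)
      stop("base budget exceeds available bases (", sum(bases), " < ",
           budget_bases, ")")
    ord <- with_seed_(perm_seed, sample.int(nrow(reads)))
    cb <- cumsum(bases[ord])
    counts <- vapply(fractions, function(f) {
      take <- ord[cb <= budget_bases * f]
      cov <- call_coverage(reads[take], target_idx)
      sum(cov >= min_cov)
    }, numeric(1))
    data.table(bases = budget_bases * fractions, count = counts)
  }
  cvA <- curve(readsA, seed)
  cvB <- curve(readsB, seed)
  nA <- cvA$count[nrow(cvA)]
  nB <- cvB$count[nrow(cvB)]
  tgt <- min(nA, nB)
  need <- function(cv) {
    if (tgt <= 0) return(NA_real_)
    if (max(cv$count) < tgt) return(NA_real_)
    if (all(cv$count == tgt)) return(min(cv$bases))
    approx(x = cv$count, y = cv$bases, xout = tgt, ties = min)$y
  }
  fold <- need(cvB) / need(cvA)
  list(cpgs_ge_cov = c(A = nA, B = nB), fold_requirement = fold,
       curves = list(A = cvA, B = cvB))
}
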