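# Z-score normalization of deconvolved proportions against a reference
# population, cell-of-origin classification calls, and evaluation metrics.

#' Z-score profile of a sample against a reference population
#'
#' For each cell type, z = (x - mu) / sigma where mu and sigma are the mean
#' and sample standard deviation (denominator n - 1) of the cell-type
#' proportion in the reference population (negative controls or non-target
#' cases). Cell types with sigma = 0 get an undefined z and are excluded from
#' ranking with a warning, as are configured background cell types. Ranking is
#' by z descending; ties break by raw proportion, then name.
#'
#' @param x Named numeric vector of the sample's cell-type proportions.
#' @param reference Matrix or data.frame of reference proportions (rows =
#'   reference samples, columns = cell types matching `names(x)`).
#' @param exclude_background Cell types excluded from ranking (but still
#'   reported).
#' @return `data.table` of class `"fc_zprofile"`: `cell_type`, `proportion`,
#'   `mu`, `sigma`, `z`, `eligible`, `rank` (`NA` for ineligible types).
#' @export
zscores <- function(x, reference, exclude_background = character()) {
  reference <- as.matrix(reference)
  if (nrow(reference) < 2L)
    stop("reference population must contain at least 2 samples")
  types <- names(x)
  stopifnot(!is.null(types), all(types %in% colnames(reference)))
  mu <- colMeans(reference[, types, drop = FALSE])
  sigma <- apply(reference[, types, drop = FALSE], 2, sd)
  z <- (x - mu) / sigma
  z[sigma == 0] <- NA_real_
  if (any(sigma == 0))
    warning("constant reference for: ",
            paste(types[sigma == 0], collapse = ", "),
            " -- z undefined, excluded from ranking")
  out <- data.table(cell_type = types, proportion = as.numeric(x),
                    mu = as.numeric(mu), sigma = as.numeric(sigma),
                    z = as.numeric(z),
                    eligible = !(types %in% exclude_background) & !is.na(z))
  ord <- order(-out$z, -out$proportion, out$cell_type, na.last = TRUE)
  rk <- rep(NA_integer_, nrow(out))
  el <- ord[out$eligible[ord]]
  rk[el] <- seq_along(el)
  out[, rank := rk]
  setattr(out, "class", c("fc_zprofile", class(out)))
  out[]
}

#' Flag extreme-low outliers
#'
#' Flags values below the extreme lower fence Q1 - 3*IQR, with quartiles by
#' linear interpolation (`quantile()` type 7 by default). Only the lower
#' fence is used; large values are never flagged. With IQR = 0 any value
#' strictly below Q1 is flagged.
#'
#' @param values Numeric vector to flag.
#' @param reference Values the quartiles are computed from (default:
#'   `values` itself), length at least 4.
#' @param type Quantile method passed to [stats::quantile()].
#' @return Logical vector of flags, with the fence attached as
#'   `attr(, "fence")`.
#' @export
flag_extreme_low <- function(values, reference = values, type = 7) {
  stopifnot(length(reference) >= 4L)
  q1 <- quantile(reference, 0.25, type = type, names = FALSE)
  q3 <- quantile(reference, 0.75, type = type, names = FALSE)
  out <- values < q1 - 3 * (q3 - q1)
  attr(out, "fence") <- q1 - 3 * (q3 - q1)
  out
}

#' Cell-of-origin classification call
#'
#' The top-ranked eligible cell type qualifies when its z-score exceeds
#' `z_threshold` and it is associated with a tumor type in `coo_map`. A
#' qualifying leader matching the gold-standard tumor type gives `Matched`; a
#' different tumor type gives `Misleading profile`. No qualifying leader, or a
#' leading cell type in `indeterminate_types`, gives `Indeterminate`.
#' Reference samples are labeled `Reference` and samples without a usable gold
#' standard `N/a`.
#'
#' @param profile An `fc_zprofile` from [zscores()].
#' @param coo_map Named character vector: cell type -> tumor type.
#' @param gold Gold-standard tumor type (NA allowed for excluded samples).
#' @param z_threshold Z-score the leader must exceed (strict, default 2).
#' @param indeterminate_types Cell types that force an Indeterminate call
#'   when leading (default `"oligodendrocyte"`).
#' @param is_reference Whether this sample was used to build the reference
#'   population.
#' @return One-row `data.table`: `category`, `leading`, `leading_z`, `gold`.
#' @export
classify_coo <- function(profile, coo_map, gold, z_threshold = 2,
                         indeterminate_types = "oligodendrocyte",
                         is_reference = FALSE) {
  mk <- function(category, leading = NA_character_, z = NA_real_)
    data.table(category = category, leading = leading, leading_z = z,
               gold = if (is.null(gold)) NA_character_ else as.character(gold))
  if (isTRUE(is_reference)) return(mk("Reference"))
  if (is.null(gold) || is.na(gold)) {
    warning("gold standard missing for a non-reference sample; labeled N/a")
    return(mk("N/a"))
  }
  lead <- profile[!is.na(rank) & rank == 1L]
  if (nrow(lead) == 0L) return(mk("Indeterminate"))
  if (lead$cell_type %in% indeterminate_types)
    return(mk("Indeterminate", lead$cell_type, lead$z))
  if (lead$z > z_threshold && lead$cell_type %in% names(coo_map)) {
    cat_ <- if (coo_map[[lead$cell_type]] == gold) "Matched" else "Misleading profile"
    return(mk(cat_, lead$cell_type, lead$z))
  }
  mk("Indeterminate", lead$cell_type, lead$z)
}

# Rank-statistic AUC with ties averaged (equivalent to the Mann-Whitney U
# normalization).
auc_rank <- function(score, positive) {
  ok <- !is.na(score) & !is.na(positive)
  score <- score[ok]; positive <- as.logical(positive[ok])
  n1 <- sum(positive); n0 <- sum(!positive)
  if (n1 == 0L || n0 == 0L) return(NA_real_)
  r <- rank(score, ties.method = "average")
  (sum(r[positive]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Evaluate classification calls
#'
#' Accuracy is `Matched / (Matched + Misleading profile)`, i.e. indeterminate
#' calls are excluded. The confusion matrix tabulates gold tumor type against
#' the called tumor type (or `Indeterminate`). Per-class AUC uses the
#' rank-statistic estimator with ties averaged on the supplied scores.
#'
#' @param calls `data.table` of stacked [classify_coo()] rows.
#' @param coo_map Cell type -> tumor type map used for the calls.
#' @param scores Optional matrix of per-sample scores (rows = samples aligned
#'   with `calls`, columns = tumor classes), typically the z-score of each
#'   class's cell of origin.
#' @return List with `accuracy`, `n_matched`, `n_misleading`,
#'   `n_indeterminate`, `confusion`, and `auc` (named per class, or `NULL`).
#' @export
evaluate_calls <- function(calls, coo_map, scores = NULL) {
  tab <- table(calls$category)
  n_m <- sum(calls$category == "Matched")
  n_w <- sum(calls$category == "Misleading profile")
  n_i <- sum(calls$category == "Indeterminate")
  acc <- if (n_m + n_w > 0L) n_m / (n_m + n_w) else NA_real_
  predicted <- ifelse(calls$category %in% c("Matched", "Misleading profile"),
                      unname(coo_map[calls$leading]), calls$category)
  conf <- table(gold = calls$gold, predicted = predicted)
  auc <- NULL
  if (!is.null(scores)) {
    scores <- as.matrix(scores)
    auc <- vapply(colnames(scores), function(cl)
      auc_rank(scores[, cl], calls$gold == cl), numeric(1))
    if (sum(!is.na(calls$gold)) > 0L &&
        length(unique(stats::na.omit(calls$gold))) < 2L &&
        all(is.na(auc)))
      warning("AUC undefined: fewer than two classes present")
  }
  list(accuracy = acc, n_matched = n_m, n_misleading = n_w,
       n_indeterminate = n_i, confusion = conf, auc = auc)
}
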