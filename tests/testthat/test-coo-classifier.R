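ref3 <- matrix(c(0.01, 0.02, 0.03, 0.10, 0.10, 0.10),
               ncol = 2, dimnames = list(NULL, c("lung", "bcell")))

test_that("z-scores use the reference mean and sample SD, with ranking rules", {
  zp <- suppressWarnings(zscores(c(lung = 0.04, bcell = 0.10), ref3))
  expect_equal(zp[cell_type == "lung", z], 2)       # (0.04-0.02)/0.01
  expect_equal(zp[cell_type == "bcell", z], NA_real_) # constant reference
  expect_warning(zscores(c(lung = 0.04, bcell = 0.10), ref3), "constant")
  expect_equal(zp[cell_type == "lung", rank], 1L)
  expect_true(is.na(zp[cell_type == "bcell", rank]))
  z0 <- suppressWarnings(zscores(c(lung = 0.02, bcell = 0.1), ref3))
  expect_equal(z0[cell_type == "lung", z], 0)
  # excluded background types are reported but never ranked
  ref2 <- matrix(runif(8), ncol = 2, dimnames = list(NULL, c("lung", "endo")))
  zx <- zscores(c(lung = 0.5, endo = 0.9), ref2,
                exclude_background = "endo")
  expect_true(is.na(zx[cell_type == "endo", rank]))
  expect_error(zscores(c(lung = 1), ref3[1, , drop = FALSE]), "at least 2")
})

test_that("z-scores are invariant to shifting a cell type by a constant", {
  ref <- matrix(runif(20), ncol = 2, dimnames = list(NULL, c("a", "b")))
  x <- c(a = 0.4, b = 0.2)
  z1 <- zscores(x, ref)
  ref_s <- ref; ref_s[, "a"] <- ref_s[, "a"] + 5
  x_s <- x; x_s["a"] <- x_s["a"] + 5
  z2 <- zscores(x_s, ref_s)
  expect_equal(z1$z, z2$z, tolerance = 1e-12)
})

test_that("extreme-low fence flags only small outliers", {
  # {1,2,3,4,5}: Q1 = 2, IQR = 2, fence = -4; -5 is below it, -3 is not
  fl <- flag_extreme_low(c(-5, -3), reference = c(1, 2, 3, 4, 5))
  expect_equal(attr(fl, "fence"), -4)
  expect_equal(as.logical(fl), c(TRUE, FALSE))
  expect_equal(as.logical(flag_extreme_low(c(1, 2, 3, 4, 5))), rep(FALSE, 5))
  # zero IQR: anything strictly below Q1 is an outlier
  expect_equal(as.logical(flag_extreme_low(c(2, 2, 2, 2, 1.9))),
               c(rep(FALSE, 4), TRUE))
  # large values never flagged (lower fence only)
  expect_equal(as.logical(flag_extreme_low(c(1, 2, 3, 4, 1e6))), rep(FALSE, 5))
  expect_error(flag_extreme_low(c(1, 2, 3)), "length")
})

mk_profile <- function(z, prop = NULL) {
  types <- names(z)
  if (is.null(prop)) prop <- rep(0.1, length(z))
  out <- data.table(cell_type = types, proportion = prop, mu = 0, sigma = 1,
                    z = as.numeric(z), eligible = TRUE)
  ord <- order(-out$z, -out$proportion, out$cell_type)
  out[ord, rank := seq_len(.N)]
  out
}

coo <- c(lung = "LUAD", bcell = "DLBC")

test_that("classification categories follow the qualification rules", {
  expect_equal(classify_coo(mk_profile(c(lung = 5, bcell = 1)), coo,
                            "LUAD")$category, "Matched")
  expect_equal(classify_coo(mk_profile(c(lung = 5, bcell = 1)), coo,
                            "DLBC")$category, "Misleading profile")
  expect_equal(classify_coo(mk_profile(c(lung = 1.5, bcell = 1)), coo,
                            "LUAD")$category, "Indeterminate")
  # strict threshold: z exactly 2 does not qualify
  expect_equal(classify_coo(mk_profile(c(lung = 2, bcell = 1)), coo,
                            "LUAD")$category, "Indeterminate")
  # leading type without a COO association -> no qualifying leader
  expect_equal(classify_coo(mk_profile(c(oligo = 9, lung = 5)), coo, "LUAD",
                            indeterminate_types = character(0))$category,
               "Indeterminate")
  expect_equal(classify_coo(mk_profile(c(oligo = 9, lung = 5)), coo, "LUAD",
                            indeterminate_types = "oligo")$category,
               "Indeterminate")
  expect_equal(classify_coo(mk_profile(c(lung = 5)), coo, "LUAD",
                            is_reference = TRUE)$category, "Reference")
  expect_warning(na_call <- classify_coo(mk_profile(c(lung = 5)), coo,
                                         NA_character_), "gold")
  expect_equal(na_call$category, "N/a")
})

test_that("evaluation reports accuracy excluding indeterminates and rank AUC", {
  calls <- rbindlist(list(
    classify_coo(mk_profile(c(lung = 5, bcell = 0)), coo, "LUAD"),
    classify_coo(mk_profile(c(lung = 4, bcell = 0)), coo, "LUAD"),
    classify_coo(mk_profile(c(bcell = 6, lung = 0)), coo, "DLBC"),
    classify_coo(mk_profile(c(bcell = 3, lung = 0)), coo, "LUAD"),
    classify_coo(mk_profile(c(lung = 1, bcell = 0)), coo, "LUAD")))
  scores <- cbind(LUAD = c(5, 4, 0, 2, 1), DLBC = c(0, 0, 6, 3, 0))
  ev <- evaluate_calls(calls, coo, scores)
  expect_equal(ev$accuracy, 0.75)                  # 3 matched, 1 misleading
  expect_equal(ev$n_indeterminate, 1L)
  expect_equal(unname(ev$auc["LUAD"]), 1)          # perfect separation
  # all matched -> accuracy 1
  all_m <- calls[category == "Matched"]
  expect_equal(evaluate_calls(all_m, coo)$accuracy, 1)
})

test_that("the rank AUC agrees with pROC on random scores", {
  skip_if_not_installed("pROC")
  withr::with_seed(99L, {
    for (i in 1:5) {
      score <- rnorm(40)
      lab <- sample(c(TRUE, FALSE), 40, TRUE)
      ours <- flankcapture:::auc_rank(score, lab)
      ref <- as.numeric(pROC::auc(pROC::roc(lab, score, quiet = TRUE,
                                            direction = "<")))
      expect_equal(ours, ref, tolerance = 1e-10)
    }
  })
})
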