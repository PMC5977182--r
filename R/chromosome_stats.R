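# X/A median-ratio statistics, rank-sum comparison and the counterfactual
# dosage-correction transform.

#' Two-sided rank-sum comparison of two expression samples
#'
#' Mann-Whitney/Wilcoxon rank-sum test as used for every X-vs-A comparison in
#' the pipeline. Uses the exact null distribution when both samples are small
#' (`min(n) <= exact_limit`) and tie-free, and the normal approximation with
#' midranks and tie-corrected variance otherwise. The continuity correction is
#' off by default so that identical samples give p = 1 exactly.
#'
#' @param x,y Numeric samples.
#' @param exact_limit Largest `min(length(x), length(y))` for which the exact
#'   distribution is used (ties permitting). Default 50.
#' @param correct Apply the normal-approximation continuity correction.
#' @return Two-sided p-value in `[0, 1]`.
#' @export
rank_sum_test <- function(x, y, exact_limit = 50, correct = FALSE) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  pooled <- c(x, y)
  if (length(unique(pooled)) == 1L) {
    warning("degenerate data: all values identical in both groups; p = 1")
    return(1)
  }
  ties <- anyDuplicated(pooled) > 0
  use_exact <- !ties && min(length(x), length(y)) <= exact_limit
  ht <- suppressWarnings(stats::wilcox.test(
    x, y, alternative = "two.sided", exact = use_exact, correct = correct))
  unname(ht$p.value)
}

#' Compare X-linked and autosomal expression distributions
#'
#' Two-sided rank-sum p-value for the X vs A partitions of a tissue table.
#'
#' @param table A `tissue_table`.
#' @inheritParams rank_sum_test
#' @return Two-sided p-value.
#' @export
compare_xa_expression <- function(table, exact_limit = 50, correct = FALSE) {
  x <- table$mean_fpkm[table$chromosome_class == "X"]
  a <- table$mean_fpkm[table$chromosome_class == "A"]
  if (!length(x) || !length(a)) stop("empty partition", call. = FALSE)
  rank_sum_test(x, a, exact_limit = exact_limit, correct = correct)
}

#' X-to-autosome median expression ratio
#'
#' Computes the median FPKM of the X and autosomal partitions, their ratio,
#' and the rank-sum p-value for the distributional comparison — one row of the
#' per-tissue summary tables. Medians and the ratio are kept unrounded
#' internally; `format()` rounds to two decimals for reporting.
#'
#' @param table A `tissue_table`.
#' @inheritParams rank_sum_test
#' @return An object of class `ratio_result`: list with `tissue`, `sex`,
#'   `n_x`, `median_x`, `n_a`, `median_a`, `xa_ratio`, `p_value`.
#' @export
median_xa_ratio <- function(table, exact_limit = 50, correct = FALSE) {
  x <- table$mean_fpkm[table$chromosome_class == "X"]
  a <- table$mean_fpkm[table$chromosome_class == "A"]
  if (!length(x) || !length(a)) stop("empty partition", call. = FALSE)
  res <- list(
    tissue = attr(table, "tissue"),
    sex = attr(table, "sex"),
    n_x = length(x),
    median_x = stats::median(x),
    n_a = length(a),
    median_a = stats::median(a),
    xa_ratio = stats::median(x) / stats::median(a),
    p_value = compare_xa_expression(table, exact_limit = exact_limit,
                                    correct = correct)
  )
  class(res) <- "ratio_result"
  res
}

#' @export
format.ratio_result <- function(x, digits = 2, ...) {
  data.frame(
    Tissue = x$tissue %||% NA_character_,
    Sex = x$sex %||% NA_character_,
    X_Genes = x$n_x,
    X_Median = round(x$median_x, digits),
    A_Genes = x$n_a,
    A_Median = round(x$median_a, digits),
    XA = round(x$xa_ratio, digits),
    p = signif(x$p_value, 2),
    stringsAsFactors = FALSE
  )
}

#' @export
print.ratio_result <- function(x, ...) {
  print(format(x), row.names = FALSE)
  invisible(x)
}

#' Dosage correction factor from an X/A ratio
#'
#' The inverse of the median X-to-autosome ratio, used to artificially restore
#' two-dose-equivalent expression to X-linked genes in a tissue lacking
#' dosage compensation. Computed from the unrounded ratio; round the result
#' for reporting.
#'
#' @param ratio A `ratio_result` or a positive numeric ratio.
#' @return The correction factor `1 / ratio`.
#' @export
correction_factor <- function(ratio) {
  r <- if (inherits(ratio, "ratio_result")) ratio$xa_ratio else ratio
  if (!is.numeric(r) || length(r) != 1 || !is.finite(r) || r <= 0) {
    stop("ratio must be a single positive number", call. = FALSE)
  }
  1 / r
}

#' Apply a counterfactual dosage correction to the X partition
#'
#' Multiplies every X-linked mean FPKM by `factor`, leaving autosomal genes
#' unchanged. The FPKM filters are deliberately not re-applied: the correction
#' is a counterfactual transform of the gene set already under analysis.
#'
#' @param table A `tissue_table`.
#' @param factor Positive multiplier (e.g. the inverse X/A ratio).
#' @return A `tissue_table` with corrected X expression; a
#'   `dosage_correction` attribute records the factor.
#' @export
dosage_correction <- function(table, factor) {
  if (!is.numeric(factor) || length(factor) != 1 || !is.finite(factor) ||
      factor <= 0) {
    stop("factor must be a single positive number", call. = FALSE)
  }
  out <- table
  is_x <- out$chromosome_class == "X"
  out$mean_fpkm[is_x] <- out$mean_fpkm[is_x] * factor
  attr(out, "dosage_correction") <- factor
  out
}

#' X/A ratio table across tissue/sex strata
#'
#' Convenience wrapper running [build_tissue_table()] and [median_xa_ratio()]
#' for every tissue/sex combination present in the records, reproducing the
#' layout of the per-tissue summary tables (Tissue, X Genes, X Median,
#' A Genes, A Median, X/A, p).
#'
#' @param records Expression records.
#' @inheritParams build_tissue_table
#' @param digits Rounding used in the returned display columns.
#' @return Data.frame with one row per stratum plus unrounded `xa_ratio_raw`.
#' @export
xa_ratio_table <- function(records, min_fpkm = 1, max_fpkm = NULL,
                           x_labels = fly_x_labels(),
                           autosome_labels = fly_autosome_labels(),
                           digits = 2) {
  strata <- unique(records[, c("tissue", "sex")])
  strata <- strata[order(strata$sex, strata$tissue), , drop = FALSE]
  rows <- lapply(seq_len(nrow(strata)), function(i) {
    tab <- build_tissue_table(records, tissue = strata$tissue[i],
                              sex = strata$sex[i], min_fpkm = min_fpkm,
                              max_fpkm = max_fpkm, x_labels = x_labels,
                              autosome_labels = autosome_labels)
    rr <- median_xa_ratio(tab)
    cbind(format(rr, digits = digits), xa_ratio_raw = rr$xa_ratio)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
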