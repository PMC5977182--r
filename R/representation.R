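# Over/under-representation of X-linked genes within cumulative expression
# categories, tested against a genome-derived expected proportion.

#' Expected proportion of X-linked genes in the genome
#'
#' The null proportion for the representation tests: the fraction of X-linked
#' genes among all distinct X-linked and autosomal genes in the entire,
#' unfiltered dataset (not the per-tissue filtered gene set).
#'
#' @param records Expression records or any data.frame with `gene_id` and
#'   `chromosome` columns.
#' @param x_labels,autosome_labels Chromosome label sets defining the classes.
#' @return Proportion in (0, 1).
#' @export
expected_x_proportion <- function(records,
                                  x_labels = fly_x_labels(),
                                  autosome_labels = fly_autosome_labels()) {
  genes <- unique(records[, c("gene_id", "chromosome")])
  n_x <- sum(genes$chromosome %in% x_labels)
  n_a <- sum(genes$chromosome %in% autosome_labels)
  if (n_x == 0 || n_a == 0) {
    stop("need at least one X-linked and one autosomal gene", call. = FALSE)
  }
  n_x / (n_x + n_a)
}

#' Cumulative expression category counts
#'
#' For each threshold t, counts the genes with mean FPKM >= t (all genes and
#' X-linked genes). Categories are nested across the ascending grid, not
#' disjoint bins.
#'
#' @param table A `tissue_table`.
#' @param thresholds Ascending numeric FPKM thresholds.
#' @return Data.frame with `threshold`, `n_x_obs`, `n_total`.
#' @export
categorize_cumulative <- function(table, thresholds = default_threshold_grid()) {
  if (is.unsorted(thresholds, strictly = TRUE)) {
    stop("thresholds must be strictly ascending", call. = FALSE)
  }
  is_x <- table$chromosome_class == "X"
  data.frame(
    threshold = thresholds,
    n_x_obs = vapply(thresholds,
                     function(t) sum(is_x & table$mean_fpkm >= t), integer(1)),
    n_total = vapply(thresholds,
                     function(t) sum(table$mean_fpkm >= t), integer(1))
  )
}

#' Goodness-of-fit test of X-linked representation in one category
#'
#' One-degree-of-freedom chi-square goodness-of-fit test of the observed
#' X/autosome split in a category against the expected proportion, without
#' continuity correction. The direction is `"under"` (`"over"`) when the
#' observed X count falls below (above) expectation and the p-value is below
#' `alpha`; `"none"` otherwise. Categories whose smaller expected count falls
#' below `min_expected` are flagged `low_expectation` (the statistic is still
#' computed).
#'
#' @param n_x_obs Observed X-linked gene count.
#' @param n_total Total genes in the category.
#' @param expected_proportion Null proportion of X-linked genes, in (0, 1).
#' @param alpha Significance level for the direction call. Default 0.05.
#' @param min_expected Minimum expected count below which the result is
#'   flagged. Default 5.
#' @return One-row data.frame: `threshold` (NA here; filled by
#'   [representation_profile()]), `n_x_obs`, `n_total`, `expected_proportion`,
#'   `chi2_stat`, `p_value`, `direction`, `low_expectation`.
#' @export
representation_test <- function(n_x_obs, n_total, expected_proportion,
                                alpha = 0.05, min_expected = 5) {
  stopifnot(n_total >= 1, n_x_obs >= 0, n_x_obs <= n_total,
            expected_proportion > 0, expected_proportion < 1)
  expected <- n_total * c(expected_proportion, 1 - expected_proportion)
  ht <- suppressWarnings(stats::chisq.test(
    c(n_x_obs, n_total - n_x_obs),
    p = c(expected_proportion, 1 - expected_proportion),
    correct = FALSE))
  p <- unname(ht$p.value)
  stat <- unname(ht$statistic)
  direction <- "none"
  if (p < alpha && n_x_obs < expected[1]) direction <- "under"
  if (p < alpha && n_x_obs > expected[1]) direction <- "over"
  data.frame(
    threshold = NA_real_,
    n_x_obs = n_x_obs,
    n_total = n_total,
    expected_proportion = expected_proportion,
    chi2_stat = stat,
    p_value = p,
    direction = direction,
    low_expectation = min(expected) < min_expected,
    stringsAsFactors = FALSE
  )
}

significance_stars <- function(p) {
  ifelse(is.na(p), "",
         ifelse(p < 0.001, "***",
                ifelse(p < 0.01, "**",
                       ifelse(p < 0.05, "*", ""))))
}

#' Representation profile across an expression threshold grid
#'
#' Runs [representation_test()] in every cumulative expression category,
#' optionally after applying a dosage correction to the X partition
#' (the counterfactual reanalysis; filters are not re-applied). Empty
#' categories yield counts (0, 0) with NA statistics. Per-category
#' significance stars mirror the conventional 0.05/0.01/0.001 levels; an
#' optional Bonferroni adjustment across the grid is off by default.
#'
#' @param table A `tissue_table`.
#' @param thresholds Ascending FPKM thresholds.
#' @param expected_proportion Null X proportion (see
#'   [expected_x_proportion()]).
#' @param correction_factor If non-`NULL`, X expression is multiplied by this
#'   factor before categorization.
#' @inheritParams representation_test
#' @param bonferroni Adjust p-values for the number of tested categories
#'   before calling direction/stars.
#' @return Data.frame with one row per threshold: counts, `chi2_stat`,
#'   `p_value`, `direction`, `stars`, `low_expectation`.
#' @export
representation_profile <- function(table, thresholds = default_threshold_grid(),
                                   expected_proportion,
                                   correction_factor = NULL,
                                   alpha = 0.05, min_expected = 5,
                                   bonferroni = FALSE) {
  if (!is.null(correction_factor)) {
    table <- dosage_correction(table, correction_factor)
  }
  counts <- categorize_cumulative(table, thresholds)
  rows <- lapply(seq_len(nrow(counts)), function(i) {
    if (counts$n_total[i] == 0) {
      return(data.frame(threshold = counts$threshold[i], n_x_obs = 0L,
                        n_total = 0L,
                        expected_proportion = expected_proportion,
                        chi2_stat = NA_real_, p_value = NA_real_,
                        direction = "none", low_expectation = TRUE,
                        stringsAsFactors = FALSE))
    }
    r <- representation_test(counts$n_x_obs[i], counts$n_total[i],
                             expected_proportion, alpha = alpha,
                             min_expected = min_expected)
    r$threshold <- counts$threshold[i]
    r
  })
  out <- do.call(rbind, rows)
  if (bonferroni) {
    m <- sum(!is.na(out$p_value))
    out$p_value <- pmin(1, out$p_value * m)
    expected <- out$n_total * out$expected_proportion
    out$direction <- ifelse(
      !is.na(out$p_value) & out$p_value < alpha,
      ifelse(out$n_x_obs < expected, "under",
             ifelse(out$n_x_obs > expected, "over", "none")),
      "none")
  }
  out$stars <- significance_stars(out$p_value)
  rownames(out) <- NULL
  out
}
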