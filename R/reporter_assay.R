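# Aggregation of hierarchical reporter-gene activity assays
# (line -> biological replicate -> technical replicate), X-vs-A comparison of
# line means, and the suppression-vs-expression regression.

#' Read a reporter assay table
#'
#' Reads a CSV or TSV of beta-galactosidase activity measurements with columns
#' `line_id`, `chromosome_class` (`X`, `A` or `control`), `tissue`,
#' `bio_rep`, `tech_rep`, `activity_mOD_min`, `flies_per_assay`. Activities
#' may be negative (blank-corrected plate-reader slopes of control lines
#' routinely are); `flies_per_assay` must be a positive count.
#'
#' @param path Path to a delimited file with a header; the delimiter is taken
#'   from the file extension (`.csv` comma, otherwise tab).
#' @return Data.frame of class `assay_measurements`.
#' @export
read_reporter_table <- function(path) {
  if (!file.exists(path)) stop("reporter table not found: ", path, call. = FALSE)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE)
  validate_assay_measurements(raw, source = path)
}

#' Validate assay measurements
#'
#' @param df Data.frame of measurements (see [read_reporter_table()]).
#' @param source Label used in error messages.
#' @return The validated measurements, classed `assay_measurements`.
#' @export
validate_assay_measurements <- function(df, source = "input") {
  req <- c("line_id", "chromosome_class", "tissue", "bio_rep", "tech_rep",
           "activity_mOD_min", "flies_per_assay")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         " in ", source, call. = FALSE)
  }
  if (!all(df$chromosome_class %in% c("X", "A", "control"))) {
    stop("chromosome_class must be one of X, A, control", call. = FALSE)
  }
  if (any(!is.finite(df$activity_mOD_min))) {
    stop("non-finite activity values in ", source, call. = FALSE)
  }
  if (any(!is.finite(df$flies_per_assay) | df$flies_per_assay <= 0)) {
    stop("flies_per_assay must be a positive count in ", source, call. = FALSE)
  }
  key <- paste(df$line_id, df$tissue, df$bio_rep, df$tech_rep, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicated (line_id, tissue, bio_rep, tech_rep) in ", source,
         call. = FALSE)
  }
  class(df) <- c("assay_measurements", "data.frame")
  df
}

#' Summarize one reporter line in one tissue
#'
#' Aggregates the replicate hierarchy: activities measured with
#' `flies_per_assay` different from `normalize_to` are first rescaled by
#' `normalize_to / flies_per_assay`; technical replicates are then averaged
#' within each biological replicate, and the biological-replicate means are
#' averaged into the line mean. The standard deviation is across
#' biological-replicate means.
#'
#' @param measurements Measurements for a single line and tissue.
#' @param normalize_to Reference fly count per assay. Default 5.
#' @return One-row data.frame: `line_id`, `chromosome_class`, `tissue`,
#'   `n_bio_reps`, `mean_activity`, `sd_activity`.
#' @export
summarize_line <- function(measurements, normalize_to = 5) {
  if (length(unique(measurements$tissue)) != 1) {
    stop("mixed tissues in input; summarize one tissue at a time",
         call. = FALSE)
  }
  if (length(unique(measurements$line_id)) != 1) {
    stop("summarize_line expects a single line; see summarize_lines()",
         call. = FALSE)
  }
  act <- measurements$activity_mOD_min *
    normalize_to / measurements$flies_per_assay
  bio_means <- tapply(act, measurements$bio_rep, mean)
  data.frame(
    line_id = measurements$line_id[1],
    chromosome_class = measurements$chromosome_class[1],
    tissue = measurements$tissue[1],
    n_bio_reps = length(bio_means),
    mean_activity = mean(bio_means),
    sd_activity = if (length(bio_means) > 1) stats::sd(bio_means) else NA_real_,
    stringsAsFactors = FALSE
  )
}

#' Summarize every reporter line in one tissue
#'
#' @param measurements Measurements for one tissue (any number of lines).
#' @inheritParams summarize_line
#' @return Data.frame with one row per line (see [summarize_line()]).
#' @export
summarize_lines <- function(measurements, normalize_to = 5) {
  if (length(unique(measurements$tissue)) != 1) {
    stop("mixed tissues in input; summarize one tissue at a time",
         call. = FALSE)
  }
  parts <- split(measurements, measurements$line_id)
  out <- do.call(rbind, lapply(parts, summarize_line,
                               normalize_to = normalize_to))
  out <- out[order(out$chromosome_class, out$line_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Compare X-linked and autosomal reporter lines
#'
#' Descriptive statistics per insertion class over line means and a two-sided
#' rank-sum p-value (same engine as the expression comparison). Control lines
#' are excluded from the comparison but summarized separately. `exclude_lines`
#' supports explicit outlier-exclusion reanalyses.
#'
#' @param summaries Line summaries for one tissue (see [summarize_lines()]).
#' @param exclude_lines Optional character vector of `line_id`s to drop.
#' @return List: `n_a`, `n_x`, `mean_a`, `median_a`, `mean_x`, `median_x`,
#'   `p_value`, plus `control` (mean/median/sd/n over control lines, or NULL).
#' @export
compare_classes <- function(summaries, exclude_lines = NULL) {
  if (!is.null(exclude_lines)) {
    summaries <- summaries[!(summaries$line_id %in% exclude_lines), ,
                           drop = FALSE]
  }
  ctrl <- summaries[summaries$chromosome_class == "control", , drop = FALSE]
  summaries <- summaries[summaries$chromosome_class %in% c("X", "A"), ,
                         drop = FALSE]
  a <- summaries$mean_activity[summaries$chromosome_class == "A"]
  x <- summaries$mean_activity[summaries$chromosome_class == "X"]
  if (!length(a) || !length(x)) {
    stop("need at least one line per class after exclusions", call. = FALSE)
  }
  list(
    n_a = length(a), n_x = length(x),
    mean_a = mean(a), median_a = stats::median(a),
    mean_x = mean(x), median_x = stats::median(x),
    p_value = rank_sum_test(x, a),
    control = if (nrow(ctrl)) {
      list(n = nrow(ctrl), mean = mean(ctrl$mean_activity),
           median = stats::median(ctrl$mean_activity),
           sd = if (nrow(ctrl) > 1) stats::sd(ctrl$mean_activity) else NA_real_)
    }
  )
}

#' Autosomal-to-X suppression ratio for one construct
#'
#' Mean autosomal activity divided by mean X-linked activity; values above 1
#' indicate suppression of the X-linked copies.
#'
#' @param mean_a,mean_x Class mean activities (mOD/min).
#' @return The ratio `mean_a / mean_x`.
#' @export
suppression_ratio <- function(mean_a, mean_x) {
  if (!is.finite(mean_x) || mean_x <= 0) {
    stop("X-class mean activity must be positive", call. = FALSE)
  }
  mean_a / mean_x
}

#' Regression of suppression degree on autosomal expression
#'
#' Ordinary least-squares fit of the suppression ratio on a construct's
#' autosomal expression level, quantifying how strongly the degree of X
#' suppression increases with expression potential. Optionally fits on
#' log-transformed expression.
#'
#' @param points Data.frame with columns `autosomal_expression` and
#'   `suppression_ratio` (one row per construct).
#' @param log_expression Regress on `log(autosomal_expression)` instead of
#'   the raw scale. Default FALSE.
#' @return List: `slope`, `intercept`, `r_squared`, `p_value` (two-sided
#'   slope test), `n`.
#' @export
suppression_vs_expression <- function(points, log_expression = FALSE) {
  stopifnot(all(c("autosomal_expression", "suppression_ratio") %in%
                  names(points)))
  if (nrow(points) < 3) stop("need at least 3 points", call. = FALSE)
  x <- points$autosomal_expression
  if (log_expression) x <- log(x)
  if (stats::var(x) == 0) stop("constant predictor", call. = FALSE)
  fit <- stats::lm(points$suppression_ratio ~ x)
  s <- summary(fit)
  list(
    slope = unname(stats::coef(fit)[2]),
    intercept = unname(stats::coef(fit)[1]),
    r_squared = unname(s$r.squared),
    p_value = unname(s$coefficients[2, 4]),
    n = nrow(points)
  )
}
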