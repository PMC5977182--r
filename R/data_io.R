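# Reading, validating, filtering and partitioning gene-expression tables.
#
# The canonical in-memory form is a long-format data.frame of class
# "expression_records": one row per gene x tissue x sex x replicate with a
# single FPKM value. Wide inputs (one column per replicate) are melted on read.

#' Read a gene-expression table
#'
#' Reads a TSV of per-gene FPKM values and returns validated long-format
#' expression records. Two layouts are accepted: `"wide"` with one row per
#' gene/tissue/sex and replicate columns (`fpkm_r1`, `fpkm_r2`, ...), and
#' `"long"` with one row per replicate and `replicate` + `fpkm` columns.
#' Column names can be remapped through `col_map`, e.g. when importing a
#' FlyAtlas2-style export whose headers differ from the defaults.
#'
#' @param path Path to a tab-separated file with a header row.
#' @param format `"wide"` or `"long"`.
#' @param col_map Named character vector mapping canonical names
#'   (`gene_id`, `chromosome`, `tissue`, `sex`, and for long format
#'   `replicate`, `fpkm`) to the column names used in the file. Unmapped
#'   names default to themselves.
#' @return A data.frame of class `expression_records` with columns
#'   `gene_id`, `chromosome`, `tissue`, `sex`, `replicate`, `fpkm`.
#' @export
read_expression_table <- function(path, format = c("wide", "long"),
                                  col_map = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop("expression table not found: ", path, call. = FALSE)
  }
  raw <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE)

  canonical <- c("gene_id", "chromosome", "tissue", "sex")
  if (format == "long") canonical <- c(canonical, "replicate", "fpkm")
  map <- stats::setNames(canonical, canonical)
  if (!is.null(col_map)) {
    bad <- setdiff(names(col_map), canonical)
    if (length(bad)) {
      stop("unknown col_map entries: ", paste(bad, collapse = ", "),
           call. = FALSE)
    }
    map[names(col_map)] <- col_map
  }
  missing <- map[!(map %in% names(raw))]
  if (format == "wide") {
    missing <- missing[names(missing) != "fpkm"]
  }
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         " in ", path, call. = FALSE)
  }

  if (format == "long") {
    rec <- data.frame(
      gene_id = as.character(raw[[map["gene_id"]]]),
      chromosome = as.character(raw[[map["chromosome"]]]),
      tissue = as.character(raw[[map["tissue"]]]),
      sex = as.character(raw[[map["sex"]]]),
      replicate = as.character(raw[[map["replicate"]]]),
      fpkm = as.numeric(raw[[map["fpkm"]]]),
      line = seq_len(nrow(raw)) + 1L,   # +1: header line
      stringsAsFactors = FALSE
    )
  } else {
    rep_cols <- grep("^fpkm_r[0-9]+$", names(raw), value = TRUE)
    if (!length(rep_cols)) {
      stop("missing required column(s): no replicate columns ",
           "(fpkm_r1, fpkm_r2, ...) in ", path, call. = FALSE)
    }
    rep_cols <- rep_cols[order(as.integer(sub("^fpkm_r", "", rep_cols)))]
    n <- nrow(raw)
    rec <- data.frame(
      gene_id = rep(as.character(raw[[map["gene_id"]]]), length(rep_cols)),
      chromosome = rep(as.character(raw[[map["chromosome"]]]), length(rep_cols)),
      tissue = rep(as.character(raw[[map["tissue"]]]), length(rep_cols)),
      sex = rep(as.character(raw[[map["sex"]]]), length(rep_cols)),
      replicate = rep(sub("^fpkm_", "", rep_cols), each = n),
      fpkm = as.numeric(unlist(raw[rep_cols], use.names = FALSE)),
      line = rep(seq_len(n) + 1L, length(rep_cols)),
      stringsAsFactors = FALSE
    )
  }
  validate_expression_records(rec, source = path)
}

#' Validate expression records
#'
#' Enforces the record invariants: FPKM values non-negative and finite, every
#' gene/tissue/sex combination carrying at least one replicate, and no
#' duplicated replicate rows. Offending rows are reported with their input
#' line numbers when available.
#'
#' @param records Long-format data.frame (see [read_expression_table()]).
#' @param source Label used in error messages.
#' @return The validated records, classed `expression_records`, with any
#'   bookkeeping `line` column removed.
#' @export
validate_expression_records <- function(records, source = "input") {
  req <- c("gene_id", "chromosome", "tissue", "sex", "replicate", "fpkm")
  missing <- setdiff(req, names(records))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         " in ", source, call. = FALSE)
  }
  lines <- if ("line" %in% names(records)) records$line else seq_len(nrow(records))
  bad <- !is.finite(records$fpkm) | records$fpkm < 0
  if (any(bad)) {
    i <- which(bad)[1]
    stop(sprintf(
      "invalid FPKM for gene '%s' (line %s of %s): %s (%d offending row(s); FPKM must be finite and >= 0)",
      records$gene_id[i], lines[i], source,
      format(records$fpkm[i]), sum(bad)), call. = FALSE)
  }
  key <- paste(records$gene_id, records$tissue, records$sex, records$replicate,
               sep = "\r")
  if (anyDuplicated(key)) {
    i <- which(duplicated(key))[1]
    stop(sprintf(
      "duplicated replicate for gene '%s', tissue '%s', sex '%s' (line %s of %s)",
      records$gene_id[i], records$tissue[i], records$sex[i], lines[i], source),
      call. = FALSE)
  }
  records$line <- NULL
  class(records) <- c("expression_records", "data.frame")
  records
}

#' Average biological replicates per gene
#'
#' Collapses replicate FPKM values to their arithmetic mean within each
#' gene/tissue/sex combination.
#'
#' @param records Validated expression records.
#' @return Data.frame with one row per gene/tissue/sex: `gene_id`,
#'   `chromosome`, `tissue`, `sex`, `mean_fpkm`, `n_replicates`.
#' @export
average_replicates <- function(records) {
  out <- stats::aggregate(
    records["fpkm"],
    by = records[c("gene_id", "chromosome", "tissue", "sex")],
    FUN = mean
  )
  n <- stats::aggregate(
    list(n_replicates = records$fpkm),
    by = records[c("gene_id", "tissue", "sex")],
    FUN = length
  )
  out <- merge(out, n, by = c("gene_id", "tissue", "sex"), sort = FALSE)
  names(out)[names(out) == "fpkm"] <- "mean_fpkm"
  out <- out[order(out$tissue, out$sex, out$gene_id),
             c("gene_id", "chromosome", "tissue", "sex", "mean_fpkm",
               "n_replicates")]
  rownames(out) <- NULL
  out
}

#' Construct a tissue table directly
#'
#' Low-level constructor for an already filtered and partitioned expression
#' set (used by tests and by re-filtering). `chromosome_class` must be
#' `"X"` or `"A"` throughout.
#'
#' @param df Data.frame with `gene_id`, `chromosome_class`, `mean_fpkm`.
#' @param tissue,sex Labels carried as attributes.
#' @param min_fpkm,max_fpkm Filter provenance recorded as attributes.
#' @return A `tissue_table`.
#' @export
new_tissue_table <- function(df, tissue, sex, min_fpkm = 0, max_fpkm = NULL) {
  stopifnot(all(c("gene_id", "chromosome_class", "mean_fpkm") %in% names(df)))
  if (!all(df$chromosome_class %in% c("X", "A"))) {
    stop("chromosome_class must be 'X' or 'A'", call. = FALSE)
  }
  df <- df[, c("gene_id", "chromosome_class", "mean_fpkm")]
  rownames(df) <- NULL
  structure(df,
            tissue = tissue, sex = sex,
            min_fpkm = min_fpkm, max_fpkm = max_fpkm,
            class = c("tissue_table", "data.frame"))
}

#' Filter, average and partition expression records for one tissue and sex
#'
#' Applies the analysis filters — replicate averaging, retention of genes with
#' mean FPKM strictly greater than `min_fpkm` and (if given) at most
#' `max_fpkm` — and partitions the retained genes into X-linked and autosomal
#' classes. Genes on chromosomes in neither label set (e.g. Y, mitochondrial,
#' unplaced scaffolds) are excluded and counted. Filtering is per tissue and
#' sex; passing an existing `tissue_table` re-applies the thresholds to its
#' means (an idempotent operation when thresholds are unchanged).
#'
#' @param records Expression records, a replicate-averaged data.frame with a
#'   `mean_fpkm` column, or a `tissue_table`.
#' @param tissue,sex Which tissue/sex stratum to analyze (required unless
#'   `records` is a `tissue_table` or contains exactly one stratum).
#' @param min_fpkm Genes kept only if `mean_fpkm > min_fpkm` (strict). Default 1.
#' @param max_fpkm If non-`NULL`, genes with `mean_fpkm > max_fpkm` are
#'   excluded (i.e. keep `mean_fpkm <= max_fpkm`); used for the
#'   high-expression exclusion reanalysis at 90 FPKM.
#' @param x_labels,autosome_labels Disjoint sets of chromosome labels defining
#'   the X and autosomal classes.
#' @return A `tissue_table`: data.frame `gene_id`, `chromosome_class`,
#'   `mean_fpkm` with attributes recording the stratum, thresholds and the
#'   counts of genes excluded by chromosome class and by the FPKM filters.
#' @export
build_tissue_table <- function(records, tissue = NULL, sex = NULL,
                               min_fpkm = 1, max_fpkm = NULL,
                               x_labels = fly_x_labels(),
                               autosome_labels = fly_autosome_labels()) {
  if (length(intersect(x_labels, autosome_labels))) {
    stop("x_labels and autosome_labels must be disjoint", call. = FALSE)
  }

  if (inherits(records, "tissue_table")) {
    tissue <- tissue %||% attr(records, "tissue")
    sex <- sex %||% attr(records, "sex")
    avg <- data.frame(gene_id = records$gene_id,
                      chromosome_class = records$chromosome_class,
                      mean_fpkm = records$mean_fpkm,
                      stringsAsFactors = FALSE)
    n_excl_chrom <- 0L
  } else {
    if (!("mean_fpkm" %in% names(records))) {
      records <- average_replicates(records)
    }
    if (is.null(tissue)) {
      tissue <- unique(records$tissue)
      if (length(tissue) != 1) {
        stop("records span multiple tissues; specify `tissue`", call. = FALSE)
      }
    }
    if (is.null(sex)) {
      sex <- unique(records$sex)
      if (length(sex) != 1) {
        stop("records span multiple sexes; specify `sex`", call. = FALSE)
      }
    }
    avg <- records[records$tissue == tissue & records$sex == sex, , drop = FALSE]
    cls <- ifelse(avg$chromosome %in% x_labels, "X",
                  ifelse(avg$chromosome %in% autosome_labels, "A", NA))
    n_excl_chrom <- sum(is.na(cls))
    avg <- data.frame(gene_id = avg$gene_id,
                      chromosome_class = cls,
                      mean_fpkm = avg$mean_fpkm,
                      stringsAsFactors = FALSE)[!is.na(cls), , drop = FALSE]
  }

  n_in <- nrow(avg)
  keep <- avg$mean_fpkm > min_fpkm
  if (!is.null(max_fpkm)) keep <- keep & avg$mean_fpkm <= max_fpkm
  out <- avg[keep, , drop = FALSE]
  n_excl_filter <- n_in - nrow(out)

  if (!any(out$chromosome_class == "X") || !any(out$chromosome_class == "A")) {
    stop("empty X or autosomal partition after filtering (tissue=", tissue,
         ", sex=", sex, "); downstream statistics undefined", call. = FALSE)
  }
  tab <- new_tissue_table(out, tissue = tissue, sex = sex,
                          min_fpkm = min_fpkm, max_fpkm = max_fpkm)
  attr(tab, "n_input") <- n_in
  attr(tab, "n_excluded_chromosome") <- n_excl_chrom
  attr(tab, "n_excluded_filter") <- n_excl_filter
  tab
}

#' @export
print.tissue_table <- function(x, ...) {
  cat(sprintf("Tissue table: %s (%s), %d X / %d A genes, FPKM > %g%s\n",
              attr(x, "tissue"), attr(x, "sex"),
              sum(x$chromosome_class == "X"), sum(x$chromosome_class == "A"),
              attr(x, "min_fpkm"),
              if (is.null(attr(x, "max_fpkm"))) ""
              else sprintf(" and <= %g", attr(x, "max_fpkm"))))
  print.data.frame(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("...", nrow(x) - 6, "more rows\n")
  invisible(x)
}

#' Write expression records or a tissue table to TSV
#'
#' `write_expression_table()` writes long-format records in the exact layout
#' [read_expression_table()] accepts (round-trip safe); `write_tissue_table()`
#' writes the filtered gene/class/mean table.
#'
#' @param records Expression records.
#' @param table A `tissue_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(records, path) {
  utils::write.table(
    as.data.frame(records)[, c("gene_id", "chromosome", "tissue", "sex",
                               "replicate", "fpkm")],
    path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_expression_table
#' @export
write_tissue_table <- function(table, path) {
  utils::write.table(as.data.frame(table), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
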