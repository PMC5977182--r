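# Orchestration: run configuration, end-to-end analysis, report emission.

#' Build a run configuration
#'
#' Collects every setting of a full analysis run into a serializable list.
#' The configuration (and its MD5 hash) is written alongside the outputs so
#' any run can be reproduced exactly from config + seed.
#'
#' @param expression_path Path to an expression TSV (see
#'   [read_expression_table()]), or NULL to skip expression sections.
#' @param expression_format `"wide"` or `"long"`.
#' @param reporter_path Optional path to a reporter assay table.
#' @param out_dir Output directory (created if absent).
#' @param x_labels,autosome_labels Chromosome label sets.
#' @param min_fpkm,high_fpkm Primary FPKM floor and the high-expression
#'   exclusion cutoff used in the secondary table (defaults 1 and 90).
#' @param thresholds Representation threshold grid.
#' @param expected_from `"dataset"` (genome-wide, default), `"tissue"`, or a
#'   numeric proportion.
#' @param correction `"auto"` (1 / observed X/A ratio per stratum), `"none"`,
#'   or a numeric factor, for the corrected representation profiles.
#' @param tissues,sexes Strata to analyze (NULL = all present).
#' @param exclude_lines Reporter lines to drop in a sensitivity reanalysis.
#' @param normalize_to Reporter fly-count reference. Default 5.
#' @param alpha Significance level. Default 0.05.
#' @param seed Seed recorded in the manifest (the analysis itself is
#'   deterministic; the seed matters for simulation-generated inputs).
#' @return Object of class `run_config`.
#' @export
run_config <- function(expression_path = NULL, expression_format = "long",
                       reporter_path = NULL, out_dir = "xsuppress_out",
                       x_labels = fly_x_labels(),
                       autosome_labels = fly_autosome_labels(),
                       min_fpkm = 1, high_fpkm = 90,
                       thresholds = default_threshold_grid(),
                       expected_from = "dataset", correction = "auto",
                       tissues = NULL, sexes = NULL,
                       exclude_lines = NULL, normalize_to = 5,
                       alpha = 0.05, seed = 1L) {
  cfg <- list(
    expression_path = expression_path, expression_format = expression_format,
    reporter_path = reporter_path, out_dir = out_dir,
    x_labels = x_labels, autosome_labels = autosome_labels,
    min_fpkm = min_fpkm, high_fpkm = high_fpkm, thresholds = thresholds,
    expected_from = expected_from, correction = correction,
    tissues = tissues, sexes = sexes,
    exclude_lines = exclude_lines, normalize_to = normalize_to,
    alpha = alpha, seed = as.integer(seed)
  )
  class(cfg) <- "run_config"
  cfg
}

#' Read a run configuration from YAML
#'
#' @param path YAML file whose keys match the arguments of [run_config()].
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  known <- names(formals(run_config))
  bad <- setdiff(names(raw), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(run_config, raw)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run the full X-vs-autosome analysis
#'
#' End-to-end orchestration: reads the inputs, then emits (a) the per-stratum
#' X/A ratio table, (b) the same table excluding highly expressed genes
#' (mean FPKM above `high_fpkm`), (c) representation profiles per stratum
#' with and without dosage correction, (d) reporter line summaries and class
#' comparisons if a reporter table is given, and (e) a JSON run manifest with
#' the configuration, its hash, package version, and gene counts at every
#' filter step. All outputs are plain TSV; a rerun with the same config and
#' inputs is byte-identical.
#'
#' @param config A `run_config`.
#' @param records Expression records passed directly (overrides
#'   `config$expression_path`); convenient for simulated input.
#' @param reporter Assay measurements passed directly (overrides
#'   `config$reporter_path`).
#' @return Invisibly, a list with the computed tables (`ratios`,
#'   `ratios_high_excluded`, `profiles`, `reporter`, `manifest`) and the
#'   output file paths.
#' @export
run_full_analysis <- function(config, records = NULL, reporter = NULL) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  manifest <- list(
    package = "xsuppress",
    version = as.character(utils::packageVersion("xsuppress")),
    config = unclass(config),
    counts = list(),
    skipped = character()
  )

  if (is.null(records) && !is.null(config$expression_path)) {
    records <- read_expression_table(config$expression_path,
                                     format = config$expression_format)
  }
  if (is.null(reporter) && !is.null(config$reporter_path)) {
    reporter <- read_reporter_table(config$reporter_path)
  }

  ratios <- ratios_high <- profiles <- reporter_out <- NULL

  if (!is.null(records)) {
    strata <- unique(as.data.frame(records)[, c("tissue", "sex")])
    if (!is.null(config$tissues)) {
      strata <- strata[strata$tissue %in% config$tissues, , drop = FALSE]
    }
    if (!is.null(config$sexes)) {
      strata <- strata[strata$sex %in% config$sexes, , drop = FALSE]
    }
    strata <- strata[order(strata$sex, strata$tissue), , drop = FALSE]

    p0 <- if (is.numeric(config$expected_from)) {
      config$expected_from
    } else if (identical(config$expected_from, "dataset")) {
      expected_x_proportion(records, config$x_labels, config$autosome_labels)
    } else NA_real_   # "tissue": computed per stratum below

    ratio_rows <- list(); high_rows <- list(); profiles <- list()
    for (i in seq_len(nrow(strata))) {
      ti <- strata$tissue[i]; si <- strata$sex[i]
      key <- paste(ti, si, sep = "_")
      tab <- build_tissue_table(records, tissue = ti, sex = si,
                                min_fpkm = config$min_fpkm,
                                x_labels = config$x_labels,
                                autosome_labels = config$autosome_labels)
      rr <- median_xa_ratio(tab)
      ratio_rows[[key]] <- format(rr)
      manifest$counts[[key]] <- list(
        input = attr(tab, "n_input"),
        excluded_chromosome = attr(tab, "n_excluded_chromosome"),
        excluded_filter = attr(tab, "n_excluded_filter"),
        retained = nrow(tab), n_x = rr$n_x, n_a = rr$n_a
      )

      high_rows[[key]] <- tryCatch({
        tab90 <- build_tissue_table(records, tissue = ti, sex = si,
                                    min_fpkm = config$min_fpkm,
                                    max_fpkm = config$high_fpkm,
                                    x_labels = config$x_labels,
                                    autosome_labels = config$autosome_labels)
        format(median_xa_ratio(tab90))
      }, error = function(e) {
        manifest$skipped <<- c(manifest$skipped,
                               paste0("high-exclusion ", key, ": ",
                                      conditionMessage(e)))
        NULL
      })

      p_strat <- if (is.na(p0)) {
        n_x <- sum(tab$chromosome_class == "X")
        n_x / nrow(tab)
      } else p0
      cf <- if (identical(config$correction, "auto")) {
        correction_factor(rr)
      } else if (is.numeric(config$correction)) {
        config$correction
      } else NULL

      prof_plain <- representation_profile(
        tab, thresholds = config$thresholds, expected_proportion = p_strat,
        alpha = config$alpha)
      prof_plain <- cbind(tissue = ti, sex = si, corrected = FALSE, prof_plain)
      profiles[[paste0(key, "_uncorrected")]] <- prof_plain
      write_tsv(prof_plain,
                fp <- file.path(config$out_dir,
                                paste0("representation_", key, ".tsv")))
      paths <- c(paths, fp)
      if (!is.null(cf)) {
        prof_corr <- representation_profile(
          tab, thresholds = config$thresholds, expected_proportion = p_strat,
          correction_factor = cf, alpha = config$alpha)
        prof_corr <- cbind(tissue = ti, sex = si, corrected = TRUE, prof_corr)
        profiles[[paste0(key, "_corrected")]] <- prof_corr
        write_tsv(prof_corr,
                  fp <- file.path(config$out_dir,
                                  paste0("representation_", key,
                                         "_corrected.tsv")))
        paths <- c(paths, fp)
      }
    }
    ratios <- do.call(rbind, ratio_rows); rownames(ratios) <- NULL
    write_tsv(ratios, fp <- file.path(config$out_dir, "ratios.tsv"))
    paths <- c(paths, fp)
    if (length(high_rows) && any(!vapply(high_rows, is.null, logical(1)))) {
      ratios_high <- do.call(rbind, high_rows); rownames(ratios_high) <- NULL
      write_tsv(ratios_high,
                fp <- file.path(config$out_dir, "ratios_high_excluded.tsv"))
      paths <- c(paths, fp)
    }
  } else {
    manifest$skipped <- c(manifest$skipped, "expression sections: no input")
  }

  if (!is.null(reporter)) {
    reporter_out <- list()
    for (ti in unique(reporter$tissue)) {
      sub <- reporter[reporter$tissue == ti, , drop = FALSE]
      summ <- summarize_lines(sub, normalize_to = config$normalize_to)
      write_tsv(summ, fp <- file.path(config$out_dir,
                                      paste0("reporter_lines_", ti, ".tsv")))
      paths <- c(paths, fp)
      cmp <- compare_classes(summ, exclude_lines = config$exclude_lines)
      cmp_df <- data.frame(
        tissue = ti, n_a = cmp$n_a, n_x = cmp$n_x,
        mean_a = cmp$mean_a, median_a = cmp$median_a,
        mean_x = cmp$mean_x, median_x = cmp$median_x,
        suppression_ratio = suppression_ratio(cmp$mean_a, cmp$mean_x),
        p = cmp$p_value, stringsAsFactors = FALSE)
      write_tsv(cmp_df, fp <- file.path(config$out_dir,
                                        paste0("reporter_compare_", ti,
                                               ".tsv")))
      paths <- c(paths, fp)
      reporter_out[[ti]] <- list(summaries = summ, comparison = cmp)
    }
  } else {
    manifest$skipped <- c(manifest$skipped, "reporter sections: no input")
  }

  cfg_path <- file.path(config$out_dir, "run_config.yaml")
  yaml::write_yaml(unclass(config), cfg_path)
  manifest$config_md5 <- unname(tools::md5sum(cfg_path))
  manifest_path <- file.path(config$out_dir, "run_manifest.json")
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA, null = "null")
  paths <- c(paths, cfg_path, manifest_path)

  invisible(list(ratios = ratios, ratios_high_excluded = ratios_high,
                 profiles = profiles, reporter = reporter_out,
                 manifest = manifest, paths = paths))
}
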