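# Generative model of germline/somatic X-linked expression: log-normal
# baseline two-dose expression, single-dose buffering in the absence of
# chromosome-wide dosage compensation, and expression-dependent X suppression
# above a threshold. Serves as the synthetic-data engine for every analysis
# stage and for parameter recovery.

#' Parameters of the threshold X-suppression model
#'
#' Builds and validates the parameter set of the generative model. Each gene
#' draws a baseline two-dose expression `e ~ logNormal(log_mean, log_sd)` and
#' is X-linked with probability `x_fraction`. In males, autosomal genes
#' express `e`; X-linked genes express `e` under somatic dosage compensation
#' or `buffering_b * e` without it (`b = 0.5` is the pure one-dose effect,
#' `b = 1` full buffering). X-linked expression is then multiplied by the
#' suppression factor `f(e) = min(1, (tau/e)^gamma)`: no suppression below
#' the threshold `tau`, increasingly severe suppression above it. Replicates
#' add independent multiplicative log-normal noise.
#'
#' @param n_genes Number of genes to simulate.
#' @param x_fraction Probability a gene is X-linked, in (0, 1). Default 0.15,
#'   roughly the X-linked share of the fly gene universe.
#' @param log_mean,log_sd Location and scale (log scale) of the baseline
#'   expression distribution. Defaults 2 and 1.5 give a median near 7 FPKM
#'   with ~5% of genes above 90 FPKM.
#' @param buffering_b Single-dose expression as a fraction of two-dose
#'   expression, in \[0.5, 1\]. Default 0.65, the buffered single-dose level
#'   observed in the absence of chromosome-wide compensation.
#' @param dosage_compensation Logical; TRUE models somatic tissue (X fully
#'   compensated), FALSE the male germline.
#' @param tau Suppression threshold (FPKM); `Inf` disables suppression.
#' @param gamma Suppression severity exponent, >= 0; 0 disables suppression.
#' @param n_replicates Biological replicates per gene. Default 3.
#' @param replicate_noise_sd Log-scale sd of replicate noise. Default 0.05.
#' @param seed Integer seed; all stochastic output is reproducible given it.
#' @return Object of class `suppression_params`.
#' @export
suppression_params <- function(n_genes = 10000, x_fraction = 0.15,
                               log_mean = 2, log_sd = 1.5,
                               buffering_b = 0.65,
                               dosage_compensation = FALSE,
                               tau = Inf, gamma = 0,
                               n_replicates = 3, replicate_noise_sd = 0.05,
                               seed = 1L) {
  stopifnot(
    n_genes >= 2,
    x_fraction > 0, x_fraction < 1,
    is.finite(log_mean), log_sd > 0,
    buffering_b >= 0.5, buffering_b <= 1,
    is.logical(dosage_compensation), length(dosage_compensation) == 1,
    tau > 0,
    gamma >= 0, is.finite(gamma),
    n_replicates >= 1,
    replicate_noise_sd >= 0, is.finite(replicate_noise_sd)
  )
  structure(list(
    n_genes = as.integer(n_genes), x_fraction = x_fraction,
    log_mean = log_mean, log_sd = log_sd,
    buffering_b = buffering_b, dosage_compensation = dosage_compensation,
    tau = tau, gamma = gamma,
    n_replicates = as.integer(n_replicates),
    replicate_noise_sd = replicate_noise_sd,
    seed = as.integer(seed)
  ), class = "suppression_params")
}

#' Expression-dependent X suppression factor
#'
#' `f(e) = min(1, (tau/e)^gamma)`: 1 (no suppression) for baseline expression
#' `e <= tau`, decreasing in `e` above the threshold, with severity set by
#' `gamma`. Continuous, non-increasing, and identically 1 when `gamma = 0` or
#' `tau = Inf`.
#'
#' @param e Baseline (two-dose, autosomal-potential) expression, > 0.
#' @param tau Threshold, > 0 (may be `Inf`).
#' @param gamma Severity exponent, >= 0.
#' @return Suppression multiplier in (0, 1].
#' @export
suppression_factor <- function(e, tau, gamma) {
  stopifnot(all(e > 0), tau > 0, gamma >= 0)
  if (gamma == 0 || is.infinite(tau)) return(rep(1, length(e)))
  pmin(1, (tau / e)^gamma)
}

#' Generate a synthetic gene-expression dataset
#'
#' Draws a gene set from the threshold-suppression model and returns
#' replicate-level records in the exact long format accepted by
#' [read_expression_table()]/[validate_expression_records()]. Buffering and
#' suppression act on the male X; in females and for autosomal genes the
#' baseline expression is emitted unchanged (apart from replicate noise).
#' X-linked genes carry chromosome label `"X"`; autosomal genes are assigned
#' uniformly to the major autosomal arms.
#'
#' @param params A `suppression_params` object.
#' @param tissue,sex Labels stamped on the records.
#' @return Expression records with an attached `baseline` attribute
#'   (data.frame `gene_id`, `baseline_e`) for model diagnostics.
#' @export
generate_expression_dataset <- function(params, tissue = "testis",
                                        sex = "male") {
  stopifnot(inherits(params, "suppression_params"))
  withr::with_seed(params$seed, {
    n <- params$n_genes
    gene_id <- sprintf("g%05d", seq_len(n))
    is_x <- stats::runif(n) < params$x_fraction
    chromosome <- ifelse(
      is_x, fly_x_labels()[1],
      sample(fly_autosome_labels()[1:4], n, replace = TRUE))
    e <- stats::rlnorm(n, meanlog = params$log_mean, sdlog = params$log_sd)

    expr <- e
    if (sex == "male") {
      dose <- if (params$dosage_compensation) 1 else params$buffering_b
      expr[is_x] <- e[is_x] * dose *
        suppression_factor(e[is_x], params$tau, params$gamma)
    }

    k <- params$n_replicates
    noise <- if (params$replicate_noise_sd > 0) {
      exp(stats::rnorm(n * k, sd = params$replicate_noise_sd))
    } else rep(1, n * k)
    rec <- data.frame(
      gene_id = rep(gene_id, k),
      chromosome = rep(chromosome, k),
      tissue = tissue, sex = sex,
      replicate = rep(paste0("r", seq_len(k)), each = n),
      fpkm = rep(expr, k) * noise,
      stringsAsFactors = FALSE
    )
    rec <- validate_expression_records(rec, source = "synthetic generator")
    attr(rec, "baseline") <- data.frame(gene_id = gene_id, baseline_e = e,
                                        stringsAsFactors = FALSE)
    rec
  })
}

#' Recover the buffering fraction from a synthetic germline dataset
#'
#' Estimates the single-dose buffering fraction `b` as the median X/A
#' expression ratio of the full dataset. No FPKM floor is applied here: under
#' a global buffering factor the usual FPKM > 1 filter truncates more of the
#' X low tail than the A low tail and would bias the median ratio upward, so
#' the unfiltered ratio is the consistent estimator. Meaningful when the
#' dataset was generated without dosage compensation and without suppression
#' (`tau = Inf`); with compensation on, the same estimator recovers 1.
#'
#' @param records Expression records (synthetic or real).
#' @param x_labels,autosome_labels Chromosome label sets.
#' @return List: `estimate` (the median X/A ratio), `n_x`, `n_a`, `p_value`.
#' @export
recover_buffering <- function(records,
                              x_labels = fly_x_labels(),
                              autosome_labels = fly_autosome_labels()) {
  tab <- build_tissue_table(records, min_fpkm = 0,
                            x_labels = x_labels,
                            autosome_labels = autosome_labels)
  rr <- median_xa_ratio(tab)
  list(estimate = rr$xa_ratio, n_x = rr$n_x, n_a = rr$n_a,
       p_value = rr$p_value)
}

#' Recover the suppression signal from a synthetic dataset
#'
#' Applies the full representation pipeline to a dataset: computes the
#' genome-wide expected X proportion, filters at FPKM > 1, applies the dosage
#' correction `1/buffering`, and runs the representation profile. The summary
#' reports which thresholds are called `under`; the call is only evaluated on
#' categories whose expected X count reaches `min_expected`, since the
#' goodness-of-fit statistic is unreliable below that.
#'
#' @param records Expression records.
#' @param buffering Buffering fraction used for the correction factor
#'   (correction = `1/buffering`).
#' @param thresholds FPKM threshold grid.
#' @param alpha Significance level.
#' @param min_expected Minimum expected X count for a category to be judged.
#' @inheritParams recover_buffering
#' @return List: `profile` (see [representation_profile()]),
#'   `under_thresholds` (thresholds called under, among judged categories),
#'   `judged_thresholds`, `expected_proportion`.
#' @export
recover_suppression_signal <- function(records, buffering = 0.65,
                                       thresholds = default_threshold_grid(),
                                       alpha = 0.05, min_expected = 5,
                                       x_labels = fly_x_labels(),
                                       autosome_labels = fly_autosome_labels()) {
  p0 <- expected_x_proportion(records, x_labels, autosome_labels)
  tab <- build_tissue_table(records, min_fpkm = 1,
                            x_labels = x_labels,
                            autosome_labels = autosome_labels)
  prof <- representation_profile(tab, thresholds = thresholds,
                                 expected_proportion = p0,
                                 correction_factor = 1 / buffering,
                                 alpha = alpha, min_expected = min_expected)
  judged <- prof$n_total * prof$expected_proportion >= min_expected &
    !is.na(prof$p_value)
  list(
    profile = prof,
    under_thresholds = prof$threshold[judged & prof$direction == "under"],
    judged_thresholds = prof$threshold[judged],
    expected_proportion = p0
  )
}

#' Generate a synthetic reporter-assay dataset
#'
#' Simulates transformed lines carrying a reporter construct at autosomal and
#' X-linked insertion sites, with the hierarchical replicate structure of the
#' activity assays. Each construct has a true autosomal activity level `a`;
#' X-linked lines express `a * f(a)` under the same threshold-suppression
#' model ([suppression_factor()]). Line-level, biological-replicate and
#' technical-replicate noise are multiplicative (log-normal). Recorded
#' activities are scaled by `flies_per_assay / normalize_to` so that assays
#' run with more flies read proportionally higher, as raw plate-reader
#' activities do; [summarize_line()] undoes this with its fly-count
#' normalization.
#'
#' @param constructs Data.frame with one row per construct: `construct`
#'   (label), `activity` (true autosomal mOD/min), and optionally
#'   `flies_per_assay` (default `normalize_to`).
#' @param tau,gamma Threshold-suppression parameters applied to X-linked
#'   insertions.
#' @param n_lines_per_class Lines per chromosome class per construct.
#' @param n_bio,n_tech Biological and technical replicates per line.
#' @param line_sd,bio_sd,tech_sd Log-scale noise sds at each level of the
#'   hierarchy (0 = deterministic).
#' @param normalize_to Reference fly count. Default 5.
#' @param tissue Tissue label. Default `"testis"`.
#' @param seed Integer seed.
#' @return `assay_measurements` data.frame with a `construct` column.
#' @export
generate_reporter_dataset <- function(constructs, tau, gamma,
                                      n_lines_per_class = 3,
                                      n_bio = 3, n_tech = 2,
                                      line_sd = 0.1, bio_sd = 0.1,
                                      tech_sd = 0.05,
                                      normalize_to = 5, tissue = "testis",
                                      seed = 1L) {
  stopifnot(all(c("construct", "activity") %in% names(constructs)),
            all(constructs$activity > 0), tau > 0, gamma >= 0,
            n_lines_per_class >= 1, n_bio >= 1, n_tech >= 1)
  if (!("flies_per_assay" %in% names(constructs))) {
    constructs$flies_per_assay <- normalize_to
  }
  withr::with_seed(as.integer(seed), {
    rows <- list()
    for (ci in seq_len(nrow(constructs))) {
      a <- constructs$activity[ci]
      flies <- constructs$flies_per_assay[ci]
      for (cls in c("A", "X")) {
        true_level <- if (cls == "X") a * suppression_factor(a, tau, gamma) else a
        for (li in seq_len(n_lines_per_class)) {
          line_id <- sprintf("%s_%s%02d", constructs$construct[ci], cls, li)
          line_level <- true_level *
            (if (line_sd > 0) exp(stats::rnorm(1, sd = line_sd)) else 1)
          for (bi in seq_len(n_bio)) {
            bio_level <- line_level *
              (if (bio_sd > 0) exp(stats::rnorm(1, sd = bio_sd)) else 1)
            for (ti in seq_len(n_tech)) {
              meas <- bio_level *
                (if (tech_sd > 0) exp(stats::rnorm(1, sd = tech_sd)) else 1)
              rows[[length(rows) + 1L]] <- data.frame(
                construct = constructs$construct[ci],
                line_id = line_id, chromosome_class = cls, tissue = tissue,
                bio_rep = paste0("b", bi), tech_rep = paste0("t", ti),
                activity_mOD_min = meas * flies / normalize_to,
                flies_per_assay = flies,
                stringsAsFactors = FALSE
              )
            }
          }
        }
      }
    }
    out <- do.call(rbind, rows)
    rownames(out) <- NULL
    validate_assay_measurements(out, source = "synthetic generator")
  })
}
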