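# Fixture builders and independent oracles used across the suite.

# Long-format expression records from per-gene mean values (each gene gets
# `reps` identical replicates, so the replicate mean equals the given value).
make_records <- function(means, chromosomes, tissue = "testis", sex = "male",
                         reps = 3, gene_ids = NULL) {
  n <- length(means)
  if (is.null(gene_ids)) gene_ids <- sprintf("g%04d", seq_len(n))
  rec <- data.frame(
    gene_id = rep(gene_ids, reps),
    chromosome = rep(chromosomes, reps),
    tissue = tissue, sex = sex,
    replicate = rep(paste0("r", seq_len(reps)), each = n),
    fpkm = rep(means, reps),
    stringsAsFactors = FALSE
  )
  validate_expression_records(rec, source = "fixture")
}

# Tissue table directly from X and A mean values.
make_table <- function(x_means, a_means, tissue = "testis", sex = "male") {
  new_tissue_table(
    data.frame(
      gene_id = sprintf("g%04d", seq_along(c(x_means, a_means))),
      chromosome_class = rep(c("X", "A"), c(length(x_means), length(a_means))),
      mean_fpkm = c(x_means, a_means),
      stringsAsFactors = FALSE
    ),
    tissue = tissue, sex = sex
  )
}

# Brute-force two-sided rank-sum p-value by enumeration of all C(n+m, n)
# rank assignments (tie-free data only). Independent of wilcox.test.
exact_ranksum_p <- function(x, y) {
  n <- length(x)
  m <- length(y)
  stopifnot(!anyDuplicated(c(x, y)))
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n)]) - n * (n + 1) / 2
  sets <- utils::combn(n + m, n)
  ws <- colSums(matrix(seq_len(n + m)[sets], nrow = n)) - n * (n + 1) / 2
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

# Direct-formula 1-df goodness-of-fit chi-square, independent of chisq.test.
chi2_formula <- function(n_x_obs, n_total, p) {
  e_x <- n_total * p
  e_a <- n_total * (1 - p)
  (n_x_obs - e_x)^2 / e_x + ((n_total - n_x_obs) - e_a)^2 / e_a
}

# Closed-form OLS R^2 = 1 - SSres/SStot, independent of lm.
r_squared_formula <- function(x, y) {
  beta <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
  alpha <- mean(y) - beta * mean(x)
  resid <- y - (alpha + beta * x)
  1 - sum(resid^2) / sum((y - mean(y))^2)
}

# One assay-measurement row.
assay_row <- function(line_id, cls, bio, tech, act, flies = 5,
                      tissue = "testis") {
  data.frame(line_id = line_id, chromosome_class = cls, tissue = tissue,
             bio_rep = bio, tech_rep = tech, activity_mOD_min = act,
             flies_per_assay = flies, stringsAsFactors = FALSE)
}
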