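test_that("parameter validation rejects out-of-range values", {
  expect_s3_class(suppression_params(), "suppression_params")
  expect_error(suppression_params(x_fraction = 0))
  expect_error(suppression_params(buffering_b = 0.4))
  expect_error(suppression_params(buffering_b = 1.2))
  expect_error(suppression_params(tau = -1))
  expect_error(suppression_params(gamma = -0.1))
  expect_error(suppression_params(log_sd = 0))
})

test_that("the suppression factor is a continuous non-increasing cap", {
  e <- c(0.1, 1, 5, 26, 26.0001, 60, 500)
  f <- suppression_factor(e, tau = 26, gamma = 1)
  expect_true(all(f > 0 & f <= 1))
  expect_true(all(diff(f) <= 0))
  expect_equal(f[e <= 26], rep(1, 4))
  expect_equal(suppression_factor(52, tau = 26, gamma = 1), 0.5)
  expect_equal(suppression_factor(e, tau = 26, gamma = 0), rep(1, 7))
  expect_equal(suppression_factor(e, tau = Inf, gamma = 2), rep(1, 7))
})

test_that("generation is byte-identical given a seed", {
  p <- suppression_params(n_genes = 300, tau = 20, gamma = 1, seed = 123)
  expect_identical(generate_expression_dataset(p),
                   generate_expression_dataset(p))
  p2 <- suppression_params(n_genes = 300, tau = 20, gamma = 1, seed = 124)
  expect_false(identical(generate_expression_dataset(p),
                         generate_expression_dataset(p2)))
  r <- generate_reporter_dataset(
    data.frame(construct = "c1", activity = 2), tau = 5, gamma = 1, seed = 9)
  expect_identical(r, generate_reporter_dataset(
    data.frame(construct = "c1", activity = 2), tau = 5, gamma = 1, seed = 9))
})

test_that("noise-free germline X expression is exactly b times baseline", {
  p <- suppression_params(n_genes = 500, buffering_b = 0.65,
                          dosage_compensation = FALSE, tau = Inf, gamma = 0,
                          replicate_noise_sd = 0, n_replicates = 1, seed = 3)
  d <- generate_expression_dataset(p)
  base <- attr(d, "baseline")
  m <- merge(as.data.frame(d), base, by = "gene_id")
  is_x <- m$chromosome == "X"
  expect_equal(m$fpkm[is_x], 0.65 * m$baseline_e[is_x])
  expect_equal(m$fpkm[!is_x], m$baseline_e[!is_x])

  # above-threshold genes are suppressed by (tau/e)^gamma
  ps <- suppression_params(n_genes = 500, buffering_b = 0.65,
                           dosage_compensation = FALSE, tau = 10, gamma = 1,
                           replicate_noise_sd = 0, n_replicates = 1, seed = 3)
  ds <- generate_expression_dataset(ps)
  ms <- merge(as.data.frame(ds), attr(ds, "baseline"), by = "gene_id")
  hi_x <- ms$chromosome == "X" & ms$baseline_e > 10
  expect_equal(ms$fpkm[hi_x],
               0.65 * ms$baseline_e[hi_x] * (10 / ms$baseline_e[hi_x]))
})

test_that("females and compensated males carry unbuffered X expression", {
  p <- suppression_params(n_genes = 400, buffering_b = 0.65,
                          dosage_compensation = FALSE, tau = Inf, gamma = 0,
                          replicate_noise_sd = 0, n_replicates = 1, seed = 6)
  fem <- generate_expression_dataset(p, sex = "female")
  mf <- merge(as.data.frame(fem), attr(fem, "baseline"), by = "gene_id")
  expect_equal(mf$fpkm, mf$baseline_e)

  pc <- suppression_params(n_genes = 400, dosage_compensation = TRUE,
                           tau = Inf, gamma = 0, replicate_noise_sd = 0,
                           n_replicates = 1, seed = 6)
  som <- generate_expression_dataset(pc)
  mso <- merge(as.data.frame(som), attr(som, "baseline"), by = "gene_id")
  expect_equal(mso$fpkm, mso$baseline_e)
})

test_that("buffering recovery is consistent across the stated range of b", {
  for (b in c(0.5, 0.65, 1.0)) {
    est <- mean(vapply(1:6, function(s) {
      p <- suppression_params(n_genes = 8000, buffering_b = b,
                              dosage_compensation = FALSE, tau = Inf,
                              gamma = 0, seed = 500 + s)
      recover_buffering(generate_expression_dataset(p))$estimate
    }, numeric(1)))
    expect_lt(abs(est - b), 0.05)
  }
})

test_that("increasing gamma monotonically empties the top expression category", {
  tau <- qlnorm(0.8, 2, 1.5)
  top_count <- vapply(c(0, 0.5, 1, 2), function(g) {
    p <- suppression_params(n_genes = 6000, buffering_b = 0.65,
                            dosage_compensation = FALSE, tau = tau,
                            gamma = g, seed = 77)   # coupled via shared seed
    d <- generate_expression_dataset(p)
    tab <- build_tissue_table(d)
    cc <- categorize_cumulative(tab, thresholds = c(1, 50))
    cc$n_x_obs[cc$threshold == 50]
  }, integer(1))
  expect_true(all(diff(top_count) <= 0))
  expect_lt(top_count[4], top_count[1])
})

test_that("noise-free reporter generation reproduces the threshold model", {
  cons <- data.frame(construct = c("lo", "hi"), activity = c(1, 10))
  d <- generate_reporter_dataset(cons, tau = 5, gamma = 1,
                                 n_lines_per_class = 2, n_bio = 2, n_tech = 2,
                                 line_sd = 0, bio_sd = 0, tech_sd = 0, seed = 2)
  s <- summarize_lines(d[d$construct == "lo", ])
  expect_equal(mean(s$mean_activity[s$chromosome_class == "A"]),
               mean(s$mean_activity[s$chromosome_class == "X"]))
  s_hi <- summarize_lines(d[d$construct == "hi", ])
  ratio <- suppression_ratio(
    mean(s_hi$mean_activity[s_hi$chromosome_class == "A"]),
    mean(s_hi$mean_activity[s_hi$chromosome_class == "X"]))
  expect_equal(ratio, 2.0)   # activity = 2 tau, gamma = 1 -> f = 0.5
})

test_that("fly-count metadata round-trips through the reporter pipeline", {
  cons <- data.frame(construct = "c6", activity = 4, flies_per_assay = 6)
  d <- generate_reporter_dataset(cons, tau = Inf, gamma = 0,
                                 n_lines_per_class = 1, n_bio = 1, n_tech = 1,
                                 line_sd = 0, bio_sd = 0, tech_sd = 0, seed = 4)
  expect_equal(d$activity_mOD_min, rep(4 * 6 / 5, 2))  # raw reads higher
  s <- summarize_lines(d)
  expect_equal(s$mean_activity, rep(4, 2))             # normalization undoes it
})

test_that("a positive expression-suppression association is recoverable", {
  cons <- data.frame(construct = paste0("c", 1:5),
                     activity = c(0.2, 1, 4, 12, 30))
  d <- generate_reporter_dataset(cons, tau = 2, gamma = 0.8,
                                 n_lines_per_class = 3, n_bio = 3, n_tech = 2,
                                 seed = 15)
  pts <- do.call(rbind, lapply(split(d, d$construct), function(sub) {
    s <- summarize_lines(sub)
    cmp <- compare_classes(s)
    data.frame(autosomal_expression = cmp$mean_a,
               suppression_ratio = suppression_ratio(cmp$mean_a, cmp$mean_x))
  }))
  fit <- suppression_vs_expression(pts)
  expect_gt(fit$slope, 0)
  expect_gt(fit$r_squared, 0.5)
})
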