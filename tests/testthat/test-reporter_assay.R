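test_that("line summary averages the replicate hierarchy in order", {
  one_bio <- rbind(assay_row("L1", "A", "b1", "t1", 2.0),
                   assay_row("L1", "A", "b1", "t2", 4.0))
  expect_equal(summarize_line(one_bio)$mean_activity, 3.0)

  two_bio <- rbind(assay_row("L1", "A", "b1", "t1", 2.0),
                   assay_row("L1", "A", "b1", "t2", 4.0),
                   assay_row("L1", "A", "b2", "t1", 5.0))
  s <- summarize_line(two_bio)
  expect_equal(s$mean_activity, 4.0)   # mean of bio means 3 and 5
  expect_equal(s$n_bio_reps, 2)
  expect_equal(s$sd_activity, sd(c(3, 5)))

  # hierarchy matters: pooling all four raw values would give 3.67, not 4.25
  uneven <- rbind(assay_row("L1", "A", "b1", "t1", 2.0),
                  assay_row("L1", "A", "b1", "t2", 3.0),
                  assay_row("L1", "A", "b1", "t3", 4.0),
                  assay_row("L1", "A", "b2", "t1", 5.5))
  expect_equal(summarize_line(uneven)$mean_activity, (3 + 5.5) / 2)

  mixed <- rbind(assay_row("L1", "A", "b1", "t1", 2.0),
                 assay_row("L1", "A", "b1", "t2", 4.0, tissue = "head"))
  expect_error(summarize_line(mixed), "mixed tissues")
})

test_that("fly-count normalization rescales measurements before averaging", {
  six <- assay_row("L1", "A", "b1", "t1", 6.0, flies = 6)
  expect_equal(summarize_line(six, normalize_to = 5)$mean_activity, 5.0)
  mixed_flies <- rbind(assay_row("L1", "A", "b1", "t1", 6.0, flies = 6),
                       assay_row("L1", "A", "b1", "t2", 5.0, flies = 5))
  expect_equal(summarize_line(mixed_flies)$mean_activity, 5.0)
})

test_that("line summary is invariant to row order", {
  rows <- rbind(assay_row("L1", "X", "b1", "t1", 1.0),
                assay_row("L1", "X", "b1", "t2", 3.0),
                assay_row("L1", "X", "b2", "t1", 2.0),
                assay_row("L1", "X", "b2", "t2", 6.0))
  expect_equal(summarize_line(rows[c(4, 1, 3, 2), ]), summarize_line(rows))
})

test_that("class comparison: rank test on line means, exclusions, controls", {
  summ <- data.frame(
    line_id = c("A1", "A2", "A3", "X1", "X2", "X3", "yw"),
    chromosome_class = c("A", "A", "A", "X", "X", "X", "control"),
    tissue = "testis", n_bio_reps = 3,
    mean_activity = c(1, 2, 3, 4, 5, 6, -0.05),
    sd_activity = 0.1, stringsAsFactors = FALSE
  )
  cmp <- compare_classes(summ)
  expect_equal(cmp$p_value, 0.1)
  expect_equal(cmp$p_value, exact_ranksum_p(c(4, 5, 6), c(1, 2, 3)))
  expect_equal(cmp$n_a, 3)
  expect_equal(cmp$control$mean, -0.05)

  excl <- compare_classes(summ, exclude_lines = "A1")
  expect_equal(excl$n_a, cmp$n_a - 1)
  expect_equal(excl$mean_x, cmp$mean_x)
  expect_equal(excl$median_x, cmp$median_x)

  # identical class distributions -> p = 1
  same <- summ[c(1:3, 1:3), ]
  same$chromosome_class <- rep(c("A", "X"), each = 3)
  same$line_id <- paste0("L", 1:6)
  expect_equal(compare_classes(same)$p_value, 1)

  # common positive rescaling preserves ranks, hence the p-value
  scaled <- summ
  scaled$mean_activity <- scaled$mean_activity * 12.7
  expect_equal(compare_classes(scaled)$p_value, cmp$p_value)

  expect_error(compare_classes(summ[summ$chromosome_class != "A", ]),
               "at least one line per class")
})

test_that("suppression ratio is the A/X quotient of class means", {
  expect_equal(suppression_ratio(0.18, 0.25), 0.72)
  expect_equal(suppression_ratio(1, 1), 1.0)
  expect_equal(suppression_ratio(4, 2), 2.0)
  expect_error(suppression_ratio(1, 0), "positive")
})

test_that("suppression-vs-expression regression matches the closed form", {
  perfect <- data.frame(autosomal_expression = 1:3, suppression_ratio = 1:3)
  fit <- suppressWarnings(suppression_vs_expression(perfect))
  expect_equal(fit$r_squared, 1)
  expect_equal(fit$slope, 1)

  flat <- data.frame(autosomal_expression = 1:3,
                     suppression_ratio = c(2, 2, 2))
  expect_equal(suppressWarnings(suppression_vs_expression(flat))$r_squared, 0)

  set.seed(88)
  x <- c(0.5, 2, 5, 11, 24)
  y <- 1 + 0.08 * x + rnorm(5, sd = 0.2)
  pts <- data.frame(autosomal_expression = x, suppression_ratio = y)
  fit2 <- suppression_vs_expression(pts)
  expect_equal(fit2$r_squared, r_squared_formula(x, y))

  const <- data.frame(autosomal_expression = c(2, 2, 2),
                      suppression_ratio = 1:3)
  expect_error(suppression_vs_expression(const), "constant predictor")
  expect_error(suppression_vs_expression(perfect[1:2, ]), "at least 3")
})

test_that("reporter tables round-trip through CSV and TSV", {
  rows <- rbind(assay_row("L1", "A", "b1", "t1", 2.0),
                assay_row("L1", "A", "b1", "t2", 4.0),
                assay_row("X9", "X", "b1", "t1", 1.5))
  for (ext in c(".csv", ".tsv")) {
    path <- tempfile(fileext = ext)
    write.table(rows, path, sep = if (ext == ".csv") "," else "\t",
                quote = FALSE, row.names = FALSE)
    back <- read_reporter_table(path)
    expect_equal(as.data.frame(back), rows, ignore_attr = TRUE)
  }
})
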