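# Expression fold changes, growth metrics, t-tests and the regression
# layer.

test_that("ddCq fold changes follow 2^-ddCq and are shift-consistent", {
  rec <- tibble::tibble(
    condition = rep(c("ctr", "up", "down"), each = 3),
    gene = "target", replicate = rep(1:3, 3),
    cq_target = c(20, 20, 20, 19, 19, 19, 23.32, 23.32, 23.32),
    cq_reference = 15
  )
  out <- ddcq_fold_change(rec, control = "ctr")
  expect_equal(out$fold_change[out$condition == "ctr"], 1)
  expect_equal(out$fold_change[out$condition == "up"], 2)
  expect_equal(out$fold_change[out$condition == "down"], 2^(-3.32))
  expect_lt(abs(out$fold_change[out$condition == "down"] - 0.1), 0.001)

  shifted <- dplyr::mutate(rec, cq_target = cq_target + 3.7,
                           cq_reference = cq_reference + 3.7)
  expect_equal(ddcq_fold_change(shifted, "ctr")$fold_change, out$fold_change)
  expect_error(ddcq_fold_change(rec[, -4], "ctr"), "columns")
  expect_error(ddcq_fold_change(rec, "absent"), "not present")
})

test_that("population doubling matches the base-10 formula", {
  expect_equal(population_doubling(100, 100), 0)
  expect_equal(population_doubling(100, 200), 1.002, tolerance = 1e-3)
  expect_equal(population_doubling(100, 1000), 3.33)
  expect_error(population_doubling(0, 10), "positive")
})

test_that("ttest_unpaired equals the closed-form pooled t on random samples", {
  set.seed(2024)
  for (i in 1:200) {
    a <- rnorm(sample(2:8, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 2))
    b <- rnorm(sample(2:8, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 2))
    got <- ttest_unpaired(a, b)
    want <- oracle_t(a, b)
    expect_equal(got$t, want$t, tolerance = 1e-12)
    expect_equal(got$df, want$df)
    expect_equal(got$p_value, want$p, tolerance = 1e-12)
  }
})

test_that("degenerate and annotated t-test cases behave as documented", {
  same <- c(1, 2, 3, 4, 5)
  res <- ttest_unpaired(same, same)
  expect_equal(res$t, 0)
  expect_equal(res$p_value, 1)
  expect_identical(res$stars, "ns")

  res2 <- ttest_unpaired(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
  want <- oracle_t(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
  expect_equal(res2$t, want$t)
  expect_equal(res2$p_value, want$p)

  expect_identical(significance_stars(c(0.03, 0.004, 5e-4, 0.2)),
                   c("*", "**", "***", "ns"))
  expect_error(ttest_unpaired(c(1, 1), c(2, 2)), "degenerate")
  expect_identical(ttest_unpaired(c(1, 1), c(1, 1))$p_value, 1)
})

test_that("group regression recovers exact lines and rejects degenerates", {
  d <- tibble::tibble(x = 1:5, y = 2 * (1:5) + 1)
  fit <- group_linear_regression(d, "x", "y")
  g <- glance(fit)
  expect_equal(g$slope, 2)
  expect_equal(g$intercept, 1)
  expect_equal(g$r_squared, 1)

  flat <- tibble::tibble(x = 1:5, y = rep(3, 5))
  gf <- glance(group_linear_regression(flat, "x", "y"))
  expect_equal(gf$slope, 0)
  expect_equal(gf$r_squared, 0)

  expect_error(group_linear_regression(d[1:2, ], "x", "y"), "3 paired")
  expect_error(group_linear_regression(tibble::tibble(x = rep(1, 4), y = 1:4),
                                       "x", "y"), "variance in predictor")
  td <- tidy(fit)
  expect_identical(td$term, c("(Intercept)", "x"))
})

test_that("regression layer recovers slopes with controlled type-I error", {
  set.seed(91)
  # slope recovery across replicated 6-condition tables
  slopes <- replicate(100, {
    x <- seq(0, 1.25, length.out = 6)
    y <- 0.9 - 0.5 * x + rnorm(6, 0, 0.1)
    glance(group_linear_regression(tibble::tibble(x = x, y = y), "x", "y"))$slope
  })
  expect_lt(abs(mean(slopes) - (-0.5)) / 0.5, 0.05)

  # nominal 5% test under the null
  rejections <- replicate(400, {
    x <- seq(0, 1.25, length.out = 6)
    y <- 0.9 + rnorm(6, 0, 0.1)
    glance(group_linear_regression(tibble::tibble(x = x, y = y), "x", "y"))$p_value < 0.05
  })
  expect_lte(mean(rejections), 0.07)
})

test_that("the correlation table joins, regresses, and is order invariant", {
  rim <- tibble::tibble(condition = c("a", "b", "c", "d", "e", "f"),
                        pct_positive_rim = c(80, 70, 62, 55, 41, 30))
  morpho <- tibble::tibble(condition = rim$condition,
                           aberration_index_mean = seq(0, 1, length.out = 6))
  expr <- tidyr::expand_grid(condition = rim$condition,
                             protein = c("lamin_a", "lamin_c"))
  set.seed(3); expr$level <- runif(nrow(expr), 0.5, 1.5)

  res <- build_correlation_table(rim, morpho, expr)
  expect_s3_class(res, "rim_correlation")
  expect_identical(nrow(res$table), 6L)
  expect_true("merged_lamin_morpho" %in% names(res$table))
  ab <- dplyr::filter(res$regressions, .data$x == "aberration_index_mean")
  expect_lt(ab$slope, 0)

  shuffled <- build_correlation_table(rim[sample(6), ], morpho[sample(6), ],
                                      expr[sample(nrow(expr)), ])
  expect_equal(shuffled$table, res$table)
  expect_equal(shuffled$regressions, res$regressions)

  expect_error(build_correlation_table(rim[1:5, ], morpho, expr), "unmatched")

  one <- build_correlation_table(rim[1, ], morpho[1, ], expr[expr$condition == "a", ])
  expect_true(all(is.na(one$regressions$slope)))
})
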