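test_that("threshold is the interpolated order-statistic quantile", {
  expect_warning(t5 <- compute_threshold(c(5, 5, 5, 5), 0.995), "100")
  expect_equal(t5, 5)

  x <- 1:1000
  expect_equal(compute_threshold(x, 0.995), oracle_quantile(x, 0.995))
  set.seed(1)
  y <- rlnorm(5000, 2, 1)
  expect_equal(compute_threshold(y, 0.995), oracle_quantile(y, 0.995))

  expect_error(compute_threshold(numeric(0)), "empty")
  expect_error(compute_threshold(1:200, 1.2), "quantile")
})

test_that("fraction of controls strictly above their own threshold is bounded", {
  set.seed(2)
  for (n in c(200, 1000, 10000)) {
    x <- rnorm(n)
    thr <- compute_threshold(x, 0.995)
    expect_lte(mean(x > thr), 0.005)
  }
})

test_that("transfection gating is strict and recovers the planted fraction", {
  tab <- data.frame(fp_cell = c(1, 2, 3))
  expect_identical(flag_transfected(tab, 2)$transfected, c(FALSE, FALSE, TRUE))
  expect_identical(flag_transfected(tab, 10)$transfected, rep(FALSE, 3))

  sim <- simulate_cell_table(n_cells = 10000, transfected_fraction = 0.5,
                             seed = 5)
  ctl <- simulate_controls(n_cells = 10000, seed = 6)
  t_fp <- compute_threshold(ctl$mock$fp_cell)
  est <- mean(flag_transfected(sim$cells, t_fp)$transfected)
  se <- sqrt(0.5 * 0.5 / 10000)
  expect_lt(abs(est - 0.5), 3 * se)
})

test_that("f+ uses a strict threshold and is undefined when empty", {
  expect_equal(fraction_stained(c(1, 2, 3, 4), 2.5), 0.5)
  expect_equal(fraction_stained(c(1, 2), 5), 0)
  expect_true(is.na(fraction_stained(numeric(0), 1)))
  # monotone non-increasing in the threshold
  set.seed(3)
  ab <- rnorm(500)
  ts <- sort(runif(20, -2, 2))
  f <- vapply(ts, function(t) fraction_stained(ab, t), 0)
  expect_true(all(diff(f) <= 0))
  expect_true(all(f >= 0 & f <= 1))
})

test_that("mean surface signal keeps negatives; normalization divides", {
  expect_equal(mean_surface_signal(c(-1, 1)), 0)
  expect_true(is.na(mean_surface_signal(numeric(0))))
  expect_equal(normalize_ab(2, 4), 0.5)
  expect_equal(normalize_ab(3, 3), 1)
  expect_error(normalize_ab(1, 0), "positive")
  expect_error(normalize_ab(1, -2), "positive")
})

test_that("bin edges are geometric or equal-count as requested", {
  b <- define_bins(c(1, 100), n_bins = 2, mode = "log_spaced")
  expect_equal(b$edges, c(1, 10, 100))

  set.seed(4)
  fp <- rlnorm(1000, 5, 1)
  bq <- define_bins(fp, n_bins = 10, mode = "equal_count")
  idx <- bin_assign(fp, bq)
  expect_equal(as.integer(table(idx)), rep(100, 10))

  expect_error(define_bins(fp, n_bins = 1), "at least 2")
})

test_that("every in-range cell lands in exactly one bin (linear-scan oracle)", {
  set.seed(9)
  fp <- rlnorm(2000, 4, 1.2)
  for (mode in c("log_spaced", "equal_count")) {
    b <- define_bins(fp, n_bins = 15, mode = mode)
    idx <- bin_assign(fp, b)
    expect_false(anyNA(idx))
    # oracle: first interval containing the value under half-open rules
    oracle <- vapply(fp, function(v) {
      for (j in seq_len(b$n_bins)) {
        hi_ok <- if (j == b$n_bins) v <= b$edges[j + 1] else v < b$edges[j + 1]
        if (v >= b$edges[j] && hi_ok) return(j)
      }
      NA_integer_
    }, 0L)
    expect_identical(idx, oracle)
    # partition: per-bin counts sum to the number of cells
    tab <- data.frame(fp_cell = fp, ab_cell = fp)
    expect_equal(sum(binned_dose(tab, b)$n), length(fp))
    # bin means lie inside their bin's edges
    bd <- binned_dose(tab, b)
    occ <- bd$n > 0
    expect_true(all(bd$fp_bin[occ] >= b$edges[bd$bin[occ]] &
                    bd$fp_bin[occ] <= b$edges[bd$bin[occ] + 1]))
  }
})

test_that("log-log slope fit handles exact, constant and degenerate input", {
  fp <- c(1, 10, 100, 1000)
  expect_equal(fit_esurface(fp, fp)$slope, 1, tolerance = 1e-12)
  expect_equal(fit_esurface(fp, rep(5, 4))$slope, 0, tolerance = 1e-12)
  f <- fit_esurface(fp, 2 * fp^0.7)
  expect_equal(f$slope, 0.7, tolerance = 1e-12)
  expect_equal(f$intercept, log(2), tolerance = 1e-12)

  # bins with non-positive ab are excluded, not log-transformed
  f2 <- fit_esurface(c(fp, 17), c(2 * fp^0.7, -3))
  expect_equal(f2$slope, 0.7, tolerance = 1e-12)
  expect_equal(f2$n_bins_used, 4)
  expect_equal(f2$n_bins_excluded, 1)

  f3 <- fit_esurface(c(1, 2), c(-1, -2))
  expect_true(is.na(f3$slope))
  expect_match(attr(f3, "diagnostic"), "bins")
})

test_that("Esurface is invariant to rescaling either channel", {
  set.seed(10)
  fp <- rlnorm(30, 3, 1)
  ab <- 0.3 * fp^1.2 * exp(0.1 * rnorm(30))
  base <- fit_esurface(fp, ab)$slope
  expect_equal(fit_esurface(3.7 * fp, ab)$slope, base, tolerance = 1e-10)
  expect_equal(fit_esurface(fp, 0.01 * ab)$slope, base, tolerance = 1e-10)
  expect_equal(fit_esurface(5 * fp, 9 * ab)$slope, base, tolerance = 1e-10)
})
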