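# Baseline estimation, dF/F0 conversion and the smoothing operators.

test_that("temporal-median baseline handles constants, identity windows and the hand-worked case", {
  expect_equal(compute_f0_temporal_median(rep(100, 50), 25), rep(100, 50))
  v <- rnorm(20)
  expect_equal(compute_f0_temporal_median(v, 1), v)
  expect_equal(compute_f0_temporal_median(c(100, 100, 100, 110, 100), 3),
               rep(100, 5))
})

test_that("temporal median rejects bad windows and warns on even ones", {
  expect_error(compute_f0_temporal_median(rnorm(10), 11), "exceeds")
  expect_error(compute_f0_temporal_median(rnorm(10), 0), "positive")
  expect_warning(f0 <- compute_f0_temporal_median(rep(1, 10), 4), "even")
  expect_equal(f0, rep(1, 10))
})

test_that("rolling median agrees with the brute-force shrinking-window oracle", {
  withr::with_seed(11, {
    for (rep in 1:20) {
      n <- sample(50:300, 1)
      v <- rnorm(n)
      k <- sample(c(3, 5, 25), 1)
      if (k > n) k <- 3
      expect_equal(compute_f0_temporal_median(v, k),
                   naive_rolling_median(v, k))
    }
  })
})

test_that("dF/F0 follows the sign convention for each polarity", {
  ts_pos <- trace_set(matrix(c(100, 110, 100), 1), 1, modality = "calcium")
  d <- compute_dff(ts_pos, matrix(100, 1, 3))
  expect_equal(as.vector(as.matrix(d)), c(0, 0.10, 0))

  ts_neg <- trace_set(matrix(c(100, 97.5, 100), 1), 1, modality = "voltage")
  d <- compute_dff(ts_neg, matrix(100, 1, 3))
  # a 2.5% dimming spike is stored as +0.025
  expect_equal(as.vector(as.matrix(d)), c(0, 0.025, 0))
})

test_that("dF/F0 is gain-invariant but offset-sensitive, and guards the baseline", {
  withr::with_seed(2, f <- matrix(100 + rnorm(200), 2))
  ts <- trace_set(f, 1)
  f0 <- compute_f0_temporal_median(ts, 25)
  d1 <- as.matrix(compute_dff(ts, f0))
  ts_scaled <- trace_set(3.7 * f, 1)
  d2 <- as.matrix(compute_dff(ts_scaled, 3.7 * f0))
  expect_equal(d1, d2)
  ts_offset <- trace_set(f + 50, 1)
  d3 <- as.matrix(compute_dff(ts_offset, f0 + 50))
  expect_gt(max(abs(d3 - d1)), 1e-4)
  expect_error(compute_dff(ts, f0 * 0), "zero/negative")
})

test_that("sliding-percentile baseline is causal and matches the interpolation oracle", {
  expect_equal(compute_f0_sliding_percentile(rep(5, 40), window_s = 0.01),
               rep(5, 40))
  v <- seq_len(100)
  expect_true(all(compute_f0_sliding_percentile(v, window_s = 0.02) <= v))
  # hand case: 25th percentile of [10,10,10,20] (type-7 interpolation)
  b <- compute_f0_sliding_percentile(c(10, 10, 10, 20), window_s = 1)
  expect_equal(b[4], 10)
  withr::with_seed(12, {
    for (rep in 1:10) {
      v <- rnorm(200)
      w <- sample(c(5, 20, 60), 1)
      expect_equal(
        compute_f0_sliding_percentile(v, window_s = w / 1000,
                                      percentile = 25),
        naive_sliding_percentile(v, w, 0.25))
    }
  })
})

test_that("pre-stimulus mean baseline averages the window before onset", {
  ts <- trace_set(matrix(c(90, 110, 200, 200), 1), frame_interval_ms = 1000)
  expect_equal(unname(compute_f0_prestim_mean(ts, 2000, pre_window_s = 2)),
               100)
  ramp <- trace_set(matrix(1:10, 1), frame_interval_ms = 1000)
  expect_equal(unname(compute_f0_prestim_mean(ramp, 10000, 10)), mean(1:10))
  expect_error(compute_f0_prestim_mean(ts, 500, pre_window_s = 2),
               "earlier")
})

test_that("polynomial drift removal flattens cubics, preserves spikes and demeans at degree 0", {
  tt <- seq(-1, 1, length.out = 500)
  cubic <- 2 + tt - 3 * tt^2 + 0.5 * tt^3
  out <- remove_drift_polyfit(cubic, 3)
  expect_lt(max(abs(out)), 1e-9 * max(abs(cubic)))

  kern <- exp(-(0:20) / 3) - exp(-(0:20) / 0.5)
  kern <- kern / max(kern) * 0.025
  spiked <- cubic
  spiked[240:260] <- spiked[240:260] + kern
  resid <- remove_drift_polyfit(spiked, 3)
  expect_lt(abs(max(resid) - 0.025) / 0.025, 0.1)

  v <- rnorm(50) + 3
  expect_equal(remove_drift_polyfit(v, 0), v - mean(v))
  expect_error(remove_drift_polyfit(rnorm(3), 3), "frames")
})

test_that("Savitzky-Golay smoothing preserves low-order polynomials and shrinks noise", {
  lin <- seq(0, 1, length.out = 100)
  expect_equal(smooth_savitzky_golay(lin), lin, tolerance = 1e-9)
  expect_equal(smooth_savitzky_golay(rep(2, 50)), rep(2, 50))
  withr::with_seed(3, {
    shrunk <- vapply(1:10, function(i) {
      v <- rnorm(500)
      var(smooth_savitzky_golay(v)) < var(v)
    }, logical(1))
    expect_true(all(shrunk))
  })
  expect_error(smooth_savitzky_golay(rnorm(10), window_frames = 4), "odd")
  expect_error(smooth_savitzky_golay(rnorm(10), window_frames = 3,
                                     polyorder = 3), "odd")
})

test_that("temporal median filtering removes single-frame outliers and keeps structure", {
  v <- rep(1, 20); v[10] <- 50
  expect_equal(median_filter_temporal(v, 3), rep(1, 20))
  expect_equal(median_filter_temporal(rep(4, 10), 3), rep(4, 10))
  expect_equal(median_filter_temporal(c(0, 0, 1, 1, 1, 0), 3),
               c(0, 0, 1, 1, 1, 0))
})

test_that("trace operators preserve shape, ROI order and class", {
  withr::with_seed(4, f <- matrix(100 + rnorm(300), 3))
  ts <- trace_set(f, 2, roi_ids = c("c", "a", "b"))
  d <- compute_dff(ts, compute_f0_temporal_median(ts, 11))
  for (out in list(remove_drift_polyfit(d), smooth_savitzky_golay(d),
                   median_filter_temporal(d))) {
    expect_s3_class(out, "dff_set")
    expect_equal(dim(out), dim(d))
    expect_equal(out$roi_ids, c("c", "a", "b"))
  }
})
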