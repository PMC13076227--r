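# Spike detection, spike-triggered averaging, half-rise and latency maps.

make_kernel <- function(dt = 1, amp = 0.025) {
  kt <- seq(0, 24, by = dt)
  k <- exp(-kt / 3) - exp(-kt / 0.5)
  k / max(k) * amp
}

inject_kernels <- function(n_frames, at, kern, noise_sd, seed) {
  withr::with_seed(seed, {
    v <- rnorm(n_frames, 0, noise_sd)
    for (t0 in at) {
      idx <- t0 + seq_along(kern) - 1
      v[idx] <- v[idx] + kern
    }
    v
  })
}

test_that("flat and constant traces produce no spikes without error", {
  expect_equal(nrow(detect_spikes(rep(1, 100))), 0)
  sp <- detect_spikes(rep(0, 100))
  expect_s3_class(sp, "spike_trains")
  expect_equal(attr(sp, "detection")$n_spikes, 0L)
})

test_that("injected spike kernels are recovered at 3 SD with at most noise-level extras", {
  at <- seq(200, 9800, by = 480)[1:20]
  kern <- make_kernel()
  peak_times <- at + which.max(kern) - 2  # kernel peak, 0-based ms
  extras <- vapply(1:5, function(s) {
    v <- inject_kernels(10000, at, kern, noise_sd = 0.004, seed = s)
    sp <- detect_spikes(smooth_savitzky_golay(v), k_sd = 3)
    matched <- vapply(peak_times, function(t0) {
      any(abs(sp$time_ms - t0) <= 1)
    }, logical(1))
    expect_true(all(matched))
    nrow(sp) - sum(vapply(sp$time_ms, function(t0) {
      any(abs(peak_times - t0) <= 1)
    }, logical(1)))
  }, numeric(1))
  # at this threshold (~3.6 sigma of the smoothed noise) the expected
  # number of pure-noise peaks is ~0.4 per 10 s trace
  expect_lte(mean(extras), 1)
})

test_that("false-positive rate on pure noise at 3 SD stays below 0.3% of frames", {
  rates <- vapply(1:10, function(s) {
    v <- withr::with_seed(500 + s, rnorm(10000, 0, 0.004))
    nrow(detect_spikes(smooth_savitzky_golay(v), k_sd = 3)) / 10000
  }, numeric(1))
  expect_lt(max(rates), 0.003)
})

test_that("spike count is nonincreasing in the threshold multiplier", {
  kern <- make_kernel()
  v <- inject_kernels(20000, seq(100, 19500, by = 650), kern, 0.004, 7)
  counts <- vapply(c(1.5, 2, 3, 5), function(k) {
    nrow(detect_spikes(v, k_sd = k))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("detection is invariant to multiplicative rescaling", {
  kern <- make_kernel()
  v <- inject_kernels(5000, seq(100, 4500, by = 700), kern, 0.004, 9)
  expect_equal(detect_spikes(v, 3)$time_ms, detect_spikes(17 * v, 3)$time_ms)
})

test_that("refractory resolution keeps the larger peak, ties keep the earlier", {
  v <- rep(0, 50)
  v[c(10, 12)] <- c(0.5, 1)  # close pair: keep the larger (frame 12)
  v[c(30, 32)] <- c(1, 1)    # tie: keep the earlier (frame 30)
  sp <- detect_spikes(v, k_sd = 1, refractory_ms = 3)
  expect_equal(sp$time_ms, c(11, 29))
})

test_that("single-event STA equals the snippet and zero traces give zero STA", {
  withr::with_seed(31, v <- rnorm(200))
  sta <- spike_triggered_average(v, 100, lag_window_ms = c(-5, 10))
  expect_equal(as.vector(sta$sta), v[96:111])
  expect_equal(sta$n_events, 1)
  sta0 <- spike_triggered_average(rep(0, 200), c(50, 100, 150), c(-5, 5))
  expect_true(all(sta0$sta == 0))
})

test_that("STA drops events without a full window and errors when none remain", {
  v <- rnorm(100)
  sta <- spike_triggered_average(v, c(2, 50, 99), lag_window_ms = c(-10, 10))
  expect_equal(sta$n_events, 1)
  expect_equal(sta$n_dropped, 2)
  expect_error(spike_triggered_average(v, c(2), c(-10, 10)), "no reference")
})

test_that("averaging 65 noisy events shrinks residual noise like 1/sqrt(n)", {
  kern <- make_kernel()
  wave <- c(rep(0, 20), kern, rep(0, 20))
  sigma <- 0.01
  ratio <- vapply(1:10, function(s) {
    withr::with_seed(600 + s, {
      n_ev <- 65
      gap <- length(wave)
      v <- rep(wave, n_ev) + rnorm(gap * n_ev, 0, sigma)
      events <- (seq_len(n_ev) - 1) * gap + 20
      sta <- spike_triggered_average(v, events, c(0, 24))
      sd(as.vector(sta$sta) - wave[21:45]) / (sigma / sqrt(n_ev))
    })
  }, numeric(1))
  expect_lt(abs(mean(ratio) - 1), 0.2)
})

test_that("STA is linear in the traces for shared events", {
  withr::with_seed(41, {
    x <- matrix(rnorm(600), 2)
    y <- matrix(rnorm(600), 2)
  })
  ev <- c(60, 150, 250)
  sab <- spike_triggered_average(2 * x + 3 * y, ev, c(-5, 5))
  sa <- spike_triggered_average(x, ev, c(-5, 5))
  sb <- spike_triggered_average(y, ev, c(-5, 5))
  expect_equal(sab$sta, 2 * sa$sta + 3 * sb$sta)
})

test_that("half-rise interpolation matches the hand-worked cases", {
  expect_equal(as.numeric(half_rise_time(c(0, 0, 1, 1))), 1.5)
  expect_equal(as.numeric(half_rise_time(c(0, 0, 0.5, 1),
                                         baseline_window = 1:2)), 2.0)
  # inclusion rule: peak must clear baseline mean + 5 SD
  wf <- c(0.1, -0.1, 0.1, -0.1, 0.15, 0.1, 0)
  out <- half_rise_time(wf, baseline_window = 1:4, inclusion_sd = 5)
  expect_true(is.na(out))
  expect_false(attr(out, "included"))
})

test_that("latency maps recover noiseless shifts and zero for identical waveforms", {
  wave <- c(rep(0, 10), make_kernel(), rep(0, 10))
  m <- rbind(wave, wave)
  sta <- structure(list(sta = m, lag_ms = seq_len(ncol(m)) - 11,
                        n_events = 10, n_dropped = 0,
                        frame_interval_ms = 1,
                        roi_ids = c("soma", "tip")),
                   class = "sta_result")
  lm0 <- backprop_latency_map(sta, "soma", baseline_window = 1:8)
  expect_equal(lm0$latency_ms, c(0, 0))

  shifted <- rbind(wave, c(rep(0, 2), wave[1:(length(wave) - 2)]))
  sta2 <- sta; sta2$sta <- shifted
  lm2 <- backprop_latency_map(sta2, 1, baseline_window = 1:8)
  expect_equal(lm2$latency_ms[2], 2.0)
})

test_that("odor-response amplitude reports signed step responses", {
  n <- 30
  flat <- trace_set(matrix(100, 1, n), 1000, modality = "calcium")
  expect_equal(odor_response_amplitude(flat, 15000)$amplitude, 0)
  step_up <- matrix(c(rep(100, 15), rep(110, 15)), 1)
  r <- odor_response_amplitude(trace_set(step_up, 1000, modality = "calcium"),
                               15000)
  expect_equal(r$amplitude, 0.10)
  expect_equal(r$f0, 100)
  step_dn <- matrix(c(rep(100, 15), rep(95, 15)), 1)
  r2 <- odor_response_amplitude(trace_set(step_dn, 1000,
                                          modality = "calcium"), 15000)
  expect_equal(r2$amplitude, -0.05)
  expect_error(odor_response_amplitude(flat, 25000), "beyond")
})

test_that("calcium-transient detection ignores single-frame artifacts but finds slow kernels", {
  v <- rep(0, 2000); v[500] <- 1
  v <- v + withr::with_seed(8, rnorm(2000, 0, 0.01))
  # the raw artifact is a detectable "spike"; the median filter removes it
  expect_true(any(abs(detect_spikes(v, k_sd = 3)$time_ms - 499) <= 1))
  filtered <- detect_calcium_transients(v, k_sd = 3)
  expect_false(any(abs(filtered$time_ms - 499) <= 5))

  kern <- exp(-(0:300) / 50) - exp(-(0:300) / 5)
  kern <- kern / max(kern) * 0.05
  at <- seq(100, 9000, by = 450)
  recovered <- vapply(1:5, function(s) {
    v <- inject_kernels(10000, at, kern, noise_sd = 0.01, seed = 700 + s)
    sp <- detect_calcium_transients(v, k_sd = 3)
    mean(vapply(at, function(t0) {
      any(sp$time_ms >= t0 & sp$time_ms <= t0 + 60)
    }, logical(1)))
  }, numeric(1))
  expect_gte(mean(recovered), 0.95)
})
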