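# The synthetic voltage/tuning generators and their ground truth.

test_that("identical config and seed reproduce the dataset bitwise", {
  cfg <- quick_config(duration_s = 2, seed = 9)
  a <- simulate_voltage_dataset(cfg)
  b <- simulate_voltage_dataset(cfg)
  expect_identical(a$traces$f, b$traces$f)
  expect_identical(a$ground_truth, b$ground_truth)
  c_ <- simulate_voltage_dataset(quick_config(duration_s = 2, seed = 10))
  expect_false(identical(a$traces$f, c_$traces$f))
})

test_that("config validation rejects impossible settings", {
  expect_error(sim_config(duration_s = 0), "duration_s")
  expect_error(sim_config(frame_interval_ms = -1), "frame_interval_ms")
  expect_error(sim_config(sister_coupling = 1.2), "sister_coupling")
  expect_error(sim_config(spike_rate_hz = -2), "nonnegative")
})

test_that("noiseless two-ROI neuron yields traces identical up to the latency shift", {
  cfg <- sim_config(n_glomeruli = 1, neurons_per_glomerulus = 1,
                    rois_per_neuron = 2, duration_s = 5,
                    backprop_latency_ms = c(0, 2),
                    backprop_jitter_sd_ms = 0, noise_sd_dff = 0,
                    subthreshold_amplitude_dff = 0, drift = c(0),
                    seed = 21)
  ds <- simulate_voltage_dataset(cfg)
  f <- ds$traces$f
  n <- ncol(f)
  expect_equal(f[2, 3:n], unname(f[1, 1:(n - 2)]), tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("ground-truth hierarchy is consistent and trains respect the refractory period", {
  ds <- simulate_voltage_dataset(quick_config(duration_s = 5, seed = 33))
  gt <- ds$ground_truth
  expect_true(all(gt$neuron_of_roi %in% seq_along(gt$true_spike_times_ms)))
  expect_length(gt$glomerulus_of_neuron, length(gt$true_spike_times_ms))
  dur <- ds$config$duration_s * 1000
  for (tr in gt$true_spike_times_ms) {
    expect_false(is.unsorted(tr))
    expect_true(!length(tr) || (min(tr) > 0 && max(tr) < dur))
    if (length(tr) > 1) expect_gt(min(diff(tr)), ds$config$refractory_ms)
  }
  expect_true(all(gt$theta_phase >= -pi & gt$theta_phase < pi))
})

test_that("sister-pair spike coincidence grows with the coupling parameter", {
  mean_si <- function(coupling) {
    mean(vapply(1:20, function(s) {
      ds <- simulate_voltage_dataset(sim_config(
        n_glomeruli = 1, neurons_per_glomerulus = 2, rois_per_neuron = 1,
        duration_s = 20, sister_coupling = coupling, seed = 100 + s))
      tr <- ds$ground_truth$true_spike_times_ms
      as.numeric(synchronicity_index(tr[[1]], tr[[2]]))
    }, numeric(1)))
  }
  si <- vapply(c(0, 0.3, 0.8), mean_si, numeric(1))
  expect_lt(si[1], si[2])
  expect_lt(si[2], si[3])
  expect_gt(si[3], 0.6)
})

test_that("uncoupled independent Poisson neurons coincide at the analytic chance level", {
  # homogeneous spiking (no theta/subthreshold rate modulation)
  sis <- vapply(1:20, function(s) {
    ds <- simulate_voltage_dataset(sim_config(
      n_glomeruli = 2, neurons_per_glomerulus = 1, rois_per_neuron = 1,
      duration_s = 60, sister_coupling = 0, theta_rate_mod = 0,
      subthreshold_rate_mod = 0, seed = 400 + s))
    tr <- ds$ground_truth$true_spike_times_ms
    as.numeric(synchronicity_index(tr[[1]], tr[[2]]))
  }, numeric(1))
  # chance level 2 r w with the realised post-refractory rate
  ds <- simulate_voltage_dataset(sim_config(
    n_glomeruli = 2, neurons_per_glomerulus = 1, rois_per_neuron = 1,
    duration_s = 60, sister_coupling = 0, theta_rate_mod = 0, seed = 401))
  r_hat <- mean(lengths(ds$ground_truth$true_spike_times_ms)) / 60000
  expected <- 2 * r_hat * 7
  se <- sd(sis) / sqrt(length(sis))
  expect_lt(abs(mean(sis) - expected), 3 * se + 0.005)
})

test_that("tuning simulator reproduces the model exactly at zero noise and is seed-stable", {
  pars <- tibble::tibble(cell_id = "c1", baseline = 0.1, r_pref = 1,
                         r_opp = 0.5, theta_pref = 45, sigma = 25)
  td <- simulate_tuning_dataset(true_params = pars, repeats = 2,
                                noise_sd = 0, seed = 5)
  tuned <- td$trials[!is.na(td$trials$direction_deg), ]
  expect_equal(tuned$response,
               two_gaussian_response(tuned$direction_deg, 0.1, 1, 0.5, 45, 25))
  blanks <- td$trials[is.na(td$trials$direction_deg), ]
  expect_equal(blanks$response, rep(0.1, nrow(blanks)))

  a <- simulate_tuning_dataset(n_cells = 4, repeats = 3, seed = 7)
  b <- simulate_tuning_dataset(n_cells = 4, repeats = 3, seed = 7)
  expect_identical(a$trials, b$trials)

  flat <- simulate_tuning_dataset(
    true_params = tibble::tibble(cell_id = "f", baseline = 0.2, r_pref = 0,
                                 r_opp = 0, theta_pref = 0, sigma = 25),
    repeats = 3, noise_sd = 0, seed = 1)
  expect_true(all(flat$trials$response == 0.2))
  expect_error(simulate_tuning_dataset(repeats = 0), "repeats")
  expect_error(simulate_tuning_dataset(directions = c(0, 40, 90)), "evenly")
})
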