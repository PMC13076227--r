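# Theta-phase reference and spike-phase statistics.

#' Build a theta reference from glomerular traces
#'
#' Averages the supplied glomerular dF/F0 traces, band-pass filters the
#' average (zero-phase Butterworth, default 1-12 Hz, bracketing the
#' sniff-coupled theta band) and extracts the instantaneous phase of the
#' analytic signal. Phase 0 corresponds to the oscillation peak (the
#' -dF/F0 maximum).
#'
#' @param x A `dff_set`, numeric matrix (traces x frame) or vector of the
#'   glomerular signal(s).
#' @param band_hz Band-pass edges in Hz (default `c(1, 12)`).
#' @param frame_interval_ms Frame interval for bare matrices (default 1).
#' @return A `theta_reference`: list with `trace` (filtered reference),
#'   `phase` (radians per frame in \[-pi, pi)), `frame_interval_ms`,
#'   `band_hz`.
#' @export
build_theta_reference <- function(x, band_hz = c(1, 12),
                                  frame_interval_ms = 1) {
  m <- trace_matrix(x)
  if (nrow(m) < 1) abort("need at least one glomerular trace.")
  dt <- if (inherits(x, c("trace_set", "dff_set"))) x$frame_interval_ms
        else frame_interval_ms
  avg <- colMeans(m)
  fs <- 1000 / dt
  if (any(band_hz <= 0) || band_hz[2] <= band_hz[1] || band_hz[2] >= fs / 2) {
    abort("`band_hz` must satisfy 0 < low < high < Nyquist.")
  }
  n <- length(avg)
  if (n * dt < 3000 / band_hz[1]) {
    abort("trace shorter than the band-pass filter transient (need >= 3 periods of the low band edge).")
  }
  bf <- signal::butter(2, band_hz / (fs / 2), type = "pass")
  filt <- as.numeric(signal::filtfilt(bf, avg - mean(avg)))
  analytic <- analytic_signal(filt)
  structure(
    list(trace = filt, phase = atan2(Im(analytic), Re(analytic)),
         frame_interval_ms = dt, band_hz = band_hz),
    class = "theta_reference")
}

#' @export
print.theta_reference <- function(x, ...) {
  cat(sprintf("<theta_reference> %d frames @ %g ms, band %g-%g Hz\n",
              length(x$trace), x$frame_interval_ms, x$band_hz[1],
              x$band_hz[2]))
  invisible(x)
}

# analytic signal via the FFT: double positive frequencies, zero negative
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1, n / 2 + 1)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

circ_mean <- function(phi) atan2(mean(sin(phi)), mean(cos(phi)))
circ_resultant <- function(phi) sqrt(mean(sin(phi))^2 + mean(cos(phi))^2)

#' Spike phases relative to a theta reference
#'
#' Assigns each spike the instantaneous theta phase at its time (linear
#' interpolation of the unwrapped phase between frames) and summarises the
#' circular mean and resultant length per condition window. With exactly
#' two conditions the odor-evoked phase shift (circular difference of the
#' condition means) is reported.
#'
#' @param spikes `spike_trains` tibble, named list of trains, or a single
#'   numeric vector of spike times (ms).
#' @param reference A `theta_reference` from [build_theta_reference()];
#'   it must cover all spike times.
#' @param condition_windows Optional tibble with `condition`, `t0_ms`,
#'   `t1_ms` defining non-overlapping analysis windows; spikes outside all
#'   windows are dropped. Default: one window "all" spanning the
#'   recording.
#' @return A `phase_result`: list with `phases` (tibble `roi_id`,
#'   `time_ms`, `phase_rad`, `condition`) and `summary` (tibble
#'   `condition`, `n_spikes`, `circ_mean_rad`, `resultant`), plus
#'   `phase_shift_rad` when there are exactly two conditions.
#' @export
spike_phases <- function(spikes, reference, condition_windows = NULL) {
  stopifnot(inherits(reference, "theta_reference"))
  if (is.numeric(spikes)) {
    spikes <- tibble(roi_id = "train_1", time_ms = sort(spikes))
  } else if (is.list(spikes) && !is.data.frame(spikes)) {
    trains <- spike_train_list(spikes)
    spikes <- tibble(roi_id = rep(names(trains), lengths(trains)),
                     time_ms = unlist(trains, use.names = FALSE))
  }
  dt <- reference$frame_interval_ms
  tms <- (seq_along(reference$phase) - 1) * dt
  if (nrow(spikes) &&
      (min(spikes$time_ms) < 0 || max(spikes$time_ms) > tms[length(tms)])) {
    abort("spike times fall outside the span of the theta reference.")
  }
  unwrapped <- unwrap_phase(reference$phase)
  ph <- wrap_phase(approx(tms, unwrapped, xout = spikes$time_ms)$y)

  condition_windows <- condition_windows %||%
    tibble(condition = "all", t0_ms = 0, t1_ms = tms[length(tms)] + dt)
  cond <- rep(NA_character_, nrow(spikes))
  for (i in seq_len(nrow(condition_windows))) {
    sel <- spikes$time_ms >= condition_windows$t0_ms[i] &
      spikes$time_ms < condition_windows$t1_ms[i]
    cond[sel] <- condition_windows$condition[i]
  }
  phases <- tibble(roi_id = spikes$roi_id, time_ms = spikes$time_ms,
                   phase_rad = ph, condition = cond)
  phases <- phases[!is.na(phases$condition), ]
  summ <- phases |>
    dplyr::group_by(.data$condition) |>
    dplyr::summarise(n_spikes = dplyr::n(),
                     circ_mean_rad = circ_mean(.data$phase_rad),
                     resultant = circ_resultant(.data$phase_rad),
                     .groups = "drop")
  shift <- if (nrow(summ) == 2) {
    wrap_phase(summ$circ_mean_rad[2] - summ$circ_mean_rad[1])
  } else {
    NA_real_
  }
  structure(list(phases = phases, summary = summ, phase_shift_rad = shift),
            class = "phase_result")
}

unwrap_phase <- function(phi) {
  d <- diff(phi)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(phi[1], d))
}

#' @export
print.phase_result <- function(x, ...) {
  cat("<phase_result>\n")
  print(x$summary)
  if (is.finite(x$phase_shift_rad)) {
    cat(sprintf("  phase shift: %.3f rad\n", x$phase_shift_rad))
  }
  invisible(x)
}

#' Tidy a phase result
#'
#' @param x A `phase_result`.
#' @param ... Unused.
#' @return The per-condition summary tibble.
#' @export
tidy.phase_result <- function(x, ...) x$summary
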