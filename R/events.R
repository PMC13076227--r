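#' Detect spikes by SD-threshold peak finding
#'
#' Local maxima of the (positive-going) dF/F0 trace that exceed
#' `mean + k_sd * SD` are reported as spikes. The mean and SD are computed
#' over the entire trace, spikes included, matching the standard
#' `findpeaks`-with-threshold convention; a robust variant (median + k *
#' MAD) is available. Peaks closer together than `refractory_ms` are
#' resolved by keeping the larger (ties: the earlier). A constant trace
#' (SD = 0) yields an empty train rather than an error. Because the
#' threshold is expressed in SD units, detection is invariant to
#' multiplicative rescaling of the trace.
#'
#' @param x A `dff_set` (typically smoothed; see
#'   [smooth_savitzky_golay()]), numeric matrix or vector.
#' @param k_sd Threshold multiplier. The in vivo dendritic pipeline uses
#'   1.5 for the synchronicity/clustering stage and 3 for final spike
#'   detection.
#' @param refractory_ms Minimum peak separation in ms (default 5,
#'   matching the absolute refractory period and exceeding the spike
#'   kernel's effective width, so one kernel cannot be counted twice).
#' @param min_prominence_sd Optional minimum peak prominence, in SD units
#'   (default 0 = off).
#' @param robust If `TRUE`, threshold on median + k_sd * MAD instead.
#' @param frame_interval_ms Frame interval when `x` is a bare matrix or
#'   vector (default 1).
#' @return A `spike_trains` tibble with columns `roi_id` and `time_ms`
#'   (peak times, ms from recording start, sorted within ROI). Attributes:
#'   `roi_ids` (all ROIs, including spikeless ones), `detection` (per-ROI
#'   tibble of mean, SD, threshold and spike count), `params`, and
#'   `duration_ms`.
#' @export
#' @examples
#' tr <- rep(0, 200); tr[c(50, 120)] <- 1
#' detect_spikes(tr + rnorm(200, 0, 0.01), k_sd = 3)
detect_spikes <- function(x, k_sd = 3, refractory_ms = 5,
                          min_prominence_sd = 0, robust = FALSE,
                          frame_interval_ms = 1) {
  if (k_sd <= 0) abort("`k_sd` must be positive.")
  m <- trace_matrix(x)
  if (ncol(m) < 3) abort("traces must have at least 3 frames.")
  dt <- if (inherits(x, c("trace_set", "dff_set"))) x$frame_interval_ms
        else frame_interval_ms
  roi_ids <- rownames(m) %||% paste0("roi_", seq_len(nrow(m)))

  per_roi <- lapply(seq_len(nrow(m)), function(i) {
    v <- m[i, ]
    if (robust) {
      mu <- median(v); sdev <- mad(v)
    } else {
      mu <- mean(v); sdev <- sd(v)
    }
    if (sdev == 0) {
      return(list(times = numeric(0), mu = mu, sdev = sdev,
                  threshold = NA_real_))
    }
    thr <- mu + k_sd * sdev
    pk <- find_peaks(v, thr)
    if (min_prominence_sd > 0 && length(pk)) {
      prom <- peak_prominence(v, pk)
      pk <- pk[prom >= min_prominence_sd * sdev]
    }
    pk <- enforce_min_distance(pk, v[pk], refractory_ms / dt)
    list(times = (pk - 1) * dt, mu = mu, sdev = sdev, threshold = thr)
  })

  trains <- tibble(
    roi_id = rep(roi_ids, vapply(per_roi, function(p) length(p$times),
                                 integer(1))),
    time_ms = unlist(lapply(per_roi, `[[`, "times")) %||% numeric(0)
  )
  detection <- tibble(
    roi_id = roi_ids,
    mean = vapply(per_roi, `[[`, numeric(1), "mu"),
    sd = vapply(per_roi, `[[`, numeric(1), "sdev"),
    threshold = vapply(per_roi, `[[`, numeric(1), "threshold"),
    n_spikes = vapply(per_roi, function(p) length(p$times), integer(1))
  )
  new_spike_trains(trains, roi_ids = roi_ids, detection = detection,
                   params = list(k_sd = k_sd, refractory_ms = refractory_ms,
                                 min_prominence_sd = min_prominence_sd,
                                 robust = robust),
                   duration_ms = ncol(m) * dt)
}

new_spike_trains <- function(trains, roi_ids, detection = NULL,
                             params = list(), duration_ms = NA_real_) {
  structure(
    as_tibble(trains),
    roi_ids = roi_ids, detection = detection, params = params,
    duration_ms = duration_ms,
    class = c("spike_trains", class(as_tibble(trains))))
}

# interior strict-rise local maxima (first sample of a plateau)
find_peaks <- function(v, thr) {
  n <- length(v)
  if (n < 3) return(integer(0))
  core <- v[2:(n - 1)]
  idx <- which(core > v[1:(n - 2)] & core >= v[3:n]) + 1L
  idx[v[idx] >= thr]
}

peak_prominence <- function(v, pk) {
  vapply(pk, function(p) {
    left <- v[seq_len(p - 1)]
    right <- v[seq(p + 1, length(v))]
    higher_l <- which(left > v[p])
    higher_r <- which(right > v[p])
    base_l <- min(left[seq(if (length(higher_l)) max(higher_l) else 1,
                           length(left))])
    base_r <- min(right[seq_len(if (length(higher_r)) min(higher_r)
                                else length(right))])
    v[p] - max(base_l, base_r)
  }, numeric(1))
}

# keep larger peaks (ties: earlier) among peaks closer than min_dist frames
enforce_min_distance <- function(pk, heights, min_dist) {
  if (length(pk) < 2) return(pk)
  ord <- order(-heights, pk)
  kept <- integer(0)
  for (p in pk[ord]) {
    if (!length(kept) || min(abs(kept - p)) > min_dist) kept <- c(kept, p)
  }
  sort(kept)
}

#' Convert spike trains to a per-ROI list
#'
#' @param spikes A `spike_trains` tibble (or a named list of numeric
#'   vectors, returned unchanged).
#' @param roi_ids Optional ROI ordering; defaults to the `roi_ids`
#'   attribute so that spikeless ROIs are kept as empty trains.
#' @return Named list of sorted spike-time vectors (ms).
#' @export
spike_train_list <- function(spikes, roi_ids = NULL) {
  if (is.list(spikes) && !is.data.frame(spikes)) {
    stopifnot(!is.null(names(spikes)))
    return(lapply(spikes, sort))
  }
  roi_ids <- roi_ids %||% attr(spikes, "roi_ids") %||% unique(spikes$roi_id)
  out <- lapply(roi_ids, function(id) {
    sort(spikes$time_ms[spikes$roi_id == id])
  })
  names(out) <- roi_ids
  out
}

#' Spike-triggered average
#'
#' Averages trace snippets from every ROI, aligned on a set of reference
#' spike times (usually the soma's detected peaks). Events whose lag window
#' extends outside the recording are dropped and counted. Averaging n
#' events reduces independent noise by ~sqrt(n); the classic backpropagation
#' mapping averages 65 events.
#'
#' @param x A `dff_set`, numeric matrix or vector.
#' @param reference_times_ms Numeric vector of reference spike times (ms).
#' @param lag_window_ms Window around each event, `c(before, after)` in ms
#'   (default `c(-10, 30)`).
#' @param frame_interval_ms Frame interval for bare matrices (default 1).
#' @return An `sta_result`: list with `sta` (ROI x lag matrix), `lag_ms`,
#'   `n_events`, `n_dropped`, `frame_interval_ms`, `roi_ids`.
#' @export
spike_triggered_average <- function(x, reference_times_ms,
                                    lag_window_ms = c(-10, 30),
                                    frame_interval_ms = 1) {
  m <- trace_matrix(x)
  dt <- if (inherits(x, c("trace_set", "dff_set"))) x$frame_interval_ms
        else frame_interval_ms
  if (!length(reference_times_ms)) abort("no reference spikes supplied.")
  lag_lo <- round(lag_window_ms[1] / dt)
  lag_hi <- round(lag_window_ms[2] / dt)
  if (lag_hi < lag_lo) abort("`lag_window_ms` must be increasing.")
  lags <- lag_lo:lag_hi
  centre <- round(reference_times_ms / dt) + 1L
  ok <- centre + lag_lo >= 1L & centre + lag_hi <= ncol(m)
  n_dropped <- sum(!ok)
  centre <- centre[ok]
  if (!length(centre)) abort("no reference event has a full lag window inside the recording.")
  acc <- matrix(0, nrow(m), length(lags))
  for (cfr in centre) {
    acc <- acc + m[, cfr + lags, drop = FALSE]
  }
  sta <- acc / length(centre)
  rownames(sta) <- rownames(m)
  structure(
    list(sta = sta, lag_ms = lags * dt, n_events = length(centre),
         n_dropped = n_dropped, frame_interval_ms = dt,
         roi_ids = rownames(m) %||% paste0("roi_", seq_len(nrow(m)))),
    class = "sta_result")
}

#' @export
print.sta_result <- function(x, ...) {
  cat(sprintf("<sta_result> %d ROI(s), lags %g..%g ms, %d events (%d dropped)\n",
              nrow(x$sta), min(x$lag_ms), max(x$lag_ms), x$n_events,
              x$n_dropped))
  invisible(x)
}

#' Tidy a spike-triggered average
#'
#' @param x An `sta_result`.
#' @param ... Unused.
#' @return Tibble with `roi_id`, `lag_ms`, `value`.
#' @export
tidy.sta_result <- function(x, ...) {
  tibble(
    roi_id = rep(x$roi_ids, times = ncol(x$sta)),
    lag_ms = rep(x$lag_ms, each = nrow(x$sta)),
    value = as.vector(x$sta)
  )
}

#' Half-rise time of a waveform
#'
#' The time at which a waveform first crosses 50% of (peak - baseline),
#' located by linear interpolation between the bracketing samples. Sample
#' i sits at time (i - 1) * frame interval. When `inclusion_sd` is given,
#' the waveform is analysed only if its peak exceeds
#' `baseline mean + inclusion_sd * baseline SD` (the usual screen is 5 SD);
#' otherwise `NA` is returned with attribute `included = FALSE`.
#'
#' @param waveform Numeric vector.
#' @param frame_interval_ms Frame interval in ms (default 1).
#' @param baseline_window Indices used for the baseline mean/SD; default
#'   the first quarter of the samples (at least 1).
#' @param peak_window Indices searched for the peak; default all samples.
#' @param inclusion_sd If non-`NULL`, the peak inclusion rule multiplier.
#' @return Half-rise time in ms (scalar), with attribute `included`.
#' @export
#' @examples
#' half_rise_time(c(0, 0, 1, 1), frame_interval_ms = 1)  # 1.5 ms
half_rise_time <- function(waveform, frame_interval_ms = 1,
                           baseline_window = NULL, peak_window = NULL,
                           inclusion_sd = NULL) {
  n <- length(waveform)
  if (n < 2) abort("waveform too short.")
  baseline_window <- baseline_window %||% seq_len(max(1L, floor(n / 4)))
  peak_window <- peak_window %||% seq_len(n)
  base <- mean(waveform[baseline_window])
  base_sd <- if (length(baseline_window) > 1) sd(waveform[baseline_window]) else 0
  peak_idx <- peak_window[which.max(waveform[peak_window])]
  peak <- waveform[peak_idx]
  if (!is.null(inclusion_sd) && peak <= base + inclusion_sd * base_sd) {
    return(structure(NA_real_, included = FALSE))
  }
  if (peak <= base) abort("waveform has no rise above baseline.")
  half <- base + 0.5 * (peak - base)
  for (i in seq(2, peak_idx)) {
    if (waveform[i] >= half && waveform[i - 1] < half) {
      frac <- (half - waveform[i - 1]) / (waveform[i] - waveform[i - 1])
      return(structure(((i - 2) + frac) * frame_interval_ms,
                       included = TRUE))
    }
  }
  if (waveform[1] >= half) abort("waveform starts above the half-rise level; no crossing found.")
  abort("no half-rise crossing found before the peak.")
}

#' Backpropagation latency map from a spike-triggered average
#'
#' Computes the half-rise time of every ROI's averaged waveform and
#' subtracts the reference ROI's (the soma, whose half-rise is defined as
#' 0 ms), giving the backpropagation latency at each dendritic ROI.
#'
#' @param sta An `sta_result` from [spike_triggered_average()].
#' @param reference_roi ROI id (or row index) of the reference/soma ROI.
#' @inheritParams half_rise_time
#' @return Tibble with `roi_id`, `half_rise_ms`, `latency_ms`, `included`.
#' @export
backprop_latency_map <- function(sta, reference_roi,
                                 baseline_window = NULL, peak_window = NULL,
                                 inclusion_sd = NULL) {
  stopifnot(inherits(sta, "sta_result"))
  ids <- sta$roi_ids
  ref_idx <- if (is.character(reference_roi)) match(reference_roi, ids)
             else as.integer(reference_roi)
  if (is.na(ref_idx) || ref_idx < 1 || ref_idx > nrow(sta$sta)) {
    abort("`reference_roi` not found.")
  }
  hr <- lapply(seq_len(nrow(sta$sta)), function(i) {
    half_rise_time(sta$sta[i, ], frame_interval_ms = sta$frame_interval_ms,
                   baseline_window = baseline_window,
                   peak_window = peak_window, inclusion_sd = inclusion_sd)
  })
  times <- vapply(hr, as.numeric, numeric(1))
  included <- vapply(hr, function(h) isTRUE(attr(h, "included")),
                     logical(1))
  if (!included[ref_idx]) {
    abort("the reference ROI fails the half-rise inclusion rule.")
  }
  tibble(
    roi_id = ids,
    half_rise_ms = times,
    latency_ms = times - times[ref_idx],
    included = included
  )
}

#' Odor-response amplitude
#'
#' The response amplitude of each ROI is the mean dF/F0 during the
#' post-onset window (default the first 10 s after odor onset), with F0
#' taken as the mean fluorescence over the pre-stimulus window (default
#' 10 s). Negative amplitudes are valid and indicate inhibitory responses.
#'
#' @param x A [trace_set()] (F0 is computed from the pre-stimulus window)
#'   or a `dff_set` (used as-is).
#' @param onset_ms Stimulus onset (ms).
#' @param post_window_s Averaging window after onset, seconds (default 10).
#' @param pre_window_s Baseline window before onset, seconds (default 10).
#' @return Tibble with `roi_id`, `f0` (NA for `dff_set` input) and
#'   `amplitude`.
#' @export
odor_response_amplitude <- function(x, onset_ms, post_window_s = 10,
                                    pre_window_s = 10) {
  dt <- if (inherits(x, c("trace_set", "dff_set"))) x$frame_interval_ms else 1
  m <- trace_matrix(x)
  tms <- (seq_len(ncol(m)) - 1) * dt
  if (onset_ms + post_window_s * 1000 > tms[length(tms)] + dt) {
    abort("the post-stimulus window extends beyond the recording.")
  }
  if (inherits(x, "trace_set")) {
    f0 <- compute_f0_prestim_mean(x, onset_ms, pre_window_s)
    d <- compute_dff(x, f0)
    dm <- d$dff
  } else {
    f0 <- rep(NA_real_, nrow(m))
    dm <- m
  }
  sel <- tms >= onset_ms & tms < onset_ms + post_window_s * 1000
  tibble(
    roi_id = rownames(m) %||% paste0("roi_", seq_len(nrow(m))),
    f0 = unname(f0),
    amplitude = unname(rowMeans(dm[, sel, drop = FALSE]))
  )
}

#' Detect calcium transients
#'
#' Median-filters the signal (three-frame window by default) to remove
#' single-frame artifacts, then applies [detect_spikes()] with the given
#' SD threshold.
#'
#' @inheritParams detect_spikes
#' @param median_window Median-filter window in frames (default 3).
#' @return A `spike_trains` tibble; see [detect_spikes()].
#' @export
detect_calcium_transients <- function(x, k_sd = 3, median_window = 3,
                                      refractory_ms = 5,
                                      frame_interval_ms = 1) {
  filtered <- median_filter_temporal(x, window_frames = median_window)
  detect_spikes(filtered, k_sd = k_sd, refractory_ms = refractory_ms,
                frame_interval_ms = frame_interval_ms)
}
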