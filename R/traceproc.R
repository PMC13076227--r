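#' Temporal-median baseline (F0)
#'
#' Computes the per-ROI baseline as a centred rolling median. This is the
#' standard F0 convention for high-speed voltage imaging (25-frame window
#' in vivo, 100 frames for slice recordings) and for slice calcium imaging
#' (10 frames). At the trace edges the window shrinks symmetrically, so no
#' data are fabricated; an even `window_frames` is incremented to the next
#' odd value with a warning.
#'
#' @param x A [trace_set()], `dff_set`, numeric matrix (ROI x frame) or
#'   numeric vector.
#' @param window_frames Window length in frames (odd; default 25).
#' @return Baseline matrix (or vector) with the same shape as the input
#'   signal.
#' @seealso [compute_dff()]
#' @export
#' @examples
#' compute_f0_temporal_median(c(100, 100, 100, 110, 100), window_frames = 3)
compute_f0_temporal_median <- function(x, window_frames = 25) {
  m <- trace_matrix(x)
  window_frames <- check_window(window_frames, ncol(m))
  out <- t(apply(m, 1, rolling_median, k = window_frames))
  if (ncol(m) == 1) out <- matrix(out, ncol = 1)
  rewrap_as_matrix(out, x)
}

# centred rolling median; the window shrinks symmetrically at the edges.
# runmed() handles the interior in O(n log k); only the (k-1)/2 frames at
# each end need the explicit shrink rule.
rolling_median <- function(v, k) {
  n <- length(v)
  if (k == 1 || n == 1) return(v)
  out <- as.numeric(runmed(v, k = k, endrule = "keep"))
  h <- (k - 1) / 2
  for (i in unique(c(seq_len(min(h, n)), seq(max(1, n - h + 1), n)))) {
    hh <- min(h, i - 1, n - i)
    out[i] <- median(v[(i - hh):(i + hh)])
  }
  out
}

check_window <- function(window_frames, n_frames) {
  if (!is.numeric(window_frames) || length(window_frames) != 1 ||
      window_frames < 1 || window_frames != round(window_frames)) {
    abort("`window_frames` must be a positive whole number.")
  }
  if (window_frames > n_frames) {
    abort(sprintf("`window_frames` (%d) exceeds the trace length (%d).",
                  window_frames, n_frames))
  }
  if (window_frames %% 2 == 0) {
    warn(sprintf(
      "`window_frames` = %d is even; using %d (centred windows need an odd length).",
      window_frames, window_frames + 1))
    window_frames <- min(window_frames + 1, n_frames)
    if (window_frames %% 2 == 0) window_frames <- window_frames - 1
  }
  as.integer(window_frames)
}

# baselines are plain matrices (or vector for vector input), never dff_sets
rewrap_as_matrix <- function(m, x) {
  if (is.vector(x) && is.numeric(x)) drop(m) else m
}

#' Convert raw fluorescence to (-)dF/F0
#'
#' dF/F0 = (F - F0) / F0. For negative-polarity indicators (Voltron-family
#' voltage sensors) the stored signal is -(F - F0)/F0, so that action
#' potentials are positive-going; a 2.5% dimming spike is stored as +0.025.
#' The result is invariant under multiplicative gain in F (scaling both F
#' and F0), but not under additive offsets.
#'
#' @param x A [trace_set()] (or numeric matrix, assumed positive polarity).
#' @param f0 Baseline: matrix of the same shape as `f`, or one scalar per
#'   ROI (e.g. from [compute_f0_prestim_mean()]).
#' @param floor_frac Baselines below `floor_frac` times the per-ROI median
#'   fluorescence are an error rather than being clipped (guards against
#'   division by ~0).
#' @return A `dff_set`.
#' @export
#' @examples
#' ts <- trace_set(matrix(c(100, 97.5, 100), nrow = 1), 1)
#' as.matrix(compute_dff(ts, matrix(100, 1, 3)))  # 2.5% spike -> +0.025
compute_dff <- function(x, f0, floor_frac = 1e-6) {
  if (!inherits(x, "trace_set")) {
    x <- trace_set(trace_matrix(x), frame_interval_ms = 1,
                   modality = "calcium", polarity = "positive")
  }
  f <- x$f
  if (is.vector(f0) && is.numeric(f0)) {
    if (length(f0) != nrow(f)) {
      abort("scalar-per-ROI `f0` must have one value per ROI.")
    }
    f0 <- matrix(f0, nrow = nrow(f), ncol = ncol(f))
  }
  if (!identical(dim(f0), dim(f))) {
    abort("`f0` must match the trace matrix shape or be one scalar per ROI.")
  }
  floor_val <- floor_frac * apply(abs(f), 1, median)
  bad <- which(f0 <= pmax(floor_val, 0), arr.ind = TRUE)
  if (nrow(bad) > 0) {
    abort(sprintf(
      "baseline is zero/negative (or below the floor) for ROI '%s' at frame %d.",
      x$roi_ids[bad[1, 1]], bad[1, 2]))
  }
  dff <- (f - f0) / f0
  if (x$polarity == "negative") dff <- -dff
  new_dff_set(dff, x, baseline_method = "precomputed",
              baseline_params = list(floor_frac = floor_frac))
}

#' Causal sliding-percentile baseline
#'
#' F0 at each time point is a low percentile (default the 25th) of the
#' fluorescence over the preceding window (default the 30 s up to and
#' including the current sample), the convention used for slow calcium
#' indicators under sustained stimulation. At the start of the trace the
#' window shrinks to the available samples (minimum 1). Percentiles use
#' linear interpolation between order statistics.
#'
#' @inheritParams compute_f0_temporal_median
#' @param window_s Window length in seconds (> 0).
#' @param percentile Percentile in (0, 100); default 25.
#' @return Baseline matrix (or vector) shaped like the input.
#' @export
compute_f0_sliding_percentile <- function(x, window_s = 30, percentile = 25) {
  m <- trace_matrix(x)
  if (ncol(m) == 0) abort("empty trace.")
  if (!is.numeric(window_s) || window_s <= 0) abort("`window_s` must be > 0.")
  if (percentile <= 0 || percentile >= 100) {
    abort("`percentile` must be strictly between 0 and 100.")
  }
  dt <- if (inherits(x, c("trace_set", "dff_set"))) x$frame_interval_ms else 1
  w <- max(1L, floor(window_s * 1000 / dt))
  p <- percentile / 100
  out <- t(apply(m, 1, function(v) {
    n <- length(v)
    vapply(seq_len(n), function(i) {
      lo <- max(1L, i - w + 1L)
      quantile(v[lo:i], probs = p, names = FALSE, type = 7)
    }, numeric(1))
  }))
  if (ncol(m) == 1) out <- matrix(out, ncol = 1)
  rewrap_as_matrix(out, x)
}

#' Pre-stimulus mean baseline
#'
#' One scalar F0 per ROI: the mean fluorescence over the window immediately
#' preceding stimulus onset (default 10 s), the convention for odor-evoked
#' calcium responses.
#'
#' @inheritParams compute_f0_temporal_median
#' @param stim_onset_ms Stimulus onset time (ms from recording start).
#' @param pre_window_s Length of the pre-stimulus window in seconds.
#' @return Named numeric vector, one F0 per ROI.
#' @export
compute_f0_prestim_mean <- function(x, stim_onset_ms, pre_window_s = 10) {
  m <- trace_matrix(x)
  dt <- if (inherits(x, c("trace_set", "dff_set"))) x$frame_interval_ms else 1
  pre_ms <- pre_window_s * 1000
  if (stim_onset_ms < pre_ms) {
    abort(sprintf(
      "stimulus onset (%g ms) is earlier than the %g s pre-stimulus window.",
      stim_onset_ms, pre_window_s))
  }
  tms <- (seq_len(ncol(m)) - 1) * dt
  sel <- tms >= (stim_onset_ms - pre_ms) & tms < stim_onset_ms
  if (!any(sel)) abort("no frames fall inside the pre-stimulus window.")
  out <- rowMeans(m[, sel, drop = FALSE])
  names(out) <- rownames(m) %||% paste0("roi_", seq_len(nrow(m)))
  out
}

#' Remove slow drift with a polynomial fit
#'
#' Fits a least-squares polynomial of the given degree to each ROI's trace
#' and subtracts it (degree 0 is mean subtraction). Intended for slow
#' photobleaching drift in dF/F0; isolated fast transients are essentially
#' untouched because they contribute little leverage to a low-order fit.
#'
#' @param x A `dff_set`, numeric matrix or vector.
#' @param degree Polynomial degree (default 3).
#' @return Drift-corrected signal, same class as the input.
#' @export
remove_drift_polyfit <- function(x, degree = 3) {
  m <- trace_matrix(x)
  n <- ncol(m)
  if (n <= degree) {
    abort(sprintf("need more than %d frames to fit a degree-%d polynomial.",
                  degree, degree))
  }
  tt <- seq(-1, 1, length.out = n)
  X <- outer(tt, 0:degree, `^`)
  # one QR solve for all ROIs at once
  fit <- qr.fitted(qr(X), t(m))
  out <- m - t(fit)
  rewrap_like(out, x, note = list(drift_degree = degree))
}

#' Savitzky-Golay smoothing
#'
#' Least-squares local-polynomial smoothing per ROI. A polynomial of degree
#' <= `polyorder` passes through unchanged, so spike peaks are far better
#' preserved than with a moving average of the same width.
#'
#' @param x A `dff_set`, numeric matrix or vector.
#' @param window_frames Odd window length (default 5).
#' @param polyorder Polynomial order, must be < `window_frames` (default 2).
#' @return Smoothed signal, same class as the input.
#' @export
smooth_savitzky_golay <- function(x, window_frames = 5, polyorder = 2) {
  m <- trace_matrix(x)
  if (window_frames %% 2 == 0 || window_frames <= polyorder) {
    abort("`window_frames` must be odd and greater than `polyorder`.")
  }
  if (window_frames > ncol(m)) {
    abort("`window_frames` exceeds the trace length.")
  }
  out <- t(apply(m, 1, function(v) {
    as.numeric(signal::sgolayfilt(v, p = polyorder, n = window_frames))
  }))
  if (ncol(m) == 1) out <- matrix(out, ncol = 1)
  rewrap_like(out, x, note = list(sg_window = window_frames,
                                  sg_polyorder = polyorder))
}

#' Temporal median filter
#'
#' Rolling-median filtering of the signal itself (not the baseline); the
#' standard despeckling step before calcium-transient detection. Windows
#' shrink at the edges exactly as in [compute_f0_temporal_median()].
#'
#' @param x A `dff_set`, numeric matrix or vector.
#' @param window_frames Odd window length (default 3).
#' @return Filtered signal, same class as the input.
#' @export
median_filter_temporal <- function(x, window_frames = 3) {
  m <- trace_matrix(x)
  window_frames <- check_window(window_frames, ncol(m))
  out <- t(apply(m, 1, rolling_median, k = window_frames))
  if (ncol(m) == 1) out <- matrix(out, ncol = 1)
  rewrap_like(out, x, note = list(median_window = window_frames))
}
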