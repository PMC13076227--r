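#' Construct a set of raw fluorescence traces
#'
#' A `trace_set` holds a raw fluorescence matrix (one row per region of
#' interest, one column per frame) in camera units, together with the frame
#' interval and the indicator metadata the downstream operators need.
#' Voltage indicators of the Voltron family dim on depolarisation, so their
#' raw polarity is `"negative"`: spikes appear as downward deflections in F
#' and are sign-flipped to positive-going -dF/F0 by [compute_dff()].
#'
#' @param f Numeric matrix (ROI x frame) of raw fluorescence, or a numeric
#'   vector for a single ROI. All values must be finite.
#' @param frame_interval_ms Frame interval in milliseconds (> 0).
#' @param roi_ids Character vector of ROI identifiers. Defaults to rownames
#'   of `f` or `"roi_1"`, `"roi_2"`, ...
#' @param modality `"voltage"` or `"calcium"`.
#' @param polarity `"negative"` (spikes dim the indicator) or `"positive"`.
#'   Defaults to `"negative"` for voltage and `"positive"` for calcium.
#'
#' @return An object of class `trace_set`.
#' @seealso [compute_dff()], [tidy.trace_set()]
#' @export
#' @examples
#' ts <- trace_set(matrix(100 + rnorm(200), nrow = 2), frame_interval_ms = 1)
#' ts
trace_set <- function(f, frame_interval_ms, roi_ids = NULL,
                      modality = c("voltage", "calcium"), polarity = NULL) {
  if (is.vector(f) && is.numeric(f)) f <- matrix(f, nrow = 1)
  if (!is.matrix(f) || !is.numeric(f)) {
    abort("`f` must be a numeric matrix (ROI x frame).")
  }
  if (!all(is.finite(f))) {
    bad <- which(!is.finite(f), arr.ind = TRUE)[1, ]
    abort(sprintf("`f` contains a non-finite value at ROI %d, frame %d.",
                  bad[1], bad[2]))
  }
  if (!is.numeric(frame_interval_ms) || length(frame_interval_ms) != 1 ||
      !is.finite(frame_interval_ms) || frame_interval_ms <= 0) {
    abort("`frame_interval_ms` must be a single positive number.")
  }
  modality <- match.arg(modality)
  if (is.null(polarity)) {
    polarity <- if (modality == "voltage") "negative" else "positive"
  }
  polarity <- match.arg(polarity, c("negative", "positive"))
  roi_ids <- roi_ids %||% rownames(f) %||% paste0("roi_", seq_len(nrow(f)))
  if (length(roi_ids) != nrow(f)) {
    abort("`roi_ids` must have one entry per row of `f`.")
  }
  if (anyDuplicated(roi_ids)) abort("`roi_ids` must be unique.")
  rownames(f) <- roi_ids
  structure(
    list(f = f, roi_ids = as.character(roi_ids),
         frame_interval_ms = frame_interval_ms,
         modality = modality, polarity = polarity),
    class = "trace_set"
  )
}

new_dff_set <- function(dff, template, baseline_method, baseline_params = list()) {
  rownames(dff) <- template$roi_ids
  structure(
    list(dff = dff, roi_ids = template$roi_ids,
         frame_interval_ms = template$frame_interval_ms,
         modality = template$modality, polarity = template$polarity,
         baseline_method = baseline_method,
         baseline_params = baseline_params),
    class = "dff_set"
  )
}

#' @export
print.trace_set <- function(x, ...) {
  cat(sprintf(
    "<trace_set> %d ROI(s) x %d frame(s) @ %g ms/frame (%s, %s polarity)\n",
    nrow(x$f), ncol(x$f), x$frame_interval_ms, x$modality, x$polarity))
  invisible(x)
}

#' @export
print.dff_set <- function(x, ...) {
  cat(sprintf(
    "<dff_set> %d ROI(s) x %d frame(s) @ %g ms/frame (%s; baseline: %s)\n",
    nrow(x$dff), ncol(x$dff), x$frame_interval_ms,
    if (x$polarity == "negative") "-dF/F0" else "dF/F0",
    x$baseline_method))
  invisible(x)
}

#' @export
dim.trace_set <- function(x) dim(x$f)

#' @export
dim.dff_set <- function(x) dim(x$dff)

#' @export
as.matrix.trace_set <- function(x, ...) x$f

#' @export
as.matrix.dff_set <- function(x, ...) x$dff

n_roi <- function(x) nrow(as.matrix(x))
n_frame <- function(x) ncol(as.matrix(x))

#' Frame times of a trace container
#'
#' Times are milliseconds from recording start; the first frame is at 0 ms.
#'
#' @param x A [trace_set()] or `dff_set`.
#' @return Numeric vector of frame times in ms.
#' @export
frame_times <- function(x) {
  (seq_len(n_frame(x)) - 1) * x$frame_interval_ms
}

#' Tidy a trace container into a long tibble
#'
#' @param x A [trace_set()] or `dff_set`.
#' @param ... Unused.
#' @return A tibble with columns `roi_id`, `frame`, `time_ms`, `value`.
#' @export
tidy.trace_set <- function(x, ...) {
  m <- as.matrix(x)
  tibble(
    roi_id = rep(x$roi_ids, times = ncol(m)),
    frame = rep(seq_len(ncol(m)), each = nrow(m)),
    time_ms = rep(frame_times(x), each = nrow(m)),
    value = as.vector(m)
  )
}

#' @rdname tidy.trace_set
#' @export
tidy.dff_set <- tidy.trace_set

# Resolve a traces argument to a plain matrix, remembering metadata.
trace_matrix <- function(x, arg = "x") {
  if (inherits(x, "trace_set")) return(x$f)
  if (inherits(x, "dff_set")) return(x$dff)
  if (is.vector(x) && is.numeric(x)) return(matrix(x, nrow = 1))
  if (is.matrix(x) && is.numeric(x)) return(x)
  abort(sprintf("`%s` must be a trace_set, dff_set, numeric matrix or vector.",
                arg))
}

# Return an output in the same shape/class family as the input signal
# container: dff_set in, dff_set out; matrix in, matrix out.
rewrap_like <- function(m, x, note = NULL) {
  if (inherits(x, "dff_set")) {
    out <- x
    out$dff <- m
    rownames(out$dff) <- out$roi_ids
    if (!is.null(note)) {
      out$baseline_params <- c(out$baseline_params, note)
    }
    return(out)
  }
  if (inherits(x, "trace_set")) {
    out <- x
    out$f <- m
    rownames(out$f) <- out$roi_ids
    return(out)
  }
  if (is.vector(x) && is.numeric(x)) return(drop(m))
  m
}
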