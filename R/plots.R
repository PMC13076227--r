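# ggplot2 visualisations for the main result types.

#' Plot stacked dF/F0 traces
#'
#' @param object A `dff_set` or [trace_set()].
#' @param rois ROI ids (or indices) to show; default the first 10.
#' @param offset Vertical offset between traces; default 4x the median
#'   per-trace SD.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dff_set <- function(object, rois = NULL, offset = NULL, ...) {
  m <- as.matrix(object)
  rois <- rois %||% utils::head(object$roi_ids, 10)
  if (is.numeric(rois)) rois <- object$roi_ids[rois]
  m <- m[rois, , drop = FALSE]
  offset <- offset %||% (4 * median(apply(m, 1, sd)))
  df <- tidy(object) |>
    dplyr::filter(.data$roi_id %in% rois) |>
    dplyr::mutate(y = .data$value +
                    offset * (match(.data$roi_id, rev(rois)) - 1))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms / 1000, .data$y,
                                   group = .data$roi_id)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (s)",
                  y = if (object$polarity == "negative")
                    expression(-Delta * F / F[0]) else
                      expression(Delta * F / F[0])) +
    ggplot2::theme_minimal()
}

#' @rdname autoplot.dff_set
#' @export
autoplot.trace_set <- autoplot.dff_set

#' Plot an orientation tuning fit
#'
#' Measured mean responses (points) with the fitted wrapped two-Gaussian
#' curve.
#'
#' @param object A `tuning_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.tuning_fit <- function(object, ...) {
  grid <- seq(0, 360, by = 2)
  df_fit <- tibble(direction = grid, response = predict(object, grid))
  df_obs <- tibble(direction = object$directions,
                   response = object$responses)
  ggplot2::ggplot(df_fit, ggplot2::aes(.data$direction, .data$response)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(data = df_obs) +
    ggplot2::scale_x_continuous(breaks = seq(0, 360, by = 45)) +
    ggplot2::labs(x = "direction (deg)", y = "response (dF/F0)") +
    ggplot2::theme_minimal()
}

#' Plot a spike-triggered average
#'
#' @param object An `sta_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.sta_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(.data$lag_ms, .data$value,
                               colour = .data$roi_id)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "lag (ms)", y = expression(-Delta * F / F[0]),
                  colour = "ROI") +
    ggplot2::theme_minimal()
}

#' Heatmap of a similarity matrix
#'
#' Displays a correlation or synchronicity matrix, optionally ordered by
#' cluster labels so the block structure is visible.
#'
#' @param mat Symmetric matrix (correlation or synchronicity).
#' @param labels Optional cluster labels (vector or the tibble from
#'   [cluster_glomeruli()]) used to order the rows/columns.
#' @return A ggplot object.
#' @export
plot_similarity_matrix <- function(mat, labels = NULL) {
  ids <- rownames(mat) %||% as.character(seq_len(nrow(mat)))
  ord <- seq_len(nrow(mat))
  if (!is.null(labels)) {
    lv <- if (is.data.frame(labels)) labels$glomerulus else labels
    ord <- order(lv)
  }
  m <- mat[ord, ord]
  df <- tibble(
    row = factor(rep(ids[ord], times = ncol(m)), levels = ids[ord]),
    col = factor(rep(ids[ord], each = nrow(m)), levels = ids[ord]),
    value = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "similarity") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
}

#' Rose plot of spike theta phases
#'
#' @param x A `phase_result` from [spike_phases()].
#' @param bins Number of phase bins (default 24).
#' @return A ggplot object.
#' @export
plot_spike_phases <- function(x, bins = 24) {
  stopifnot(inherits(x, "phase_result"))
  ggplot2::ggplot(x$phases, ggplot2::aes(.data$phase_rad)) +
    ggplot2::geom_histogram(breaks = seq(-pi, pi, length.out = bins + 1),
                            fill = "steelblue", colour = "white") +
    ggplot2::coord_polar(start = pi / 2, direction = -1) +
    ggplot2::facet_wrap(~condition) +
    ggplot2::scale_x_continuous(
      breaks = c(-pi / 2, 0, pi / 2, pi),
      labels = c("-pi/2", "0", "pi/2", "pi")) +
    ggplot2::labs(x = "theta phase (rad)", y = "spike count") +
    ggplot2::theme_minimal()
}
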