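# Pixel-level rendering of synthetic datasets and trace extraction.

# geometry defaults: glomeruli on a grid of `cell`-sized tiles, each with a
# circular glomerular mask and up to 9 footprint slots
movie_geometry <- function(cfg, roi_map) {
  g <- max(roi_map$glomerular_label)
  cols <- ceiling(sqrt(g))
  rows <- ceiling(g / cols)
  geo <- list(cell = 24, glom_radius = 9, background = 100,
              n_decoy_small = 1, n_decoy_outside = 1)
  geo[names(cfg$geometry %||% list())] <- cfg$geometry
  geo$grid <- c(rows, cols)
  geo$height <- geo$height %||% (rows * geo$cell)
  geo$width <- geo$width %||% (cols * geo$cell)
  geo
}

glom_centre <- function(g, geo) {
  cols <- geo$grid[2]
  cx <- geo$cell * ((g - 1) %% cols) + geo$cell / 2
  cy <- geo$cell * ((g - 1) %/% cols) + geo$cell / 2
  c(x = cx, y = cy)
}

rect_pixels <- function(x0, y0, w, h, geo) {
  cols <- rep(seq(x0, x0 + w - 1), each = h)
  rows <- rep(seq(y0, y0 + h - 1), times = w)
  if (any(rows < 1 | rows > geo$height | cols < 1 | cols > geo$width)) {
    abort("a footprint does not fit inside the image.")
  }
  as.integer(rows + (cols - 1) * geo$height)
}

# lay out non-overlapping footprints inside each glomerular disc, plus
# decoy ROIs (< 5 px inside a glomerulus; normal-sized outside the mask)
place_footprints <- function(roi_map, geo) {
  slots <- expand.grid(dx = c(-6, -2, 2), dy = c(-6, -2, 2))
  roi_map$footprint <- vector("list", nrow(roi_map))
  slot_used <- list()
  for (i in seq_len(nrow(roi_map))) {
    g <- roi_map$glomerular_label[i]
    used <- slot_used[[as.character(g)]] %||% 0L
    if (used >= nrow(slots) - 1) {
      abort("too many ROIs per glomerulus for the movie geometry (max 8).")
    }
    slot <- slots[used + 1L, ]
    ctr <- glom_centre(g, geo)
    w <- 3L
    h <- if (i %% 2 == 0) 2L else 3L
    roi_map$footprint[[i]] <- rect_pixels(ctr["x"] + slot$dx,
                                          ctr["y"] + slot$dy, w, h, geo)
    roi_map$pixel_count[i] <- w * h
    roi_map$centroid_x[i] <- ctr["x"] + slot$dx + (w - 1) / 2
    roi_map$centroid_y[i] <- ctr["y"] + slot$dy + (h - 1) / 2
    slot_used[[as.character(g)]] <- used + 1L
  }
  n_decoys <- 0L
  decoy_rows <- list()
  for (k in seq_len(geo$n_decoy_small %||% 0)) {
    g <- ((k - 1) %% max(roi_map$glomerular_label)) + 1
    used <- slot_used[[as.character(g)]] %||% 0L
    slot <- slots[min(used + 1L, nrow(slots)), ]
    slot_used[[as.character(g)]] <- used + 1L
    ctr <- glom_centre(g, geo)
    n_decoys <- n_decoys + 1L
    decoy_rows[[length(decoy_rows) + 1]] <- tibble(
      roi_id = sprintf("decoy_small_%d", k), pixel_count = 4L,
      centroid_x = ctr["x"] + slot$dx + 0.5,
      centroid_y = ctr["y"] + slot$dy + 0.5,
      glomerular_label = as.integer(g),
      footprint = list(rect_pixels(ctr["x"] + slot$dx, ctr["y"] + slot$dy,
                                   2L, 2L, geo)))
  }
  for (k in seq_len(geo$n_decoy_outside %||% 0)) {
    n_decoys <- n_decoys + 1L
    decoy_rows[[length(decoy_rows) + 1]] <- tibble(
      roi_id = sprintf("decoy_outside_%d", k), pixel_count = 9L,
      centroid_x = 3 + 4 * (k - 1), centroid_y = 2,
      glomerular_label = 0L,
      footprint = list(rect_pixels(2 + 4 * (k - 1), 1, 3L, 3L, geo)))
  }
  if (length(decoy_rows)) {
    roi_map <- dplyr::bind_rows(roi_map, dplyr::bind_rows(decoy_rows))
  }
  attr(roi_map, "geometry") <- geo
  list(roi_map = roi_map, n_decoys = n_decoys)
}

#' Render a synthetic dataset as a multi-frame movie
#'
#' Produces a pixel-level image stack in which each ROI's footprint
#' carries that ROI's raw fluorescence trace, pixels outside any footprint
#' sit at the background level, and optional Gaussian pixel noise is
#' added. With zero pixel noise, [extract_traces()] on the rendered movie
#' reproduces the input traces exactly.
#'
#' @param traces A [trace_set()] (e.g. from [simulate_voltage_dataset()]
#'   with `movie = TRUE`).
#' @param roi_map ROI tibble carrying a `footprint` list-column of pixel
#'   indices and a `geometry` attribute (as produced by the simulator).
#'   Overlapping footprints are rejected.
#' @param pixel_noise_sd SD of per-pixel Gaussian noise in camera units
#'   (default 0).
#' @param seed Seed for the pixel noise.
#' @return Numeric array (height x width x frame) with attribute
#'   `geometry`.
#' @export
render_movie <- function(traces, roi_map, pixel_noise_sd = 0, seed = 0) {
  stopifnot(inherits(traces, "trace_set"))
  geo <- attr(roi_map, "geometry")
  if (is.null(geo) || is.null(roi_map$footprint)) {
    abort("`roi_map` has no footprints; simulate with `movie = TRUE`.")
  }
  pix <- unlist(roi_map$footprint)
  if (anyDuplicated(pix)) abort("ROI footprints overlap.")
  ord <- match(roi_map$roi_id, traces$roi_ids)
  if (anyNA(ord)) abort("`roi_map` and `traces` disagree on ROI ids.")
  nt <- n_frame(traces)
  movie <- array(geo$background, dim = c(geo$height, geo$width, nt))
  npix <- geo$height * geo$width
  for (i in seq_len(nrow(roi_map))) {
    fp <- roi_map$footprint[[i]]
    tr <- traces$f[ord[i], ]
    movie[outer(fp, (seq_len(nt) - 1) * npix, `+`)] <-
      rep(tr, each = length(fp))
  }
  if (pixel_noise_sd > 0) {
    movie <- movie + withr::with_seed(
      seed, array(rnorm(length(movie), 0, pixel_noise_sd), dim = dim(movie)))
  }
  attr(movie, "geometry") <- geo
  movie
}

#' Extract ROI traces from a movie
#'
#' The trace of each ROI is the per-frame mean pixel value over its
#' footprint (the standard mean-over-mask extraction).
#'
#' @param movie Array (height x width x frame).
#' @param roi_map Tibble with `roi_id` and a `footprint` list-column of
#'   pixel indices into the image.
#' @param frame_interval_ms Frame interval of the movie (default 1).
#' @param modality,polarity Metadata for the resulting [trace_set()].
#' @return A [trace_set()] with one row per ROI in `roi_map`.
#' @export
extract_traces <- function(movie, roi_map, frame_interval_ms = 1,
                           modality = "voltage", polarity = NULL) {
  stopifnot(length(dim(movie)) == 3)
  if (is.null(roi_map$footprint)) abort("`roi_map` has no footprints.")
  npix <- prod(dim(movie)[1:2])
  nt <- dim(movie)[3]
  flat <- matrix(movie, nrow = npix, ncol = nt)
  f <- t(vapply(seq_len(nrow(roi_map)), function(i) {
    fp <- roi_map$footprint[[i]]
    if (!length(fp)) abort(sprintf("ROI '%s' has an empty footprint.",
                                   roi_map$roi_id[i]))
    if (any(fp < 1 | fp > npix)) {
      abort(sprintf("footprint of ROI '%s' is outside the image.",
                    roi_map$roi_id[i]))
    }
    colMeans(flat[fp, , drop = FALSE])
  }, numeric(nt)))
  if (nt == 1) f <- matrix(f, ncol = 1)
  trace_set(f, frame_interval_ms = frame_interval_ms,
            roi_ids = roi_map$roi_id, modality = modality,
            polarity = polarity)
}

#' Write a movie as a multi-frame TIFF stack
#'
#' Stores each frame as a 32-bit float TIFF page, scaled by `scale` (TIFF
#' float pages preserve the raw camera units when `scale = 1`).
#'
#' @param movie Array (height x width x frame).
#' @param path Output file path.
#' @param scale Multiplicative scale applied before writing (default 1).
#' @return The path, invisibly.
#' @export
write_movie_tiff <- function(movie, path, scale = 1) {
  frames <- lapply(seq_len(dim(movie)[3]), function(t) {
    movie[, , t] * scale
  })
  tiff::writeTIFF(frames, path, bits.per.sample = 32L, reduce = FALSE)
  invisible(path)
}

#' Read a multi-frame TIFF stack as a movie array
#'
#' @param path TIFF file path.
#' @return Numeric array (height x width x frame).
#' @export
read_movie_tiff <- function(path) {
  frames <- tiff::readTIFF(path, all = TRUE, as.is = FALSE)
  if (!is.list(frames)) frames <- list(frames)
  array(unlist(frames), dim = c(dim(frames[[1]])[1:2], length(frames)))
}
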