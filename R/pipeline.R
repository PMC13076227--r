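# End-to-end orchestration, on-disk formats, validation and provenance.

#' Pipeline configuration
#'
#' Collects every stage parameter of the demixing pipeline with defaults
#' reproducing the reference analysis: 25-frame temporal-median F0,
#' Savitzky-Golay smoothing (5 frames, order 2), spike thresholds 1.5 SD
#' (synchronicity/clustering stage) and 3 SD (final detection), +/-7 ms
#' coincidence window, k-means with k = number of glomeruli, and a
#' dendrogram cut at 10% of the maximum distance.
#'
#' @param ... Named overrides of the defaults listed below.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    sim = sim_config(),
    f0_window_frames = 25,
    sg_window_frames = 5,
    sg_polyorder = 2,
    k_sd_clustering = 1.5,
    k_sd_final = 3,
    refractory_ms = 5,
    sync_half_window_ms = 7,
    k = NULL,                      # defaults to the number of glomeruli
    n_restarts = 50,
    threshold_fraction = 0.10,
    band_hz = c(1, 12),
    reference_f0_window_frames = 1001,  # slow baseline for the theta reference
    min_pixels = 5,
    seed = 1,
    write_traces = FALSE)
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) {
    abort(sprintf("unknown pipeline_config field(s): %s",
                  paste(unknown, collapse = ", ")))
  }
  cfg[names(dots)] <- dots
  structure(cfg, class = "pipeline_config")
}

#' Run the full demixing pipeline
#'
#' Executes simulate (or ingest) -> preprocess -> detect -> demix -> phase
#' and writes every result table, a human-readable report and a
#' machine-readable manifest (stage list, parameters, MD5 of every output
#' file) into `out_dir`. Identical configuration and seed give
#' byte-identical outputs and therefore identical manifest hashes. A
#' failing stage aborts with the stage name and leaves no partial outputs
#' (results are written only after all stages succeed).
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created; must be empty or absent).
#'   `NULL` runs the stages in memory without writing anything.
#' @param input Optional input dataset (a `voltage_dataset` or a
#'   [trace_set()]); when omitted the configured simulation is run. A
#'   path is read with [read_dataset()].
#' @return Invisibly, a list with all stage results and the manifest.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = NULL,
                         input = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  res <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)))
    })
  }

  # -- simulate / ingest ----------------------------------------------------
  ds <- stage("simulate", {
    if (is.null(input)) {
      simulate_voltage_dataset(config$sim)
    } else {
      if (is.character(input)) input <- read_dataset(input)
      if (inherits(input, "trace_set")) {
        input <- list(traces = input, roi_map = NULL, ground_truth = NULL)
      }
      v <- validate_dataset(input$traces)
      if (!attr(v, "pass")) {
        abort(paste("input failed validation:",
                    paste(v$detail[v$status == "fail"], collapse = "; ")))
      }
      input
    }
  })
  res$dataset <- ds

  # -- ROI filtering (when pixel metadata is available) ---------------------
  keep_ids <- ds$traces$roi_ids
  if (!is.null(ds$roi_map) &&
      all(c("pixel_count", "glomerular_label") %in% names(ds$roi_map))) {
    flt <- stage("simulate", filter_rois(ds$roi_map, config$min_pixels))
    res$roi_filter <- flt
    keep_ids <- intersect(keep_ids, flt$retained$roi_id)
  }
  traces <- ds$traces
  sel <- match(keep_ids, traces$roi_ids)
  traces$f <- traces$f[sel, , drop = FALSE]
  traces$roi_ids <- keep_ids

  # -- preprocess -----------------------------------------------------------
  dffs <- stage("preprocess", {
    f0 <- compute_f0_temporal_median(traces, config$f0_window_frames)
    d <- compute_dff(traces, f0)
    smooth_savitzky_golay(d, config$sg_window_frames, config$sg_polyorder)
  })
  res$dff <- dffs

  # -- detect ---------------------------------------------------------------
  det <- stage("detect", {
    list(clustering = detect_spikes(dffs, k_sd = config$k_sd_clustering,
                                    refractory_ms = config$refractory_ms),
         final = detect_spikes(dffs, k_sd = config$k_sd_final,
                               refractory_ms = config$refractory_ms))
  })
  res$spikes <- det

  # -- demix ----------------------------------------------------------------
  dem <- stage("demix", {
    cc <- correlation_matrix(dffs)
    k <- config$k %||% ds$config$n_glomeruli %||%
      abort("`k` must be set when the input carries no glomerulus count.")
    glom <- cluster_glomeruli(cc, k = k, seed = config$seed,
                              n_restarts = config$n_restarts)
    sync <- synchronicity_matrix(det$clustering,
                                 half_window_ms = config$sync_half_window_ms)
    labels <- subcluster_neurons(sync, glom,
                                 threshold_fraction = config$threshold_fraction)
    sister <- if (max(labels$subcluster) >= 2 && k >= 2) {
      tryCatch(sister_synchrony_comparison(
        labels, det$final, half_window_ms = config$sync_half_window_ms),
        error = function(e) NULL)
    }
    list(correlation = cc, sync = sync, labels = labels, sister = sister)
  })
  res$demix <- dem

  # -- phase ----------------------------------------------------------------
  pha <- stage("phase", {
    f0_slow <- compute_f0_temporal_median(
      traces, min(config$reference_f0_window_frames,
                  n_frame(traces) - (1 - n_frame(traces) %% 2)))
    d_slow <- compute_dff(traces, f0_slow)
    glom_means <- do.call(rbind, lapply(
      split(seq_along(dem$labels$glomerulus), dem$labels$glomerulus),
      function(idx) colMeans(d_slow$dff[idx, , drop = FALSE])))
    ref <- build_theta_reference(glom_means, band_hz = config$band_hz,
                                 frame_interval_ms = traces$frame_interval_ms)
    windows <- phase_windows(ds)
    merged <- lapply(split(dem$labels$roi_id, dem$labels$subcluster),
                     function(ids) merge_subcluster_train(
                       det$final, ids, config$sync_half_window_ms))
    names(merged) <- paste0("subcluster_", names(merged))
    list(reference = ref,
         result = spike_phases(merged, ref, windows))
  })
  res$phase <- pha

  if (!is.null(out_dir)) {
    res$manifest <- write_run_outputs(res, config, out_dir)
  }
  invisible(res)
}

phase_windows <- function(ds) {
  w <- ds$config$odor_window_s
  dur <- ds$config$duration_s * 1000
  if (is.null(w)) return(NULL)
  tibble(condition = c("baseline", "odor"),
         t0_ms = c(0, w[1] * 1000),
         t1_ms = c(w[1] * 1000, min(w[2] * 1000, dur)))
}

write_run_outputs <- function(res, config, out_dir) {
  if (dir.exists(out_dir) && length(list.files(out_dir))) {
    abort("`out_dir` exists and is not empty.")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- character(0)
  put <- function(name, writer) {
    p <- file.path(out_dir, name)
    writer(p)
    paths[[length(paths) + 1]] <<- p
    p
  }
  cfg_json <- unclass(config)
  cfg_json$sim <- unclass(cfg_json$sim)
  put("config.json", function(p) jsonlite::write_json(
    unclass(cfg_json), p, auto_unbox = TRUE, digits = NA, null = "null",
    pretty = TRUE))
  put("labels.csv", function(p) write.csv(res$demix$labels, p,
                                          row.names = FALSE))
  put("spikes_clustering.csv",
      function(p) write_spikes_csv(res$spikes$clustering, p))
  put("spikes_final.csv", function(p) write_spikes_csv(res$spikes$final, p))
  put("correlation_matrix.csv", function(p)
    write.csv(round(res$demix$correlation, 10), p))
  put("synchronicity_matrix.csv", function(p)
    write.csv(round(res$demix$sync, 10), p))
  if (!is.null(res$demix$sister)) {
    put("sister_comparison.csv", function(p)
      write.csv(res$demix$sister$pairs, p, row.names = FALSE))
  }
  put("phase_summary.csv", function(p)
    write.csv(res$phase$result$summary, p, row.names = FALSE))
  if (!is.null(res$roi_filter)) {
    put("roi_exclusions.csv", function(p)
      write.csv(res$roi_filter$excluded, p, row.names = FALSE))
  }
  if (isTRUE(config$write_traces)) {
    put("traces.csv", function(p) write_traces_csv(res$dataset$traces, p))
  }
  put("report.txt", function(p) {
    s <- res$demix$sister
    lines <- c(
      "demixing pipeline report",
      sprintf("ROIs analysed: %d", nrow(res$demix$labels)),
      sprintf("glomerulus clusters: %d",
              length(unique(res$demix$labels$glomerulus))),
      sprintf("subclusters (putative neurons): %d",
              length(unique(res$demix$labels$subcluster))),
      if (!is.null(s)) sprintf(
        "sister synchrony: same-glomerulus mean SI %.3f vs different %.3f (p = %.3g)",
        s$mean_same, s$mean_diff, s$p_value),
      sprintf("spikes (final threshold): %d", nrow(res$spikes$final)))
    writeLines(lines, p)
  })
  stages <- c("simulate", "preprocess", "detect", "demix", "phase")
  manifest <- list(
    stages = stages,
    parameters = cfg_json,
    files = lapply(stats::setNames(paths, basename(unlist(paths))),
                   function(p) unname(tools::md5sum(p))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null",
                       pretty = TRUE)
  manifest
}

#' Validate a trace container or dataset
#'
#' Checks shapes, finiteness, metadata completeness and (for full
#' datasets) ground-truth consistency, reporting each finding instead of
#' erroring.
#'
#' @param x A [trace_set()], `dff_set`, or `voltage_dataset`.
#' @return Tibble with columns `check`, `status` (`"pass"`/`"fail"`) and
#'   `detail`; overall result as attribute `pass`.
#' @export
validate_dataset <- function(x) {
  findings <- list()
  note <- function(check, ok, detail = "") {
    findings[[length(findings) + 1]] <<-
      tibble(check = check, status = if (ok) "pass" else "fail",
             detail = detail)
  }
  if (inherits(x, "voltage_dataset")) {
    gt <- x$ground_truth
    note("roi_map_ids", all(x$traces$roi_ids %in% x$roi_map$roi_id),
         "every trace ROI appears in the ROI map")
    note("neuron_map",
         all(stats::na.omit(gt$neuron_of_roi) %in%
               seq_along(gt$true_spike_times_ms)),
         "every ROI maps to a known neuron")
    note("glomerulus_map",
         length(gt$glomerulus_of_neuron) ==
           length(gt$true_spike_times_ms),
         "every neuron maps to a glomerulus")
    dur <- x$config$duration_s * 1000
    inside <- all(vapply(gt$true_spike_times_ms, function(s) {
      !length(s) || (min(s) > 0 && max(s) < dur)
    }, logical(1)))
    note("spike_times_inside", inside,
         "true spike times strictly inside (0, duration)")
    x <- x$traces
  }
  if (inherits(x, c("trace_set", "dff_set"))) {
    m <- as.matrix(x)
    if (all(is.finite(m))) {
      note("finite", TRUE, "all samples finite")
    } else {
      bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
      note("finite", FALSE,
           sprintf("non-finite value at ROI '%s', frame %d",
                   (rownames(m) %||% as.character(seq_len(nrow(m))))[bad[1]],
                   bad[2]))
    }
    fi <- x$frame_interval_ms
    note("frame_interval",
         is.numeric(fi) && length(fi) == 1 && is.finite(fi) && fi > 0,
         "frame_interval_ms present and positive")
    note("roi_ids", !anyDuplicated(x$roi_ids) &&
           length(x$roi_ids) == nrow(m), "ROI ids unique and complete")
    note("n_frames", ncol(m) >= 1, "at least one frame")
  } else if (!length(findings)) {
    note("type", FALSE, "not a trace_set, dff_set or voltage_dataset")
  }
  out <- dplyr::bind_rows(findings)
  attr(out, "pass") <- all(out$status == "pass")
  out
}

# ---- on-disk formats ------------------------------------------------------

#' Write and read trace CSV files
#'
#' Traces are stored frames x ROIs with a header of ROI ids (the
#' conventional orientation for spreadsheet inspection); the frame
#' interval travels separately (sidecar JSON or function argument).
#'
#' @param x A [trace_set()] or `dff_set`.
#' @param path CSV file path.
#' @return `write_traces_csv()`: the path, invisibly. `read_traces_csv()`:
#'   a [trace_set()].
#' @export
write_traces_csv <- function(x, path) {
  m <- t(as.matrix(x))
  colnames(m) <- if (inherits(x, c("trace_set", "dff_set"))) x$roi_ids
                 else colnames(m)
  write.csv(m, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @param frame_interval_ms,modality,polarity Metadata for the
#'   reconstructed [trace_set()].
#' @export
read_traces_csv <- function(path, frame_interval_ms = 1,
                            modality = "voltage", polarity = NULL) {
  m <- as.matrix(read.csv(path, check.names = FALSE))
  trace_set(t(m), frame_interval_ms = frame_interval_ms,
            roi_ids = colnames(m), modality = modality, polarity = polarity)
}

#' Write and read spike-train CSV files
#'
#' Two columns: `roi_id`, `time_ms`.
#'
#' @param spikes A `spike_trains` tibble.
#' @param path CSV file path.
#' @return `write_spikes_csv()`: the path, invisibly. `read_spikes_csv()`:
#'   a `spike_trains` tibble.
#' @export
write_spikes_csv <- function(spikes, path) {
  write.csv(as.data.frame(spikes[, c("roi_id", "time_ms")]), path,
            row.names = FALSE)
  invisible(path)
}

#' @rdname write_spikes_csv
#' @param roi_ids Optional full ROI roster (so spikeless ROIs survive the
#'   round trip).
#' @export
read_spikes_csv <- function(path, roi_ids = NULL) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  new_spike_trains(as_tibble(df), roi_ids = roi_ids %||% unique(df$roi_id))
}

#' Write a synthetic dataset to a directory
#'
#' Plain-text container: `traces.csv` (frames x ROIs), `roi_map.csv`,
#' `true_spikes.csv` (`neuron_id`, `time_ms`), `ground_truth.json`
#' (hierarchy, latencies, stimulus onsets) and `config.json` echoing the
#' full [sim_config()] including the seed.
#'
#' @param dataset A `voltage_dataset`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  stopifnot(inherits(dataset, "voltage_dataset"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_traces_csv(dataset$traces, file.path(dir, "traces.csv"))
  rm_out <- dataset$roi_map
  rm_out$footprint <- NULL
  write.csv(rm_out, file.path(dir, "roi_map.csv"), row.names = FALSE)
  gt <- dataset$ground_truth
  spikes <- tibble(
    neuron_id = rep(names(gt$true_spike_times_ms),
                    lengths(gt$true_spike_times_ms)),
    time_ms = unlist(gt$true_spike_times_ms, use.names = FALSE))
  write.csv(spikes, file.path(dir, "true_spikes.csv"), row.names = FALSE)
  jsonlite::write_json(
    list(glomerulus_of_neuron = as.list(gt$glomerulus_of_neuron),
         neuron_of_roi = as.list(gt$neuron_of_roi),
         roi_latency_ms = as.list(gt$roi_latency_ms),
         stimulus_onsets_ms = gt$stimulus_onsets_ms),
    file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  cfg <- unclass(dataset$config)
  cfg$geometry <- NULL
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(dir)
}

#' Read a dataset directory written by [write_dataset()]
#'
#' @param dir Directory path.
#' @return A `voltage_dataset` (without pixel footprints).
#' @export
read_dataset <- function(dir) {
  cfgfile <- file.path(dir, "config.json")
  if (!file.exists(cfgfile)) abort("no config.json found; not a dataset directory.")
  cfg <- jsonlite::read_json(cfgfile, simplifyVector = TRUE)
  cfg_obj <- tryCatch(do.call(sim_config, cfg[!vapply(cfg, is.null,
                                                      logical(1))]),
                      error = function(e) NULL)
  traces <- read_traces_csv(file.path(dir, "traces.csv"),
                            frame_interval_ms = cfg$frame_interval_ms %||% 1,
                            modality = "voltage")
  roi_map <- as_tibble(read.csv(file.path(dir, "roi_map.csv"),
                                stringsAsFactors = FALSE))
  gt <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                            simplifyVector = TRUE)
  spikes <- read.csv(file.path(dir, "true_spikes.csv"),
                     stringsAsFactors = FALSE)
  gt$true_spike_times_ms <- split(spikes$time_ms, spikes$neuron_id)
  structure(list(traces = traces, roi_map = roi_map,
                 ground_truth = gt, config = cfg_obj %||% cfg),
            class = "voltage_dataset")
}

#' Read a pipeline configuration from YAML
#'
#' The YAML keys mirror [pipeline_config()]; a nested `sim:` block is
#' passed to [sim_config()].
#'
#' @param path YAML file path.
#' @return A [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (!is.null(y$sim)) y$sim <- do.call(sim_config, y$sim)
  do.call(pipeline_config, y)
}
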