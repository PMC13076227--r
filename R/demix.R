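#' Filter ROIs by size and glomerular membership
#'
#' Drops ROIs smaller than `min_pixels` pixels (strict `<`) and ROIs
#' outside any glomerulus (`glomerular_label == 0`), the standard
#' pre-filter before demixing dendritic voltage traces. Every exclusion is
#' reported with its reason.
#'
#' @param roi_map Tibble with at least `roi_id`, `pixel_count` and
#'   `glomerular_label` (0 = outside all glomeruli).
#' @param min_pixels Minimum pixel count to retain (default 5).
#' @return A list of class `roi_filter`: `retained` (the filtered
#'   `roi_map`) and `excluded` (tibble of `roi_id`, `reason`).
#' @export
#' @examples
#' rm <- tibble::tibble(roi_id = c("a", "b", "c"),
#'                      pixel_count = c(4L, 12L, 50L),
#'                      glomerular_label = c(1L, 1L, 0L))
#' filter_rois(rm)
filter_rois <- function(roi_map, min_pixels = 5) {
  stopifnot(all(c("roi_id", "pixel_count", "glomerular_label") %in%
                  names(roi_map)))
  too_small <- roi_map$pixel_count < min_pixels
  outside <- roi_map$glomerular_label == 0
  drop <- too_small | outside
  reason <- dplyr::case_when(
    too_small & outside ~ "too_small; outside_glomeruli",
    too_small ~ "too_small",
    outside ~ "outside_glomeruli",
    TRUE ~ NA_character_
  )
  if (all(drop)) abort("all ROIs were excluded by the size/location filter.")
  structure(
    list(retained = roi_map[!drop, , drop = FALSE],
         excluded = tibble(roi_id = roi_map$roi_id[drop],
                           reason = reason[drop])),
    class = "roi_filter")
}

#' @export
print.roi_filter <- function(x, ...) {
  cat(sprintf("<roi_filter> %d retained, %d excluded\n",
              nrow(x$retained), nrow(x$excluded)))
  if (nrow(x$excluded)) print(x$excluded, n = 10)
  invisible(x)
}

#' Zero-lag Pearson correlation matrix of traces
#'
#' @param x A `dff_set`, [trace_set()] or numeric matrix (ROI x frame).
#' @return Symmetric correlation matrix with unit diagonal and ROI ids as
#'   dimnames. A zero-variance ROI is an error naming the ROI.
#' @export
correlation_matrix <- function(x) {
  m <- trace_matrix(x)
  if (nrow(m) < 2) abort("need at least 2 ROIs.")
  if (ncol(m) < 3) abort("need at least 3 frames.")
  v <- apply(m, 1, var)
  if (any(v == 0)) {
    ids <- rownames(m) %||% as.character(seq_len(nrow(m)))
    abort(sprintf("ROI '%s' has zero variance; correlation is undefined.",
                  ids[which(v == 0)[1]]))
  }
  cc <- cor(t(m))
  diag(cc) <- 1
  cc
}

#' Assign ROIs to glomeruli by k-means on the correlation matrix
#'
#' Rows of the ROI x ROI correlation matrix serve as feature vectors
#' (Euclidean distance); k is fixed to the anatomical number of glomeruli.
#' Each restart is seeded with k-means++ and the best solution by total
#' within-cluster sum of squares is kept. Labels are arbitrary up to
#' permutation, so agreement with a reference partition should be scored
#' with the adjusted Rand index.
#'
#' @param corr Correlation matrix from [correlation_matrix()] (or, with
#'   `features = "traces"`, a ROI x frame matrix clustered directly).
#' @param k Number of glomeruli.
#' @param seed Integer seed fixing the restarts.
#' @param n_restarts Number of k-means++ restarts (default 50).
#' @param features `"correlation"` (rows of the correlation matrix; the
#'   default) or `"traces"`.
#' @return Tibble with `roi_id` and integer `glomerulus`; the fitted
#'   `stats::kmeans` object is attached as attribute `kmeans`.
#' @export
cluster_glomeruli <- function(corr, k, seed = 1, n_restarts = 50,
                              features = c("correlation", "traces")) {
  features <- match.arg(features)
  X <- as.matrix(corr)
  if (features == "correlation" && nrow(X) != ncol(X)) {
    abort("`corr` must be square when `features = \"correlation\"`.")
  }
  n <- nrow(X)
  if (k < 1 || k > n) abort(sprintf("`k` must be between 1 and %d.", n))
  ids <- rownames(X) %||% paste0("roi_", seq_len(n))
  km <- withr::with_seed(seed, kmeans_pp(X, k, n_restarts))
  structure(tibble(roi_id = ids, glomerulus = as.integer(km$cluster)),
            kmeans = km)
}

# k-means with k-means++ seeding, best of n_restarts by within-cluster SS
kmeans_pp <- function(X, k, n_restarts) {
  n <- nrow(X)
  if (k == 1) return(kmeans(X, centers = 1))
  best <- NULL
  for (r in seq_len(n_restarts)) {
    centres <- matrix(NA_real_, k, ncol(X))
    centres[1, ] <- X[sample.int(n, 1), ]
    d2 <- rowSums((X - matrix(centres[1, ], n, ncol(X), byrow = TRUE))^2)
    for (j in seq(2, k)) {
      if (all(d2 == 0)) {
        centres[j, ] <- X[sample.int(n, 1), ]
      } else {
        i <- sample.int(n, 1, prob = d2 / sum(d2))
        centres[j, ] <- X[i, ]
        d2 <- pmin(d2, rowSums((X - matrix(centres[j, ], n, ncol(X),
                                           byrow = TRUE))^2))
      }
    }
    km <- tryCatch(
      suppressWarnings(kmeans(X, centers = centres, iter.max = 100)),
      error = function(e) NULL)
    if (!is.null(km) &&
        (is.null(best) || km$tot.withinss < best$tot.withinss)) {
      best <- km
    }
  }
  if (is.null(best)) abort("k-means failed to converge from any restart.")
  best
}

#' Spike synchronicity index between two trains
#'
#' A synchronous event is a spike in one train matched one-to-one to a
#' spike in the other within +/- `half_window_ms` (inclusive; the default
#' +/-7 ms is a 21-ms window at 7-ms frames). Matching is greedy by
#' nearest time difference, so no spike is counted twice. The index is the
#' number of matches divided by half the total number of spikes:
#' `SI = matches / ((nA + nB) / 2)`, which is 1 for identical trains and 0
#' for disjoint ones. Two empty trains give 0 with attribute
#' `both_empty = TRUE`.
#'
#' @param a,b Sorted numeric vectors of spike times (ms).
#' @param half_window_ms Coincidence half-window (default 7).
#' @return The synchronicity index in \[0, 1\].
#' @export
#' @examples
#' synchronicity_index(c(0, 100, 200), c(5, 300))  # 1 match -> 0.4
synchronicity_index <- function(a, b, half_window_ms = 7) {
  if (is.unsorted(a) || is.unsorted(b)) {
    abort("spike trains must be sorted in time.")
  }
  na <- length(a); nb <- length(b)
  if (na + nb == 0) return(structure(0, both_empty = TRUE))
  if (na == 0 || nb == 0) return(0)
  matches <- count_coincident(a, b, half_window_ms)
  matches / ((na + nb) / 2)
}

# greedy one-to-one nearest-time matching within +/- w (inclusive)
count_coincident <- function(a, b, w) {
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) return(0L)
  lo <- findInterval(a - w, b, left.open = TRUE)
  hi <- findInterval(a + w, b)
  nc <- pmax(hi - lo, 0L)
  if (all(nc == 0L)) return(0L)
  ii <- rep.int(seq_len(na), nc)
  jj <- sequence(nc, from = lo + 1L)
  d <- abs(a[ii] - b[jj])
  ord <- order(d, ii, jj)
  used_a <- logical(na); used_b <- logical(nb)
  m <- 0L
  for (k in ord) {
    i <- ii[k]; j <- jj[k]
    if (!used_a[i] && !used_b[j]) {
      used_a[i] <- TRUE; used_b[j] <- TRUE
      m <- m + 1L
    }
  }
  m
}

#' Pairwise synchronicity matrix
#'
#' @param spikes A `spike_trains` tibble from [detect_spikes()] or a named
#'   list of sorted spike-time vectors.
#' @param half_window_ms Coincidence half-window in ms (default 7).
#' @return Symmetric matrix of synchronicity indices. Diagonal entries are
#'   1 for non-empty trains and 0 for empty ones; ids of empty trains are
#'   attached as attribute `empty_rois`.
#' @export
synchronicity_matrix <- function(spikes, half_window_ms = 7) {
  trains <- spike_train_list(spikes)
  n <- length(trains)
  S <- matrix(0, n, n, dimnames = list(names(trains), names(trains)))
  diag(S) <- ifelse(lengths(trains) > 0, 1, 0)
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in seq(i + 1, n)) {
        S[i, j] <- S[j, i] <-
          as.numeric(synchronicity_index(trains[[i]], trains[[j]],
                                         half_window_ms))
      }
    }
  }
  structure(S, empty_rois = names(trains)[lengths(trains) == 0])
}

#' Subcluster ROIs into putative single neurons
#'
#' Within each glomerulus independently, agglomerative clustering
#' (average linkage by default) on the distance `d = 1 - SI` groups ROIs
#' whose backpropagating spikes are synchronous; the dendrogram is cut at
#' `threshold_fraction` (default 10%) of the maximum merge distance. By
#' default the maximum is taken over the whole dataset's dendrograms
#' (`threshold_scope = "dataset"`), which keeps the cut height meaningful
#' for glomeruli that contain a single neuron; `"glomerulus"` applies the
#' fraction to each glomerulus's own maximum. Each retained ROI receives a
#' globally unique subcluster id, and subclusters never span two
#' glomeruli.
#'
#' @param sync Synchronicity matrix from [synchronicity_matrix()].
#' @param glomerulus_labels Integer vector of glomerulus labels aligned
#'   with the rows of `sync`, or the tibble returned by
#'   [cluster_glomeruli()].
#' @param threshold_fraction Dendrogram cut as a fraction of the maximum
#'   merge distance (default 0.10).
#' @param linkage Agglomeration method (default `"average"`).
#' @param threshold_scope `"dataset"` (default) or `"glomerulus"`; see
#'   Details.
#' @return Tibble with `roi_id`, `glomerulus`, `subcluster` (globally
#'   unique integers).
#' @export
subcluster_neurons <- function(sync, glomerulus_labels,
                               threshold_fraction = 0.10,
                               linkage = "average",
                               threshold_scope = c("dataset", "glomerulus")) {
  threshold_scope <- match.arg(threshold_scope)
  if (is.data.frame(glomerulus_labels)) {
    labels <- glomerulus_labels$glomerulus
    ids <- glomerulus_labels$roi_id
  } else {
    labels <- glomerulus_labels
    ids <- rownames(sync) %||% paste0("roi_", seq_along(labels))
  }
  if (length(labels) != nrow(sync)) {
    abort("`glomerulus_labels` must have one label per row of `sync`.")
  }
  gloms <- unique(labels)
  dendro <- list()
  for (g in gloms) {
    idx <- which(labels == g)
    if (length(idx) > 1) {
      dendro[[as.character(g)]] <-
        hclust(stats::as.dist(1 - sync[idx, idx, drop = FALSE]),
               method = linkage)
    }
  }
  max_all <- max(c(0, unlist(lapply(dendro, `[[`, "height"))))
  sub <- integer(length(labels))
  nxt <- 1L
  for (g in gloms) {
    idx <- which(labels == g)
    if (length(idx) == 1) {
      sub[idx] <- nxt
      nxt <- nxt + 1L
      next
    }
    hc <- dendro[[as.character(g)]]
    h_max <- if (threshold_scope == "dataset") max_all else max(hc$height)
    lab <- cutree(hc, h = threshold_fraction * h_max)
    sub[idx] <- lab + nxt - 1L
    nxt <- nxt + max(lab)
  }
  tibble(roi_id = ids, glomerulus = as.integer(labels),
         subcluster = as.integer(sub))
}

#' Merge the spike trains of a subcluster
#'
#' Pools the member-ROI trains and collapses events that fall within the
#' coincidence half-window of the previously kept event (they are the same
#' underlying spike seen on several dendritic branches).
#'
#' @param spikes `spike_trains` tibble or named list of trains.
#' @param members Character vector of member ROI ids.
#' @param half_window_ms Deduplication half-window (default 7).
#' @return Sorted numeric vector of merged event times (ms).
#' @export
merge_subcluster_train <- function(spikes, members, half_window_ms = 7) {
  trains <- spike_train_list(spikes)
  x <- sort(unlist(trains[members], use.names = FALSE))
  if (length(x) < 2) return(x)
  keep <- x[1]
  for (v in x[-1]) {
    if (v - keep[length(keep)] > half_window_ms) keep <- c(keep, v)
  }
  keep
}

#' Compare spike synchrony of sister versus non-sister subclusters
#'
#' Forms one merged spike train per subcluster, computes the synchronicity
#' index for every subcluster pair, and contrasts pairs belonging to the
#' same glomerulus ("sister" mitral/tufted cells) against pairs from
#' different glomeruli with a two-sided Wilcoxon rank-sum test.
#'
#' @param labels Tibble from [subcluster_neurons()] (`roi_id`,
#'   `glomerulus`, `subcluster`).
#' @param spikes `spike_trains` tibble or named list of per-ROI trains
#'   (typically the final, 3-SD detection).
#' @param half_window_ms Coincidence half-window (default 7).
#' @return A `sister_synchrony` object: list with `pairs` (tibble of
#'   `sub_a`, `sub_b`, `same_glomerulus`, `si`), `mean_same`, `mean_diff`,
#'   `n_same`, `n_diff`, `p_value` (NA when either group is empty).
#' @export
sister_synchrony_comparison <- function(labels, spikes, half_window_ms = 7) {
  stopifnot(all(c("roi_id", "glomerulus", "subcluster") %in% names(labels)))
  subs <- sort(unique(labels$subcluster))
  if (length(subs) < 2) abort("need at least two subclusters to compare.")
  glom_of_sub <- vapply(subs, function(s) {
    labels$glomerulus[labels$subcluster == s][1]
  }, numeric(1))
  merged <- lapply(subs, function(s) {
    merge_subcluster_train(spikes, labels$roi_id[labels$subcluster == s],
                           half_window_ms)
  })
  pr <- utils::combn(seq_along(subs), 2)
  si <- vapply(seq_len(ncol(pr)), function(k) {
    as.numeric(synchronicity_index(merged[[pr[1, k]]], merged[[pr[2, k]]],
                                   half_window_ms))
  }, numeric(1))
  same <- glom_of_sub[pr[1, ]] == glom_of_sub[pr[2, ]]
  p <- if (any(same) && any(!same)) {
    suppressWarnings(wilcox.test(si[same], si[!same])$p.value)
  } else {
    NA_real_
  }
  structure(
    list(pairs = tibble(sub_a = subs[pr[1, ]], sub_b = subs[pr[2, ]],
                        same_glomerulus = same, si = si),
         mean_same = if (any(same)) mean(si[same]) else NA_real_,
         mean_diff = if (any(!same)) mean(si[!same]) else NA_real_,
         n_same = sum(same), n_diff = sum(!same), p_value = p,
         half_window_ms = half_window_ms),
    class = "sister_synchrony")
}

#' @export
print.sister_synchrony <- function(x, ...) {
  cat(sprintf(
    "<sister_synchrony> same-glomerulus pairs: %d (mean SI %.3f); different: %d (mean SI %.3f)\n",
    x$n_same, x$mean_same, x$n_diff, x$mean_diff))
  cat(sprintf("  Wilcoxon rank-sum p = %s\n", format.pval(x$p_value)))
  invisible(x)
}

#' Glance at a sister-synchrony comparison
#'
#' @param x A `sister_synchrony` object.
#' @param ... Unused.
#' @return One-row tibble with the group means, counts and p-value.
#' @export
glance.sister_synchrony <- function(x, ...) {
  tibble(mean_same = x$mean_same, mean_diff = x$mean_diff,
         n_same = x$n_same, n_diff = x$n_diff, p_value = x$p_value)
}
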