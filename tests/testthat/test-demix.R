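# ROI filtering, correlation clustering, synchronicity and subclustering.

test_that("ROI filter applies the strict 5-pixel rule and the glomerular mask", {
  rm <- tibble::tibble(
    roi_id = c("small_in", "boundary", "big_out", "big_in"),
    pixel_count = c(4L, 5L, 50L, 12L),
    glomerular_label = c(1L, 2L, 0L, 1L))
  flt <- filter_rois(rm)
  expect_setequal(flt$retained$roi_id, c("boundary", "big_in"))
  expect_equal(flt$excluded$reason[flt$excluded$roi_id == "small_in"],
               "too_small")
  expect_equal(flt$excluded$reason[flt$excluded$roi_id == "big_out"],
               "outside_glomeruli")
  rm_all_bad <- tibble::tibble(roi_id = "x", pixel_count = 2L,
                               glomerular_label = 0L)
  expect_error(filter_rois(rm_all_bad), "all ROIs")
})

test_that("correlation matrix matches the hand Pearson computation and flags zero variance", {
  x <- c(1, 2, 3, 4, 5)
  y <- c(2, 4, 5, 4, 5)
  cc <- correlation_matrix(rbind(x, y))
  expect_equal(cc[1, 2], 0.7746, tolerance = 1e-3)
  expect_equal(diag(cc), c(x = 1, y = 1))
  cc2 <- correlation_matrix(rbind(a = x, b = -x + 10))
  expect_equal(cc2["a", "b"], -1)
  expect_error(correlation_matrix(rbind(a = x, flatliner = rep(1, 5))),
               "flatliner")
})

test_that("k-means recovers separable correlation blocks and honours k", {
  block <- matrix(0, 12, 12)
  block[1:6, 1:6] <- 1
  block[7:12, 7:12] <- 1
  diag(block) <- 1
  lab <- cluster_glomeruli(block, k = 2, seed = 1)
  expect_equal(ari(lab$glomerulus, rep(1:2, each = 6)), 1)
  lab1 <- cluster_glomeruli(block, k = 1, seed = 1)
  expect_equal(unique(lab1$glomerulus), 1L)
  expect_error(cluster_glomeruli(block, k = 13, seed = 1), "between")
  expect_identical(cluster_glomeruli(block, 2, seed = 7)$glomerulus,
                   cluster_glomeruli(block, 2, seed = 7)$glomerulus)
})

test_that("synchronicity index reproduces the worked examples", {
  t10 <- seq(0, 900, by = 100)
  expect_equal(as.numeric(synchronicity_index(t10, t10)), 1)
  expect_equal(as.numeric(synchronicity_index(c(0, 100, 200), c(5, 300))),
               0.4)
  expect_equal(as.numeric(synchronicity_index(c(0, 50), c(500, 900))), 0)
  both <- synchronicity_index(numeric(0), numeric(0))
  expect_equal(as.numeric(both), 0)
  expect_true(attr(both, "both_empty"))
  expect_error(synchronicity_index(c(5, 1), c(0)), "sorted")
  # window boundary is inclusive
  expect_equal(as.numeric(synchronicity_index(0, 7)), 1)
  expect_equal(as.numeric(synchronicity_index(0, 7.001)), 0)
})

test_that("synchronicity index is symmetric, bounded and obeys the matching bound", {
  withr::with_seed(77, {
    for (i in 1:200) {
      a <- sort(runif(sample(0:12, 1), 0, 500))
      b <- sort(runif(sample(0:12, 1), 0, 500))
      sab <- as.numeric(synchronicity_index(a, b))
      expect_equal(sab, as.numeric(synchronicity_index(b, a)))
      expect_gte(sab, 0)
      expect_lte(sab, 1)
      if (length(a) + length(b) > 0) {
        expect_lte(sab, 2 * min(length(a), length(b)) /
                     max(1, length(a) + length(b)))
      }
    }
  })
})

test_that("greedy matcher is near-optimal against exhaustive bipartite matching", {
  withr::with_seed(88, {
    deficit <- vapply(1:300, function(i) {
      a <- sort(runif(sample(1:8, 1), 0, 60))
      b <- sort(runif(sample(1:8, 1), 0, 60))
      opt <- optimal_match_count(a, b, 7)
      greedy <- voltdemix:::count_coincident(a, b, 7)
      expect_lte(greedy, opt)
      opt - greedy
    }, numeric(1))
    # even at this density (far above physiological) the greedy matcher
    # drops at most one match per pair
    expect_lte(max(deficit), 1)
  })
})

test_that("synchronicity matrix equals elementwise computation and handles edge cases", {
  trains <- list(a = c(0, 100, 200), b = c(5, 300), c = numeric(0))
  S <- synchronicity_matrix(trains)
  for (i in 1:3) {
    for (j in 1:3) {
      if (i != j) {
        expect_equal(S[i, j], as.numeric(
          synchronicity_index(trains[[i]], trains[[j]])))
      }
    }
  }
  expect_equal(diag(S), c(a = 1, b = 1, c = 0))
  expect_equal(attr(S, "empty_rois"), "c")
  expect_equal(S, t(S))
  single <- synchronicity_matrix(list(only = c(1, 2, 3)))
  expect_equal(dim(single), c(1, 1))
  allempty <- synchronicity_matrix(list(x = numeric(0), y = numeric(0)))
  expect_true(all(allempty == 0))
})

test_that("subclustering separates neurons and respects degenerate similarity", {
  ids <- sprintf("r%d", 1:6)
  S1 <- matrix(1, 6, 6, dimnames = list(ids, ids))
  lab <- subcluster_neurons(S1, rep(1L, 6))
  expect_equal(length(unique(lab$subcluster)), 1)

  S0 <- diag(6); dimnames(S0) <- list(ids, ids)
  lab0 <- subcluster_neurons(S0, rep(1L, 6))
  expect_equal(length(unique(lab0$subcluster)), 6)

  # two neurons x 3 ROIs in one glomerulus: within ~0.95, across ~0.2
  S <- matrix(0.2, 6, 6, dimnames = list(ids, ids))
  S[1:3, 1:3] <- 0.95
  S[4:6, 4:6] <- 0.95
  diag(S) <- 1
  lab2 <- subcluster_neurons(S, rep(1L, 6))
  expect_equal(ari(lab2$subcluster, rep(1:2, each = 3)), 1)
  # subclusters never span glomerulus labels
  lab3 <- subcluster_neurons(S, c(1L, 1L, 1L, 2L, 2L, 2L))
  tab <- table(lab3$subcluster, lab3$glomerulus)
  expect_true(all(rowSums(tab > 0) == 1))
})

test_that("subcluster count is weakly decreasing in the threshold fraction", {
  withr::with_seed(5, {
    n <- 12
    S <- matrix(runif(n * n, 0, 0.9), n)
    S <- (S + t(S)) / 2
    diag(S) <- 1
    dimnames(S) <- list(sprintf("r%d", 1:n), sprintf("r%d", 1:n))
  })
  counts <- vapply(c(0.01, 0.1, 0.5), function(f) {
    length(unique(subcluster_neurons(S, rep(1L, 12),
                                     threshold_fraction = f)$subcluster))
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("merged subcluster trains deduplicate events within the window", {
  trains <- list(a = c(0, 100, 200), b = c(3, 103, 400))
  merged <- merge_subcluster_train(trains, c("a", "b"))
  expect_equal(merged, c(0, 100, 200, 400))
})

test_that("sister comparison reports empty same-glomerulus sets instead of erroring", {
  labels <- tibble::tibble(roi_id = c("a", "b"), glomerulus = c(1L, 2L),
                           subcluster = c(1L, 2L))
  trains <- list(a = c(0, 100), b = c(50, 400))
  cmp <- sister_synchrony_comparison(labels, trains)
  expect_equal(cmp$n_same, 0)
  expect_true(is.na(cmp$p_value))
  expect_true(is.na(glance(cmp)$mean_same))
})

test_that("small end-to-end demixing recovers the simulated hierarchy", {
  cfg <- sim_config(n_glomeruli = 3, duration_s = 20, seed = 11)
  res <- run_pipeline(pipeline_config(sim = cfg))
  gt <- res$dataset$ground_truth
  idx <- match(res$demix$labels$roi_id, names(gt$neuron_of_roi))
  expect_gte(ari(res$demix$labels$glomerulus,
                 gt$glomerulus_of_neuron[gt$neuron_of_roi[idx]]), 0.9)
  expect_gte(ari(res$demix$labels$subcluster, gt$neuron_of_roi[idx]), 0.85)
})
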