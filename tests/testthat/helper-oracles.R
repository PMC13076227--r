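# Independent brute-force oracles used across the suite.

# centred rolling median with symmetric edge shrinking, O(n * w)
naive_rolling_median <- function(v, k) {
  h <- (k - 1) / 2
  n <- length(v)
  vapply(seq_len(n), function(i) {
    hh <- min(h, i - 1, n - i)
    median(v[(i - hh):(i + hh)])
  }, numeric(1))
}

# causal sliding percentile with linear interpolation between order
# statistics, written without stats::quantile
naive_sliding_percentile <- function(v, w, p) {
  n <- length(v)
  vapply(seq_len(n), function(i) {
    s <- sort(v[max(1, i - w + 1):i])
    m <- length(s)
    if (m == 1) return(s)
    h <- (m - 1) * p
    lo <- floor(h)
    s[lo + 1] + (h - lo) * (s[min(lo + 2, m)] - s[lo + 1])
  }, numeric(1))
}

# maximum bipartite matching size between two spike trains (igraph oracle)
optimal_match_count <- function(a, b, w = 7) {
  na <- length(a); nb <- length(b)
  if (na == 0 || nb == 0) return(0L)
  edges <- integer(0)
  for (i in seq_len(na)) {
    for (j in seq_len(nb)) {
      if (abs(a[i] - b[j]) <= w) edges <- c(edges, i, na + j)
    }
  }
  if (!length(edges)) return(0L)
  g <- igraph::make_bipartite_graph(c(rep(FALSE, na), rep(TRUE, nb)),
                                    edges = edges)
  igraph::max_bipartite_match(g)$matching_size
}

# sorted homogeneous Poisson train on (0, dur_ms)
poisson_train <- function(rate_hz, dur_ms) {
  t <- cumsum(rexp(ceiling(rate_hz / 1000 * dur_ms * 2 + 20),
                   rate_hz / 1000))
  t[t < dur_ms]
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

# circular absolute difference in degrees
ang_abs_diff <- function(x, y) {
  d <- abs(x - y) %% 360
  pmin(d, 360 - d)
}

# small quiet simulation defaults for unit tests
quick_config <- function(...) {
  sim_config(n_glomeruli = 2, neurons_per_glomerulus = 2,
             rois_per_neuron = 2, ...)
}
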