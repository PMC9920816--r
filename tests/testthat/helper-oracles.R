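# Independent oracles used to cross-check the implementation.

# All-pairs shortest paths by Floyd-Warshall on a dense weight matrix
# (Inf = no edge). Independent of igraph's Dijkstra.
fw_distances <- function(W) {
  n <- nrow(W)
  D <- W
  diag(D) <- 0
  for (k in seq_len(n)) {
    D <- pmin(D, outer(D[, k], D[k, ], `+`))
  }
  D
}

# Peak assignment from a Floyd-Warshall distance matrix, with the same
# tie-break as assign_grid: higher-density peak first, then lower index.
fw_assign <- function(W, peaks, peak_density) {
  D <- fw_distances(W)
  ord <- order(-peak_density, peaks)
  peaks <- peaks[ord]
  sub <- D[peaks, , drop = FALSE]
  peaks[apply(sub, 2L, which.min)]
}

# Random connected weighted graph: a spanning path plus extra random
# edges, weights in (0, 1]. Returns the dense weight matrix and an igraph.
random_graph <- function(n, extra = 2 * n) {
  W <- matrix(Inf, n, n)
  put <- function(i, j, w) { W[i, j] <<- w; W[j, i] <<- w }
  perm <- sample(n)
  for (k in seq_len(n - 1)) put(perm[k], perm[k + 1], runif(1, 0.05, 1))
  for (k in seq_len(extra)) {
    ij <- sample(n, 2)
    put(ij[1], ij[2], runif(1, 0.05, 1))
  }
  el <- which(upper.tri(W) & is.finite(W), arr.ind = TRUE)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, t(el))
  igraph::E(g)$weight <- W[el]
  list(W = W, g = g)
}

# O(n * N) exhaustive nearest-grid-point scan (geodesic distance).
brute_nearest <- function(u, pts) {
  apply(u, 1L, function(v) {
    ang <- acos(pmin(1, pmax(-1, pts %*% v)))
    which.min(ang)
  })
}

# Straight-line re-derivation of the weekly features from a session label
# sequence and a label -> centre lookup; independent of weekly_features().
features_from_labels <- function(labels, centers) {
  k <- length(labels)
  ctr <- centers[as.character(labels), , drop = FALSE]
  hav <- function(p, q) 2 * asin(min(1, sqrt(sum((p - q)^2)) / 2))
  td <- 0; arc <- 0; mot <- c(0, 0, 0); diffs <- NULL
  if (k >= 2) {
    for (i in seq_len(k - 1)) {
      td <- td + hav(ctr[i, ], ctr[i + 1, ])
      arc <- arc + acos(min(1, max(-1, sum(ctr[i, ] * ctr[i + 1, ]))))
      diffs <- rbind(diffs, ctr[i + 1, ] - ctr[i, ])
    }
    mot <- colSums(abs(diffs))
  }
  list(
    n_clusters = length(unique(labels)),
    total_distance = td,
    n_transitions = if (k >= 2) sum(labels[-1] != labels[-k]) else 0,
    median_xyz = apply(ctr, 2L, median),
    sum_motion = mot,
    motion_sd = if (!is.null(diffs) && nrow(diffs) >= 2) {
      apply(diffs, 2L, sd)
    } else c(0, 0, 0),
    arc_sum = arc)
}

# Tiny deterministic cluster_model built by hand (no KDE/graph machinery),
# for feature tests: session labels + centres are given directly.
toy_model <- function(session_labels, centers, user = "u1", week = 2766L) {
  k <- length(session_labels)
  peak_idx <- sort(unique(session_labels))
  readings <- data.frame(
    user_id = user,
    session_id = rep(sprintf("s%02d", seq_len(k)), each = 3),
    t = as.POSIXct("2023-01-02", tz = "UTC") + seq_len(3 * k) * 60,
    label = rep(session_labels, each = 3))
  sessions <- data.frame(
    session_id = sprintf("s%02d", seq_len(k)),
    label = session_labels,
    start = as.POSIXct("2023-01-02", tz = "UTC") + (seq_len(k) - 1) * 180 + 60)
  peaks <- structure(list(
    peak_indices = peak_idx,
    peak_coords = centers[as.character(peak_idx), , drop = FALSE],
    peak_density = rev(seq_along(peak_idx)),
    threshold = 0), class = "peak_set")
  structure(list(peaks = peaks, grid_labels = NULL, readings = readings,
                 sessions = sessions, user_id = user, week_index = week),
            class = "cluster_model")
}

shared_grid <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- make_grid(1000)
    cache
  }
})
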