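#' Candidate density peaks on the grid
#'
#' A candidate peak is a grid point whose density strictly exceeds the
#' density at all 8 of its lattice neighbours (plateaus yield no peak).
#'
#' @param field A [fit_vmf_kde()] `density_field`.
#' @return Integer vector of candidate grid indices (possibly empty).
#' @export
find_peaks <- function(field) {
  d <- field$density
  nb <- field$grid$neighbors
  nbmax <- matrix(d[nb], nrow = nrow(nb))
  nbmax <- do.call(pmax, as.data.frame(nbmax))
  which(d > nbmax)
}

#' Histogram noise threshold for peak rejection
#'
#' The density range is split into `n_bins` equal-width bins; the threshold
#' is the upper edge of the second bin,
#' `min + 2 * (max - min) / n_bins`. Peaks whose density falls below it are
#' treated as noise: the lowest bins hold the parts of the field with
#' next to no readings. For a constant field the threshold equals that
#' constant (and strict peaks cannot exist anyway).
#'
#' @param field A `density_field`.
#' @param n_bins Number of histogram bins (default 50, minimum 2).
#' @return numeric threshold on the density scale.
#' @export
noise_threshold <- function(field, n_bins = 50) {
  stopifnot(n_bins >= 2)
  d <- field$density
  min(d) + 2 * (max(d) - min(d)) / n_bins
}

#' Surviving peak set
#'
#' Candidates from [find_peaks()] with density at or above the
#' [noise_threshold()], sorted by decreasing density (ties by lower grid
#' index).
#'
#' @param field A `density_field`.
#' @param n_bins Histogram bins for the noise threshold.
#' @return Object of class `peak_set`: list with `peak_indices`,
#'   `peak_coords` (k x 3), `peak_density`, `threshold`.
#' @export
find_cluster_peaks <- function(field, n_bins = 50) {
  cand <- find_peaks(field)
  thr <- noise_threshold(field, n_bins)
  keep <- cand[field$density[cand] >= thr]
  keep <- keep[order(-field$density[keep], keep)]
  structure(list(peak_indices = keep,
                 peak_coords = field$grid$points[keep, , drop = FALSE],
                 peak_density = field$density[keep],
                 threshold = thr),
            class = "peak_set")
}

#' @export
print.peak_set <- function(x, ...) {
  cat("peak_set:", length(x$peak_indices), "surviving peak(s), threshold",
      format(x$threshold, digits = 4), "\n")
  invisible(x)
}

#' Density-weighted neighbour graph
#'
#' One undirected edge per lattice neighbour pair, weighted
#' \deqn{w_{ij} = e^{-(f_i + f_j)/2}} where \eqn{f} is the density field.
#' Edges inside high-density regions are short, so shortest paths run
#' uphill towards peaks. Weights lie in (0, 1] for non-negative densities.
#'
#' @param field A `density_field`.
#' @return An [igraph::graph] with vertex count `grid$n` and edge attribute
#'   `weight`.
#' @export
build_graph <- function(field) {
  nb <- field$grid$neighbors
  n <- field$grid$n
  i <- rep(seq_len(n), times = ncol(nb))
  j <- as.vector(nb)
  lo <- pmin(i, j); hi <- pmax(i, j)
  keep <- !duplicated(cbind(lo, hi))
  lo <- lo[keep]; hi <- hi[keep]
  w <- exp(-(field$density[lo] + field$density[hi]) / 2)
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  g <- igraph::add_edges(g, rbind(lo, hi))
  igraph::E(g)$weight <- w
  g
}

#' Assign every graph node to its nearest peak by shortest path
#'
#' Runs Dijkstra from each surviving peak and labels every node with the
#' peak of minimum path length. Ties go to the higher-density peak, then to
#' the lower peak index; each peak is labelled as itself (path length 0).
#'
#' @param graph Weighted undirected [igraph::graph] (edge attribute
#'   `weight`).
#' @param peaks A `peak_set`, or an integer vector of peak node indices
#'   (then `peak_density` supplies the tie-break order).
#' @param peak_density Densities for an integer `peaks` vector; ignored
#'   when `peaks` is a `peak_set`.
#' @return Integer vector: for each node, the grid index of its peak.
#' @export
assign_grid <- function(graph, peaks, peak_density = NULL) {
  if (inherits(peaks, "peak_set")) {
    idx <- peaks$peak_indices
    dens <- peaks$peak_density
  } else {
    idx <- as.integer(peaks)
    dens <- if (is.null(peak_density)) rep(0, length(idx)) else peak_density
  }
  if (!length(idx)) stop("no surviving peaks: no clusters this week")
  ord <- order(-dens, idx)            # tie-break: higher density, lower index
  idx <- idx[ord]
  dmat <- igraph::distances(graph, v = idx, weights = igraph::E(graph)$weight,
                            algorithm = "dijkstra")
  best <- apply(dmat, 2L, which.min)  # first minimum = preferred peak
  idx[best]
}

#' Transfer grid labels to readings by nearest grid point
#'
#' Each reading inherits the label of its nearest grid point (maximum
#' cosine similarity; equivalent to geodesic nearest on the unit sphere).
#' Ties break to the lower grid index.
#'
#' @param readings data.frame with `ux/uy/uz` or an n x 3 unit matrix.
#' @param grid A `sphere_grid`.
#' @param grid_labels Integer labels per grid point from [assign_grid()].
#' @return Integer vector of labels, one per reading.
#' @export
assign_readings <- function(readings, grid, grid_labels) {
  u <- as_unit_matrix(readings)
  sim <- u %*% t(grid$points)                   # n x N
  nearest <- max.col(sim, ties.method = "first")
  grid_labels[nearest]
}

#' Collapse reading labels to one label per session
#'
#' The session label is the modal reading label; ties go to the label
#' whose peak has the higher density.
#'
#' @param session_id Character/factor vector, one entry per reading.
#' @param reading_labels Integer peak labels, one per reading.
#' @param peaks `peak_set` used for the tie-break.
#' @return data.frame with `session_id` and `label`, in order of first
#'   appearance of each session.
#' @export
assign_sessions <- function(session_id, reading_labels, peaks) {
  stopifnot(length(session_id) == length(reading_labels))
  dens <- stats::setNames(peaks$peak_density, peaks$peak_indices)
  sess <- unique(session_id)
  lab <- vapply(sess, function(s) {
    tab <- table(reading_labels[session_id == s])
    cand <- as.integer(names(tab)[tab == max(tab)])
    if (length(cand) > 1L) cand <- cand[order(-dens[as.character(cand)], cand)]
    cand[1L]
  }, integer(1))
  data.frame(session_id = sess, label = lab, stringsAsFactors = FALSE)
}

#' Cluster one user-week of unit readings
#'
#' Full weekly clustering: vMF KDE on the grid, strict 8-neighbour local
#' maxima, histogram noise threshold, density-weighted graph, Dijkstra
#' assignment of grid points, nearest-neighbour label transfer to
#' readings, and modal session labels.
#'
#' @param readings data.frame of one week's unit readings
#'   (`filter_gravity_band()` output) with `session_id` and `t`.
#' @param grid A `sphere_grid` (built once and reused across weeks).
#' @param bandwidth KDE bandwidth or `"auto"`.
#' @param n_bins Histogram bins for the noise threshold.
#' @param min_readings Weeks with fewer readings are skipped (returns
#'   `NULL` with a message).
#' @return Object of class `cluster_model`: list with `peaks` (`peak_set`),
#'   `field`, `grid_labels`, `readings` (input plus `label` column),
#'   `sessions` (session_id, start, label), `user_id`, `week_index`;
#'   or `NULL` when the week is skipped (too few readings or no surviving
#'   peak).
#' @export
cluster_week <- function(readings, grid, bandwidth = "auto", n_bins = 50,
                         min_readings = 50) {
  if (nrow(readings) < min_readings) {
    message("cluster_week: skipping week with ", nrow(readings),
            " reading(s) (< ", min_readings, ")")
    return(NULL)
  }
  field <- fit_vmf_kde(readings, grid, bandwidth)
  peaks <- find_cluster_peaks(field, n_bins)
  if (!length(peaks$peak_indices)) {
    message("cluster_week: no surviving peaks; skipping week")
    return(NULL)
  }
  graph <- build_graph(field)
  grid_labels <- assign_grid(graph, peaks)
  readings$label <- assign_readings(readings, grid, grid_labels)
  ord <- order(readings$t)
  sess_first <- readings[ord, ][!duplicated(readings$session_id[ord]), ]
  sessions <- assign_sessions(readings$session_id, readings$label, peaks)
  sessions <- sessions[match(sess_first$session_id, sessions$session_id), ]
  sessions$start <- sess_first$t
  rownames(sessions) <- NULL
  structure(list(peaks = peaks, field = field, grid_labels = grid_labels,
                 readings = readings, sessions = sessions,
                 user_id = readings$user_id[1],
                 week_index = if (!is.null(readings$week_index))
                   readings$week_index[1] else iso_week_index(readings$t[1])),
            class = "cluster_model")
}

#' @export
print.cluster_model <- function(x, ...) {
  cat(sprintf(
    "cluster_model: user %s week %s | %d peak(s), %d readings, %d sessions\n",
    x$user_id, iso_week_label(x$week_index),
    length(x$peaks$peak_indices), nrow(x$readings), nrow(x$sessions)))
  invisible(x)
}
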