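#' Great-circle (haversine) distance between unit vectors
#'
#' Central angle between two points on the unit sphere via the haversine
#' formulation `2 * asin(||p - q|| / 2)`, numerically stable near 0 and
#' near pi. Symmetric, in [0, pi].
#'
#' @param p,q Unit 3-vectors (or n x 3 matrices, recycled rowwise).
#' @return Angle(s) in radians.
#' @examples
#' haversine(c(0, 0, 1), c(1, 0, 0))  # pi / 2
#' @export
haversine <- function(p, q) {
  p <- rbind(p); q <- rbind(q)
  chk <- function(m) {
    if (any(abs(sqrt(rowSums(m^2)) - 1) > 1e-6)) {
      stop("haversine: inputs must be unit vectors")
    }
  }
  chk(p); chk(q)
  half_chord <- sqrt(rowSums((p - q)^2)) / 2
  2 * asin(pmin(1, half_chord))
}

#' Weekly orientation feature vector
#'
#' Computes the per-week orientation features from a [cluster_week()]
#' model. Sessions are ordered by start time; a session's "centre" is the
#' unit-sphere coordinate of its peak. Features:
#' \describe{
#'   \item{n_clusters}{distinct orientation clusters used by the week's
#'     sessions}
#'   \item{total_distance_between_clusters}{sum of haversine distances
#'     between consecutive session centres (radians)}
#'   \item{avg_n_clusters_perSession}{mean number of distinct reading
#'     labels within a session}
#'   \item{avg_n_transitions_perSession}{mean number of consecutive
#'     reading-label changes within a session}
#'   \item{n_cluster_transitions}{number of consecutive session-label
#'     changes}
#'   \item{median_X/Y/Z}{median over sessions of the session centre
#'     coordinates}
#'   \item{sum_X/Y/Z_motion}{sum of |differences| of consecutive session
#'     centre coordinates}
#'   \item{X/Y/Z_motion_sd}{standard deviation (n-1) of those signed
#'     differences; 0 with fewer than two differences}
#'   \item{arc_sum}{sum of central angles (arccos of the clamped dot
#'     product) between consecutive session centres; equals
#'     total_distance_between_clusters by construction and is kept as a
#'     separate column}
#' }
#'
#' @param model A `cluster_model`.
#' @return One-row data.frame with `user_id`, `week_index` and the
#'   features above.
#' @export
weekly_features <- function(model) {
  sess <- model$sessions[order(model$sessions$start), , drop = FALSE]
  if (!nrow(sess)) stop("weekly_features: model has no session labels")
  centers <- model$peaks$peak_coords[
    match(sess$label, model$peaks$peak_indices), , drop = FALSE]

  per_sess <- function(f) {
    vapply(sess$session_id, function(s) {
      labs <- model$readings$label[model$readings$session_id == s]
      labs <- labs[order(model$readings$t[model$readings$session_id == s])]
      f(labs)
    }, numeric(1))
  }
  n_distinct <- per_sess(function(l) length(unique(l)))
  n_trans <- per_sess(function(l) if (length(l) < 2) 0 else sum(diff(l) != 0))

  k <- nrow(sess)
  if (k >= 2) {
    a <- centers[-k, , drop = FALSE]
    b <- centers[-1, , drop = FALSE]
    hav <- haversine(a, b)
    # central angle; the chord form replaces acos near dot = 1, where
    # acos loses ~1e-8 of precision (coincident centres must give 0)
    dot <- pmin(1, pmax(-1, rowSums(a * b)))
    arc <- ifelse(dot > 0.99,
                  2 * asin(pmin(1, sqrt(rowSums((a - b)^2)) / 2)),
                  acos(dot))
    dcoord <- b - a
    sum_motion <- colSums(abs(dcoord))
    sd_motion <- if (k >= 3) apply(dcoord, 2L, stats::sd) else c(0, 0, 0)
    n_session_trans <- sum(sess$label[-1] != sess$label[-k])
  } else {
    hav <- arc <- 0
    sum_motion <- sd_motion <- c(0, 0, 0)
    n_session_trans <- 0
  }

  data.frame(
    user_id = model$user_id,
    week_index = model$week_index,
    n_clusters = length(unique(sess$label)),
    total_distance_between_clusters = sum(hav),
    avg_n_clusters_perSession = mean(n_distinct),
    avg_n_transitions_perSession = mean(n_trans),
    n_cluster_transitions = n_session_trans,
    median_X = stats::median(centers[, 1]),
    median_Y = stats::median(centers[, 2]),
    median_Z = stats::median(centers[, 3]),
    sum_X_motion = sum_motion[1],
    sum_Y_motion = sum_motion[2],
    sum_Z_motion = sum_motion[3],
    X_motion_sd = sd_motion[1],
    Y_motion_sd = sd_motion[2],
    Z_motion_sd = sd_motion[3],
    arc_sum = sum(arc),
    stringsAsFactors = FALSE
  )
}

#' Feature column names produced by [weekly_features()]
#' @return character vector (excludes the `user_id`/`week_index` keys).
#' @export
orientation_feature_names <- function() {
  c("n_clusters", "total_distance_between_clusters",
    "avg_n_clusters_perSession", "avg_n_transitions_perSession",
    "n_cluster_transitions", "median_X", "median_Y", "median_Z",
    "sum_X_motion", "sum_Y_motion", "sum_Z_motion",
    "X_motion_sd", "Y_motion_sd", "Z_motion_sd", "arc_sum")
}

#' Hourly predominant-cluster series
#'
#' For each user and clock hour (UTC) with at least one labelled reading,
#' the modal cluster label and the haversine distance from the previous
#' non-empty hour's predominant cluster centre; the first hour gets
#' distance 0. Mirrors the orientation-shift trace used to visualise
#' regime changes over weeks.
#'
#' @param models List of `cluster_model` objects (typically one per week
#'   for one or more users).
#' @return data.frame with `user_id`, `hour` (POSIXct, UTC, floored),
#'   `label` (grid index of the predominant peak), `cx`, `cy`, `cz`
#'   (its centre) and `dist_prev` (radians).
#' @export
hourly_series <- function(models) {
  models <- Filter(Negate(is.null), models)
  if (!length(models)) return(data.frame())
  rows <- do.call(rbind, lapply(models, function(m) {
    ctr <- m$peaks$peak_coords[match(m$readings$label,
                                     m$peaks$peak_indices), , drop = FALSE]
    data.frame(user_id = m$readings$user_id, t = m$readings$t,
               label = m$readings$label,
               cx = ctr[, 1], cy = ctr[, 2], cz = ctr[, 3],
               stringsAsFactors = FALSE)
  }))
  rows$hour <- as.POSIXct(floor(as.numeric(rows$t) / 3600) * 3600,
                          origin = "1970-01-01", tz = "UTC")
  out <- do.call(rbind, lapply(split(rows, rows$user_id), function(ur) {
    hrs <- sort(unique(ur$hour))
    per <- lapply(hrs, function(h) {
      hr <- ur[ur$hour == h, ]
      tab <- table(hr$label)
      lab <- as.integer(names(tab)[which.max(tab)])
      one <- hr[match(lab, hr$label), ]
      data.frame(user_id = one$user_id, hour = h, label = lab,
                 cx = one$cx, cy = one$cy, cz = one$cz,
                 stringsAsFactors = FALSE)
    })
    per <- do.call(rbind, per)
    ctr <- as.matrix(per[, c("cx", "cy", "cz")])
    nh <- nrow(per)
    per$dist_prev <- if (nh >= 2) {
      c(0, haversine(ctr[-nh, , drop = FALSE], ctr[-1, , drop = FALSE]))
    } else 0
    per
  }))
  rownames(out) <- NULL
  out
}
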