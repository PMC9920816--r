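#' Run the full orientation-clustering pipeline on raw readings
#'
#' Gravity-band filtering, unit normalisation, weekly grouping, per-week
#' vMF-KDE graph clustering, and weekly feature extraction, in one call.
#' Weeks with too few sedentary readings or no surviving density peak are
#' skipped.
#'
#' @param accel data.frame of raw readings (`user_id`, `session_id`, `t`
#'   POSIXct, `x`, `y`, `z`) as returned by [read_accel_table()], or a
#'   `cohort_sim` (its `accel` table is used, with `timestamp` renamed).
#' @param grid A [make_grid()] lattice; built at the default 1000 points
#'   when `NULL`.
#' @param band_lo,band_hi Gravity band in g.
#' @param bandwidth KDE bandwidth or `"auto"`.
#' @param n_bins Histogram bins for the noise threshold.
#' @param min_readings Minimum sedentary readings per week.
#' @return List of class `pipeline_result`: `features` (one row per
#'   clustered user-week), `models` (named list of `cluster_model`s,
#'   `"user:week"`), `grid`, and `n_weeks_skipped`.
#' @export
run_pipeline <- function(accel, grid = NULL, band_lo = 0.95, band_hi = 1.05,
                         bandwidth = "auto", n_bins = 50, min_readings = 50) {
  if (inherits(accel, "cohort_sim")) accel <- accel$accel
  if ("timestamp" %in% names(accel) && !"t" %in% names(accel)) {
    names(accel)[names(accel) == "timestamp"] <- "t"
  }
  if (is.null(grid)) grid <- make_grid(1000)
  unit <- filter_gravity_band(accel, band_lo, band_hi)
  groups <- group_by_week(unit)
  models <- list()
  skipped <- 0L
  for (key in names(groups)) {
    m <- suppressMessages(
      cluster_week(groups[[key]], grid, bandwidth = bandwidth,
                   n_bins = n_bins, min_readings = min_readings))
    if (is.null(m)) skipped <- skipped + 1L else models[[key]] <- m
  }
  features <- if (length(models)) {
    out <- do.call(rbind, lapply(models, weekly_features))
    rownames(out) <- NULL
    out
  } else NULL
  structure(list(features = features, models = models, grid = grid,
                 n_weeks_skipped = skipped),
            class = "pipeline_result")
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf(
    "pipeline_result: %d clustered user-week(s), %d skipped\n",
    length(x$models), x$n_weeks_skipped))
  invisible(x)
}
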