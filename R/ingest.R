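#' Read a raw accelerometer table
#'
#' Reads a CSV of per-reading accelerometer samples recorded during typing
#' sessions. Required columns: `user_id`, `session_id`, `timestamp`, `x`,
#' `y`, `z`. Acceleration components are in units of g (gravity-normalised).
#'
#' Rows with non-numeric coordinates or unparseable timestamps are dropped;
#' the number of dropped rows is reported via the `"n_skipped"` attribute
#' and a message. A missing required column is a fatal error.
#'
#' @param path Path to a CSV file with a header row.
#' @param dialect Timestamp dialect: `"iso8601"` (e.g.
#'   `"2023-02-01T14:05:03.200Z"`, assumed UTC) or `"epoch_ms"`
#'   (integer milliseconds since the Unix epoch).
#' @return A data.frame with columns `user_id`, `session_id`, `t`
#'   (POSIXct, UTC), `x`, `y`, `z`, ordered as read, with attribute
#'   `n_skipped`.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' writeLines(c("user_id,session_id,timestamp,x,y,z",
#'              "u1,s1,2023-02-01T10:00:00Z,0,0,1"), f)
#' read_accel_table(f)
#' @export
read_accel_table <- function(path, dialect = c("iso8601", "epoch_ms")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character")
  required <- c("user_id", "session_id", "timestamp", "x", "y", "z")
  missing <- setdiff(required, names(raw))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  x <- suppressWarnings(as.numeric(raw$x))
  y <- suppressWarnings(as.numeric(raw$y))
  z <- suppressWarnings(as.numeric(raw$z))
  t <- parse_timestamp(raw$timestamp, dialect)
  ok <- is.finite(x) & is.finite(y) & is.finite(z) & !is.na(t)
  n_skipped <- sum(!ok)
  if (n_skipped > 0) {
    message("read_accel_table: skipped ", n_skipped,
            " row(s) with non-numeric coordinates or bad timestamps")
  }
  out <- data.frame(user_id = raw$user_id[ok],
                    session_id = raw$session_id[ok],
                    t = t[ok], x = x[ok], y = y[ok], z = z[ok],
                    stringsAsFactors = FALSE)
  attr(out, "n_skipped") <- n_skipped
  out
}

parse_timestamp <- function(s, dialect) {
  if (dialect == "epoch_ms") {
    ms <- suppressWarnings(as.numeric(s))
    return(as.POSIXct(ms / 1000, origin = "1970-01-01", tz = "UTC"))
  }
  s2 <- sub("Z$", "", s)
  s2 <- sub("T", " ", s2, fixed = TRUE)
  out <- as.POSIXct(strptime(s2, "%Y-%m-%d %H:%M:%OS", tz = "UTC"))
  for (fmt in c("%Y-%m-%d %H:%M", "%Y-%m-%d")) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(s2[miss], fmt, tz = "UTC"))
  }
  out
}

#' Read a weekly PHQ-8 table
#'
#' @param path CSV with columns `user_id`, `date` (ISO `YYYY-MM-DD`),
#'   `phq8` (integer 0-24).
#' @return data.frame with `user_id`, `date` (Date), `phq8` and derived
#'   `week_index` (ISO-aligned week number, see [iso_week_index()]).
#' @export
read_phq_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("user_id", "date", "phq8")
  missing <- setdiff(required, names(d))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "))
  }
  d$date <- as.Date(d$date)
  d$phq8 <- as.integer(d$phq8)
  if (any(!is.na(d$phq8) & (d$phq8 < 0 | d$phq8 > 24))) {
    stop("phq8 values must lie in [0, 24]")
  }
  d$week_index <- iso_week_index(d$date)
  d
}

#' Keep sedentary readings and normalise them to the unit sphere
#'
#' Retains readings whose acceleration magnitude lies in the closed gravity
#' band `[band_lo, band_hi]` (default 0.95-1.05 g) -- i.e. the phone is not
#' accelerating except under gravity, so the user is sedentary -- and
#' rescales each retained reading to unit norm.
#'
#' @param readings data.frame with numeric columns `x`, `y`, `z` (and any
#'   id/timestamp columns, preserved).
#' @param band_lo,band_hi Band limits in g; `band_lo < band_hi`.
#' @return The retained rows, in input order, with added unit-vector
#'   columns `ux`, `uy`, `uz` and attribute `n_filtered` (rows removed).
#' @export
filter_gravity_band <- function(readings, band_lo = 0.95, band_hi = 1.05) {
  stopifnot(band_lo < band_hi)
  mag <- sqrt(readings$x^2 + readings$y^2 + readings$z^2)
  keep <- is.finite(mag) & mag >= band_lo & mag <= band_hi
  out <- readings[keep, , drop = FALSE]
  m <- mag[keep]
  out$ux <- out$x / m
  out$uy <- out$y / m
  out$uz <- out$z / m
  rownames(out) <- NULL
  if (!nrow(out)) message("filter_gravity_band: no readings in band")
  attr(out, "n_filtered") <- sum(!keep)
  out
}

#' ISO-aligned week index
#'
#' Continuous week number with ISO-8601 alignment: weeks start on Monday,
#' boundaries taken in UTC, consecutive calendar weeks differ by exactly 1
#' (so `week + 1` arithmetic is safe across year boundaries). Week 0
#' contains 1970-01-01.
#'
#' @param t POSIXct (UTC) or Date vector.
#' @return integer vector of week indices.
#' @export
iso_week_index <- function(t) {
  days <- if (inherits(t, "Date")) as.integer(unclass(t))
          else as.integer(floor(as.numeric(t) / 86400))
  (days + 3L) %/% 7L
}

#' Human-readable ISO week label ("2023-W05") for a week index
#' @param week_index integer as returned by [iso_week_index()].
#' @return character vector.
#' @export
iso_week_label <- function(week_index) {
  monday <- as.Date(week_index * 7L - 3L, origin = "1970-01-01")
  format(monday, "%G-W%V")
}

#' Group unit readings by user and ISO week
#'
#' Partitions readings into per-(user, week) groups. Every reading falls in
#' exactly one group; empty groups are never emitted.
#'
#' @param readings data.frame of unit readings as produced by
#'   [filter_gravity_band()], with `user_id` and `t` columns.
#' @return A named list of data.frames (names `"user:week"`), each with an
#'   added `week_index` column, ordered by user then week.
#' @export
group_by_week <- function(readings) {
  if (!nrow(readings)) return(list())
  wk <- iso_week_index(readings$t)
  readings$week_index <- wk
  key <- paste(readings$user_id, wk, sep = ":")
  groups <- split(readings, factor(key, levels = unique(key[order(readings$user_id, wk)])))
  lapply(groups, function(g) { rownames(g) <- NULL; g })
}
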