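#' Specification of a synthetic typing-accelerometer cohort
#'
#' Bundles the generator's parameters: cohort size, session/diurnal
#' structure at 10 Hz, per-user mixtures of preferred phone orientations
#' (von Mises-Fisher components on the unit sphere), the sedentary
#' fraction, the weekly PHQ-8 model and the injectable association between
#' orientation-regime volatility and PHQ change.
#'
#' Each user owns a pool of 4 well-separated mean orientations (pairwise
#' geodesic separation at least `min_separation_deg`). Each user-week
#' draws a baseline volatility `u0 ~ Uniform(0.5, 4.5)`; the week uses
#' `K = round(u)` (in 1..4) of the pool's components as its orientation
#' regimes, and sessions switch between regimes with a probability that
#' grows with `u`. Change events (a clinically relevant PHQ shift,
#' |dPHQ| >= 4, at the following week) occur independently at rate
#' `change_prob`; in weeks preceding a change event the volatility is
#' scaled by the effect multiplier, `u = min(4.5, u0 * odds_multiplier)`,
#' so such weeks show more orientation regimes and more regime
#' transitions. `odds_multiplier = 1` leaves `u = u0`: orientation
#' behaviour is then exactly independent of the change label.
#'
#' @param n_users Number of users (default 50).
#' @param weeks Weeks per user (default 11, i.e. 10 labelled transitions).
#' @param sessions_per_day Mean typing sessions per day (Poisson rate).
#' @param readings_per_session Mean accelerometer readings per session
#'   (Poisson, floored at 10), sampled at 10 Hz.
#' @param sedentary_fraction Probability a reading is sedentary (magnitude
#'   in the gravity band); the rest get magnitudes outside \[0.95, 1.05\].
#' @param kappa vMF concentration of each orientation component.
#' @param min_separation_deg Minimum pairwise separation of a user's
#'   component means, degrees.
#' @param phq_baseline_range Integer range the user's starting PHQ-8 is
#'   drawn from.
#' @param phq_noise_sd SD of the week-to-week PHQ noise (rounded to
#'   integers; scores clamped to \[0, 24\]).
#' @param change_prob Probability that a week is followed by a clinically
#'   relevant change (|dPHQ| >= 4).
#' @param odds_multiplier Volatility multiplier applied to change-event
#'   weeks (1 = no association); see [inject_effect()].
#' @param dropout_prob Per-user-week probability that the accelerometer
#'   stream (and, independently, the PHQ report) is missing, emulating
#'   voluntary app usage.
#' @param regime_count Optional fixed regime count K (length 1 or
#'   `weeks`); overrides the volatility draw, setting `u = K`.
#' @param start_monday Date of the first week's Monday.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_users = 50, weeks = 11, sessions_per_day = 6,
                        readings_per_session = 50, sedentary_fraction = 0.7,
                        kappa = 100, min_separation_deg = 60,
                        phq_baseline_range = c(5L, 15L), phq_noise_sd = 1,
                        change_prob = 0.15, odds_multiplier = 1,
                        dropout_prob = 0.05, regime_count = NULL,
                        start_monday = as.Date("2023-01-02")) {
  stopifnot(n_users >= 1, weeks >= 1, sessions_per_day > 0,
            readings_per_session > 0,
            sedentary_fraction >= 0, sedentary_fraction <= 1,
            kappa > 0, change_prob > 0, change_prob < 1,
            odds_multiplier > 0, dropout_prob >= 0, dropout_prob < 1)
  if (!is.null(regime_count)) {
    stopifnot(all(regime_count %in% 1:4),
              length(regime_count) %in% c(1L, weeks))
  }
  structure(as.list(environment()), class = "cohort_spec")
}

#' Inject (or remove) the volatility-change association
#'
#' Returns the spec with `odds_multiplier` set: weeks that precede a
#' clinically relevant PHQ change get their orientation-regime volatility
#' (hence regime count and transition rate) scaled by the multiplier.
#' `1` makes orientation features exactly independent of the change
#' label; larger values raise the odds that a high-regime week is
#' followed by a change.
#'
#' @param spec A [cohort_spec()].
#' @param odds_multiplier Positive volatility multiplier.
#' @return Modified `cohort_spec`.
#' @export
inject_effect <- function(spec, odds_multiplier) {
  stopifnot(inherits(spec, "cohort_spec"), odds_multiplier > 0)
  spec$odds_multiplier <- odds_multiplier
  spec
}

#' Draw from a von Mises-Fisher distribution on the 2-sphere
#'
#' Inverse-CDF sampler in the tangent-normal decomposition: the cosine `w`
#' of the angle to `mu` has density proportional to `exp(kappa * w)` on
#' \[-1, 1\], and the tangential direction is uniform.
#'
#' @param n Number of draws.
#' @param mu Unit mean direction (length 3).
#' @param kappa Concentration (> 0).
#' @return `n x 3` matrix of unit vectors.
#' @export
rvmf <- function(n, mu, kappa) {
  stopifnot(kappa > 0, length(mu) == 3)
  mu <- mu / sqrt(sum(mu^2))
  u <- stats::runif(n)
  w <- 1 + log(u + (1 - u) * exp(-2 * kappa)) / kappa
  theta <- stats::runif(n, 0, 2 * pi)
  s <- sqrt(pmax(0, 1 - w^2))
  a <- if (abs(mu[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  b1 <- a - sum(a * mu) * mu
  b1 <- b1 / sqrt(sum(b1^2))
  b2 <- c(mu[2] * b1[3] - mu[3] * b1[2],
          mu[3] * b1[1] - mu[1] * b1[3],
          mu[1] * b1[2] - mu[2] * b1[1])
  w %o% mu + (s * cos(theta)) %o% b1 + (s * sin(theta)) %o% b2
}

# pool of n_comp unit vectors with pairwise separation >= sep_rad
draw_separated_means <- function(n_comp, sep_rad, max_tries = 10000) {
  means <- matrix(NA_real_, n_comp, 3)
  for (k in seq_len(n_comp)) {
    placed <- FALSE
    for (try in seq_len(max_tries)) {
      v <- stats::rnorm(3)
      v <- v / sqrt(sum(v^2))
      if (k == 1 ||
          all(acos(pmin(1, means[seq_len(k - 1), , drop = FALSE] %*% v)) >=
              sep_rad)) {
        means[k, ] <- v
        placed <- TRUE
        break
      }
    }
    if (!placed) stop("could not place separated component means")
  }
  means
}

#' Simulate a synthetic typing-accelerometer cohort with ground truth
#'
#' Generates per-reading accelerometer streams (10 Hz within sessions,
#' sessions placed by a diurnally weighted Poisson process), weekly PHQ-8
#' trajectories, and full ground truth (per-reading component and
#' sedentary flag, per-week regime count, volatility, true session
#' transitions and change label). Deterministic for a fixed seed.
#'
#' @param spec A [cohort_spec()].
#' @param seed Integer RNG seed.
#' @return List of class `cohort_sim`:
#' \describe{
#'   \item{accel}{data.frame `user_id, session_id, timestamp` (POSIXct
#'     UTC), `x, y, z` (g)}
#'   \item{phq}{data.frame `user_id, date, phq8`}
#'   \item{truth}{list with `readings` (per-reading `component`,
#'     `sedentary`), and `weeks` (per-user-week `K_true`, `u_vol`,
#'     `n_session_transitions_true`, `phq8`, `change_next`,
#'     `accel_observed`, `phq_observed`)}
#' }
#' @export
simulate_cohort <- function(spec = cohort_spec(), seed = 1) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(as.integer(seed))
  hour_w <- c(rep(0.15, 7), rep(1, 12), rep(0.7, 4), 0.3)  # diurnal template
  sep_rad <- spec$min_separation_deg * pi / 180
  m <- spec$odds_multiplier

  # per-session accumulators, bound into data.frames once at the end
  A <- list(user = list(), sid = list(), t = list(),
            x = list(), y = list(), z = list(),
            comp = list(), sed = list(), wk = list())
  week_rows <- list(); phq_rows <- list()

  for (ui in seq_len(spec$n_users)) {
    user <- sprintf("u%03d", ui)
    pool <- draw_separated_means(4, sep_rad)
    phq <- integer(spec$weeks)
    phq[1] <- sample(seq(spec$phq_baseline_range[1],
                         spec$phq_baseline_range[2]), 1)
    u_vol <- if (is.null(spec$regime_count)) {
      stats::runif(spec$weeks, 0.5, 4.5)
    } else rep(as.numeric(spec$regime_count), length.out = spec$weeks)
    change_ind <- c(stats::runif(max(spec$weeks - 1, 0)) < spec$change_prob,
                    NA)
    u0 <- u_vol
    if (is.null(spec$regime_count)) {
      boost <- !is.na(change_ind) & change_ind
      u_vol[boost] <- pmin(4.5, u_vol[boost] * m)
    }
    sess_counter <- 0L
    user_week_rows <- vector("list", spec$weeks)

    for (w in seq_len(spec$weeks)) {
      K <- min(4L, max(1L, as.integer(floor(u_vol[w] + 0.5))))
      wts <- stats::runif(K, 0.5, 1)
      wts <- wts / sum(wts)
      # regime count saturates at the pool size, so the effect multiplier
      # also scales the regime-switching rate directly
      scale_w <- if (is.null(spec$regime_count) &&
                       !is.na(change_ind[w]) && change_ind[w]) m else 1
      switch_p <- min(0.8, (0.05 + 0.12 * u0[w]) * scale_w)
      monday <- spec$start_monday + (w - 1) * 7L
      week_index <- iso_week_index(monday)

      n_sess_day <- stats::rpois(7, spec$sessions_per_day)
      if (sum(n_sess_day) == 0) n_sess_day[1] <- 1L
      sess_comp_prev <- NA_integer_
      wk_sess_comp <- integer(0)
      for (day in 1:7) {
        ns <- n_sess_day[day]
        if (ns == 0) next
        hrs <- sample(0:23, ns, replace = TRUE, prob = hour_w)
        # offset capped so a session's readings never cross the UTC day line
        t0 <- sort(as.numeric(as.POSIXct(monday + (day - 1), tz = "UTC")) +
                     hrs * 3600 + stats::runif(ns, 0, 3400))
        for (si in seq_len(ns)) {
          sess_counter <- sess_counter + 1L
          sid <- sprintf("%s-s%05d", user, sess_counter)
          comp <- if (is.na(sess_comp_prev) || stats::runif(1) < switch_p) {
            sample(seq_len(K), 1, prob = wts)
          } else sess_comp_prev
          sess_comp_prev <- comp
          wk_sess_comp <- c(wk_sess_comp, comp)
          nr <- max(10L, stats::rpois(1, spec$readings_per_session))
          sed <- stats::runif(nr) < spec$sedentary_fraction
          dirs <- matrix(NA_real_, nr, 3)
          if (any(sed)) {
            dirs[sed, ] <- rvmf(sum(sed), pool[comp, ], spec$kappa)
          }
          if (any(!sed)) {
            v <- matrix(stats::rnorm(3 * sum(!sed)), ncol = 3)
            dirs[!sed, ] <- v / sqrt(rowSums(v^2))
          }
          mag <- numeric(nr)
          mag[sed] <- stats::runif(sum(sed), 0.96, 1.04)
          lowhigh <- stats::runif(sum(!sed)) < 0.5
          mag[!sed] <- ifelse(lowhigh, stats::runif(sum(!sed), 0.50, 0.90),
                              stats::runif(sum(!sed), 1.15, 2.50))
          k <- length(A$user) + 1L
          A$user[[k]] <- rep(user, nr)
          A$sid[[k]] <- rep(sid, nr)
          A$t[[k]] <- t0[si] + (seq_len(nr) - 1) * 0.1
          A$x[[k]] <- dirs[, 1] * mag
          A$y[[k]] <- dirs[, 2] * mag
          A$z[[k]] <- dirs[, 3] * mag
          A$comp[[k]] <- rep(comp, nr)
          A$sed[[k]] <- sed
          A$wk[[k]] <- rep(week_index, nr)
        }
      }

      if (w < spec$weeks) {
        if (change_ind[w]) {
          delta <- sample(4:8, 1) * (if (phq[w] >= 12) -1L else 1L)
        } else {
          delta <- as.integer(round(stats::rnorm(1, 0, spec$phq_noise_sd)))
        }
        phq[w + 1] <- min(24L, max(0L, phq[w] + delta))
      }

      user_week_rows[[w]] <- data.frame(
        user_id = user, week_index = week_index,
        K_true = K, u_vol = u_vol[w],
        n_session_transitions_true =
          if (length(wk_sess_comp) >= 2) sum(diff(wk_sess_comp) != 0) else 0L,
        phq8 = NA_integer_, change_next = NA,
        accel_observed = stats::runif(1) >= spec$dropout_prob,
        phq_observed = stats::runif(1) >= spec$dropout_prob,
        stringsAsFactors = FALSE)
    }

    for (w in seq_len(spec$weeks)) {
      user_week_rows[[w]]$phq8 <- phq[w]
      user_week_rows[[w]]$change_next <- if (w < spec$weeks) {
        abs(phq[w + 1] - phq[w]) >= 4
      } else NA
      phq_rows[[length(phq_rows) + 1L]] <- data.frame(
        user_id = user, date = spec$start_monday + (w - 1) * 7L + 6L,
        phq8 = phq[w], stringsAsFactors = FALSE)
    }
    week_rows <- c(week_rows, user_week_rows)
  }

  accel <- data.frame(
    user_id = unlist(A$user), session_id = unlist(A$sid),
    timestamp = as.POSIXct(unlist(A$t), origin = "1970-01-01", tz = "UTC"),
    x = unlist(A$x), y = unlist(A$y), z = unlist(A$z),
    stringsAsFactors = FALSE)
  truth_rd <- data.frame(
    user_id = accel$user_id, session_id = accel$session_id,
    week_index = unlist(A$wk), component = unlist(A$comp),
    sedentary = unlist(A$sed), stringsAsFactors = FALSE)
  weeks_df <- do.call(rbind, week_rows)
  phq_df <- do.call(rbind, phq_rows)
  rownames(weeks_df) <- rownames(phq_df) <- NULL

  # dropout: unobserved accel weeks / PHQ reports are simply not emitted
  obs_accel <- weeks_df$accel_observed[
    match(paste(truth_rd$user_id, truth_rd$week_index),
          paste(weeks_df$user_id, weeks_df$week_index))]
  accel <- accel[obs_accel, , drop = FALSE]
  truth_rd <- truth_rd[obs_accel, , drop = FALSE]
  obs_phq <- weeks_df$phq_observed[
    match(paste(phq_df$user_id, iso_week_index(phq_df$date)),
          paste(weeks_df$user_id, weeks_df$week_index))]
  phq_df <- phq_df[obs_phq, , drop = FALSE]
  rownames(accel) <- rownames(truth_rd) <- rownames(phq_df) <- NULL

  structure(list(accel = accel, phq = phq_df,
                 truth = list(readings = truth_rd, weeks = weeks_df),
                 spec = spec, seed = as.integer(seed)),
            class = "cohort_sim")
}

#' @export
print.cohort_sim <- function(x, ...) {
  cat(sprintf(
    "cohort_sim: %d users x %d weeks | %d accel readings, %d PHQ reports (seed %d)\n",
    x$spec$n_users, x$spec$weeks, nrow(x$accel), nrow(x$phq), x$seed))
  invisible(x)
}

#' Write a simulated cohort to the CSV dialects the ingest module reads
#'
#' `accel.csv` uses the `epoch_ms` timestamp dialect (exact integer
#' milliseconds, byte-stable across runs); `phq.csv` uses ISO dates.
#'
#' @param sim A `cohort_sim`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the two file paths.
#' @export
write_cohort <- function(sim, dir) {
  stopifnot(inherits(sim, "cohort_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  acc <- sim$accel
  acc$timestamp <- sprintf("%.0f", round(as.numeric(acc$timestamp) * 1000))
  f_accel <- file.path(dir, "accel.csv")
  f_phq <- file.path(dir, "phq.csv")
  utils::write.csv(acc, f_accel, row.names = FALSE, quote = FALSE)
  utils::write.csv(sim$phq, f_phq, row.names = FALSE, quote = FALSE)
  invisible(c(accel = f_accel, phq = f_phq))
}
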