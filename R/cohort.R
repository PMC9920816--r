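#' Assemble the user-week modelling cohort
#'
#' Joins weekly orientation features with weekly PHQ-8 scores (and optional
#' pass-through covariates) on `(user_id, week_index)`, defines the binary
#' outcome `label = 1` iff `|phq8(week + 1) - phq8(week)| >= 4` (a
#' clinically relevant change the following week), and handles missingness:
#'
#' * `mode = "filter"`: users with any missing feature-week or PHQ-week
#'   inside their observed span are dropped entirely.
#' * `mode = "impute"`: missing numeric features are filled with the
#'   per-user median (global median fallback); missing PHQ scores are
#'   last-observation-carried-forward. The label is always computed from
#'   observed PHQ only -- never from an imputed next-week value.
#'
#' @param features data.frame from [run_pipeline()] (keys `user_id`,
#'   `week_index` plus feature columns).
#' @param phq data.frame with `user_id`, `phq8` and either `week_index`
#'   or `date` (the ISO week is then derived); multiple reports in a week
#'   collapse to the last.
#' @param covariates Optional data.frame keyed by `user_id` (and
#'   optionally `week_index`) carried through untouched.
#' @param mode `"impute"` or `"filter"`.
#' @return data.frame of cohort rows: keys, feature columns, covariates,
#'   `phq8`, `label` (NA where the next week's PHQ is unobserved).
#' @export
build_cohort <- function(features, phq, covariates = NULL,
                         mode = c("impute", "filter")) {
  mode <- match.arg(mode)
  if (!"week_index" %in% names(phq) && "date" %in% names(phq)) {
    phq$week_index <- iso_week_index(as.Date(phq$date))
  }
  stopifnot(all(c("user_id", "week_index") %in% names(features)),
            all(c("user_id", "week_index", "phq8") %in% names(phq)))
  phq <- phq[order(phq$user_id, phq$week_index), ]
  phq <- phq[!duplicated(phq[c("user_id", "week_index")], fromLast = TRUE),
             c("user_id", "week_index", "phq8")]

  users <- union(features$user_id, phq$user_id)
  feat_cols <- setdiff(names(features), c("user_id", "week_index"))
  rows <- list()
  for (u in users) {
    fu <- features[features$user_id == u, , drop = FALSE]
    pu <- phq[phq$user_id == u, , drop = FALSE]
    wks <- sort(union(fu$week_index, pu$week_index))
    if (!length(wks)) next
    span <- seq(min(wks), max(wks))
    have_feat <- span %in% fu$week_index
    have_phq <- span %in% pu$week_index
    if (mode == "filter" && (!all(have_feat) || !all(have_phq))) next

    fmat <- fu[match(span, fu$week_index), feat_cols, drop = FALSE]
    if (mode == "impute") {
      for (cc in feat_cols) {
        v <- fmat[[cc]]
        if (anyNA(v) && is.numeric(v)) {
          fill <- stats::median(v, na.rm = TRUE)
          if (is.na(fill)) fill <- stats::median(features[[cc]], na.rm = TRUE)
          v[is.na(v)] <- fill
          fmat[[cc]] <- v
        }
      }
    }
    phq_obs <- pu$phq8[match(span, pu$week_index)]
    phq_used <- phq_obs
    if (mode == "impute" && anyNA(phq_used)) {
      for (i in seq_along(phq_used)) {
        if (is.na(phq_used[i]) && i > 1) phq_used[i] <- phq_used[i - 1]
      }
    }
    # label from observed PHQ only
    nxt <- c(phq_obs[-1], NA)
    label <- ifelse(is.na(phq_obs) | is.na(nxt), NA_integer_,
                    as.integer(abs(nxt - phq_obs) >= 4))
    rows[[u]] <- data.frame(user_id = u, week_index = span, fmat,
                            phq8 = phq_used, label = label,
                            stringsAsFactors = FALSE, row.names = NULL)
  }
  if (!length(rows)) stop("no overlapping user-weeks between features and PHQ")
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (!is.null(covariates)) {
    by <- intersect(c("user_id", "week_index"), names(covariates))
    out <- merge(out, covariates, by = by, all.x = TRUE, sort = FALSE)
  }
  out
}

#' Balance classes by synthetic minority oversampling (SMOTE)
#'
#' Oversamples the minority class to parity by interpolating each new row
#' between a random minority row and one of its `k` nearest minority
#' neighbours (Euclidean distance in feature space):
#' `x_new = x + U(0,1) * (x_nn - x)`. Apply to training folds only.
#'
#' @param rows data.frame of training rows.
#' @param label_col Name of the binary 0/1 label column.
#' @param feature_cols Numeric feature columns to interpolate (defaults to
#'   all numeric columns except the label and `week_index`).
#' @param k Number of minority neighbours (default 5, capped at minority
#'   size - 1).
#' @param seed Integer seed.
#' @return data.frame with equal class counts; synthetic rows carry
#'   `user_id = "synthetic"` when a `user_id` column exists.
#' @export
smote_balance <- function(rows, label_col = "label", feature_cols = NULL,
                          k = 5, seed = 1) {
  y <- rows[[label_col]]
  stopifnot(!anyNA(y), all(y %in% 0:1))
  tab <- table(factor(y, levels = 0:1))
  if (any(tab == 0)) stop("both classes must be present before SMOTE")
  if (min(tab) == max(tab)) return(rows)
  minority <- as.integer(names(tab)[which.min(tab)])
  if (min(tab) < 2) {
    stop("minority class has fewer than 2 rows; reduce the number of folds")
  }
  if (is.null(feature_cols)) {
    feature_cols <- names(rows)[vapply(rows, is.numeric, logical(1))]
    feature_cols <- setdiff(feature_cols, c(label_col, "week_index"))
  }
  Xm <- as.matrix(rows[y == minority, feature_cols, drop = FALSE])
  n_new <- max(tab) - min(tab)
  kk <- min(k, nrow(Xm) - 1)
  d2 <- as.matrix(stats::dist(Xm))^2
  diag(d2) <- Inf
  nn <- apply(d2, 1L, function(r) order(r)[seq_len(kk)])
  nn <- if (kk == 1) matrix(nn, ncol = 1) else t(nn)

  set.seed(as.integer(seed))
  base_i <- sample(nrow(Xm), n_new, replace = TRUE)
  nn_i <- nn[cbind(base_i, sample(kk, n_new, replace = TRUE))]
  gap <- stats::runif(n_new)
  Xnew <- Xm[base_i, , drop = FALSE] +
    gap * (Xm[nn_i, , drop = FALSE] - Xm[base_i, , drop = FALSE])

  synth <- rows[rep(which(y == minority)[1], n_new), , drop = FALSE]
  synth[feature_cols] <- as.data.frame(Xnew)
  synth[[label_col]] <- minority
  if ("user_id" %in% names(synth)) synth$user_id <- "synthetic"
  out <- rbind(rows, synth)
  rownames(out) <- NULL
  out
}
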