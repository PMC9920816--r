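#' Train and evaluate a change-prediction classifier
#'
#' Grouped K-fold cross-validation (all of a user's weeks stay in one
#' fold, so repeated within-user rows never leak between training and
#' evaluation), SMOTE balancing of each training fold only, and a random
#' forest (`ranger`) or gradient-boosted trees (`xgboost`) classifier
#' predicting a clinically relevant PHQ change the following week.
#'
#' @param rows Cohort rows from [build_cohort()]; rows with `NA` labels are
#'   dropped.
#' @param model `"rf"` or `"gbm"`.
#' @param feature_cols Feature columns (default: the orientation features
#'   present in `rows`).
#' @param k_folds Number of user-grouped folds (default 5).
#' @param seed Integer seed controlling fold assignment, SMOTE and model
#'   fits; identical seeds and inputs give identical reports.
#' @param smote Apply SMOTE to training folds (default TRUE).
#' @return Object of class `eval_report`: `folds` (per-fold `acc`, `auc`,
#'   `n_test`), `mean_acc`, `sd_acc`, `mean_auc`, `sd_auc` (over folds with
#'   defined AUC; single-class test folds are reported with `auc = NA` and
#'   skipped in the aggregate), and a `config` echo.
#' @export
train_eval <- function(rows, model = c("rf", "gbm"), feature_cols = NULL,
                       k_folds = 5, seed = 1, smote = TRUE) {
  model <- match.arg(model)
  rows <- rows[!is.na(rows$label), , drop = FALSE]
  if (is.null(feature_cols)) {
    feature_cols <- intersect(orientation_feature_names(), names(rows))
  }
  stopifnot(length(feature_cols) >= 1, nrow(rows) >= k_folds)
  users <- unique(rows$user_id)
  if (length(users) < 2 * k_folds) {
    stop("need at least 2 users per fold; reduce k_folds")
  }
  set.seed(as.integer(seed))
  fold_of <- stats::setNames(
    rep(seq_len(k_folds), length.out = length(users))[sample(length(users))],
    users)

  folds <- data.frame(fold = seq_len(k_folds), acc = NA_real_,
                      auc = NA_real_, n_test = NA_integer_)
  for (f in seq_len(k_folds)) {
    test <- rows[fold_of[rows$user_id] == f, , drop = FALSE]
    train <- rows[fold_of[rows$user_id] != f, , drop = FALSE]
    if (!nrow(test) || length(unique(train$label)) < 2) next
    if (smote) {
      train <- smote_balance(train, "label", feature_cols,
                             seed = seed + f)
    }
    p <- fit_predict(train, test, model, feature_cols, seed + f)
    folds$acc[f] <- mean((p > 0.5) == (test$label == 1))
    folds$n_test[f] <- nrow(test)
    if (length(unique(test$label)) == 2) {
      folds$auc[f] <- as.numeric(pROC::auc(
        pROC::roc(test$label, p, quiet = TRUE, direction = "<",
                  levels = c(0, 1))))
    }
  }
  ok_auc <- !is.na(folds$auc)
  structure(list(
    folds = folds,
    mean_acc = mean(folds$acc, na.rm = TRUE),
    sd_acc = stats::sd(folds$acc[!is.na(folds$acc)]),
    mean_auc = if (any(ok_auc)) mean(folds$auc[ok_auc]) else NA_real_,
    sd_auc = if (sum(ok_auc) > 1) stats::sd(folds$auc[ok_auc]) else NA_real_,
    config = list(model = model, k_folds = k_folds, seed = seed,
                  smote = smote, feature_cols = feature_cols)),
    class = "eval_report")
}

fit_predict <- function(train, test, model, feature_cols, seed) {
  xtr <- as.matrix(train[feature_cols])
  xte <- as.matrix(test[feature_cols])
  ytr <- factor(train$label, levels = 0:1)
  if (model == "rf") {
    fit <- ranger::ranger(x = xtr, y = ytr, probability = TRUE,
                          num.trees = 500, seed = seed, num.threads = 1)
    stats::predict(fit, data = xte, num.threads = 1)$predictions[, "1"]
  } else {
    dtr <- xgboost::xgb.DMatrix(xtr, label = train$label, nthread = 1)
    fit <- xgboost::xgb.train(
      params = list(objective = "binary:logistic", max_depth = 3,
                    eta = 0.1, nthread = 1, seed = seed),
      data = dtr, nrounds = 200, verbose = 0)
    stats::predict(fit, xgboost::xgb.DMatrix(xte, nthread = 1))
  }
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf(
    "eval_report (%s, %d-fold grouped CV): accuracy %.3f +/- %.3f | AUC %.3f +/- %.3f\n",
    x$config$model, x$config$k_folds, x$mean_acc,
    ifelse(is.na(x$sd_acc), 0, x$sd_acc), x$mean_auc,
    ifelse(is.na(x$sd_auc), 0, x$sd_auc)))
  invisible(x)
}

#' Rank features by forest impurity importance
#'
#' Fits a random forest on all labelled rows and returns features ordered
#' by decreasing impurity-decrease (Gini information gain) importance;
#' ties break alphabetically.
#'
#' @param rows Cohort rows with a 0/1 `label`.
#' @param feature_cols Features to rank (default: orientation features
#'   present).
#' @param seed Integer seed.
#' @return data.frame `feature`, `score`, in rank order, covering every
#'   input feature exactly once.
#' @export
rank_features <- function(rows, feature_cols = NULL, seed = 1) {
  rows <- rows[!is.na(rows$label), , drop = FALSE]
  if (is.null(feature_cols)) {
    feature_cols <- intersect(orientation_feature_names(), names(rows))
  }
  stopifnot(length(feature_cols) >= 2)
  fit <- ranger::ranger(x = as.matrix(rows[feature_cols]),
                        y = factor(rows$label, levels = 0:1),
                        importance = "impurity", num.trees = 500,
                        seed = seed, num.threads = 1)
  imp <- fit$variable.importance
  out <- data.frame(feature = names(imp), score = as.numeric(imp),
                    stringsAsFactors = FALSE)
  out <- out[order(-out$score, out$feature), ]
  rownames(out) <- NULL
  out
}

#' Odds ratio of change for a dichotomised feature
#'
#' Splits the feature at its median (`> median` = exposed), forms the 2x2
#' table against the change label, and returns the cross-product odds
#' ratio with a Woolf (log-normal) 95% confidence interval. When any cell
#' is zero the Haldane-Anscombe 0.5 correction is applied to all cells.
#'
#' @param rows Cohort rows with a 0/1 `label`.
#' @param feature Name of a numeric feature column.
#' @param split `"median"` (default) or `"tertile"` (top tertile exposed).
#' @return List of class `odds_ratio`: `or`, `ci_lo`, `ci_hi`, `table`.
#' @export
odds_ratio <- function(rows, feature, split = c("median", "tertile")) {
  split <- match.arg(split)
  rows <- rows[!is.na(rows$label), , drop = FALSE]
  x <- rows[[feature]]
  stopifnot(is.numeric(x), length(unique(rows$label)) == 2)
  cut_at <- if (split == "median") stats::median(x)
            else stats::quantile(x, 2 / 3, names = FALSE)
  exposed <- x > cut_at
  if (all(exposed) || !any(exposed)) {
    stop("degenerate dichotomisation: all rows on one side of the split")
  }
  y <- rows$label == 1
  a <- sum(exposed & y); b <- sum(exposed & !y)
  c_ <- sum(!exposed & y); d <- sum(!exposed & !y)
  cells <- c(a = a, b = b, c = c_, d = d)
  if (any(cells == 0)) cells <- cells + 0.5
  or <- (cells["a"] * cells["d"]) / (cells["b"] * cells["c"])
  se <- sqrt(sum(1 / cells))
  structure(list(feature = feature, or = unname(or),
                 ci_lo = unname(or * exp(-1.96 * se)),
                 ci_hi = unname(or * exp(1.96 * se)),
                 table = matrix(c(a, b, c_, d), 2, byrow = TRUE,
                                dimnames = list(c("exposed", "unexposed"),
                                                c("change", "no change")))),
            class = "odds_ratio")
}

#' @export
print.odds_ratio <- function(x, ...) {
  cat(sprintf("odds_ratio[%s]: OR = %.3f (95%% CI %.3f-%.3f)\n",
              x$feature, x$or, x$ci_lo, x$ci_hi))
  invisible(x)
}
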