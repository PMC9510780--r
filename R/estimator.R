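#' Estimator settings
#'
#' Hyperparameters of the lagged-feature gradient-boosting regressor:
#' 100 boosting steps of depth-3 regression trees over the features of
#' the three most recent 10 s windows, squared-error loss, learning
#' rate 0.1 (standard boosting default; the loss and depth cap define
#' plain stagewise residual fitting).
#'
#' @param steps Number of boosting steps (trees).
#' @param max_depth Maximum tree depth.
#' @param learning_rate Shrinkage applied to every tree.
#' @param lags Number of consecutive windows stacked into one input.
#' @param min_train_rows Minimum training rows required to fit.
#' @param levels Discrete concentration levels for nearest-neighbor
#'   quantization of isoflurane predictions.
#' @return A list of class `estimator_config`.
#' @export
estimator_config <- function(steps = 100, max_depth = 3,
                             learning_rate = 0.1, lags = 3,
                             min_train_rows = 50,
                             levels = c(1.0, 1.5, 2.3)) {
  cfg <- as.list(environment())
  class(cfg) <- "estimator_config"
  cfg
}

#' Assemble the lagged-feature dataset
#'
#' Builds one row per window `n >= lags` within each contiguous run of
#' windows (a per-concentration block): the input stacks the feature
#' vectors of windows `n - lags + 1, ..., n` (named with suffixes
#' `_t-2`, `_t-1`, `_t-0`, oldest first) and the target is the value at
#' window `n`. Rows never span a block boundary or the discarded
#' transition interval, so no input mixes concentrations across a
#' switch.
#'
#' @param feature_table A cohort feature table (with `era` column when
#'   `target = "era"`).
#' @param target `"isoflurane"` (administered concentration, percent),
#'   `"era"` (evoked-response attenuation) or `"time"` (elapsed
#'   seconds, for the control analysis).
#' @param lags Number of stacked windows (default 3).
#' @return A list of class `lagged_dataset`: `X` (numeric matrix, rows
#'   x lagged features), `y`, `animal_id`, `t_s` (time of the target
#'   window) and `feature_names`.
#' @export
assemble_dataset <- function(feature_table,
                             target = c("isoflurane", "era", "time"),
                             lags = 3) {
  target <- match.arg(target)
  feats <- feature_columns(feature_table)
  ft <- feature_table[order(feature_table$animal_id,
                            feature_table$t_start_s), ]
  if (target == "era" && is.null(ft$era))
    stop("feature table has no `era` column; run add_era_target() first")
  grp <- interaction(ft$animal_id, ft$segment, drop = TRUE)
  Xs <- list(); ys <- numeric(0); ids <- character(0); ts <- numeric(0)
  for (g in levels(grp)) {
    sub <- ft[grp == g, ]
    N <- nrow(sub)
    if (N < lags) next
    M <- as.matrix(sub[, feats])
    for (n in lags:N) {
      row <- as.numeric(t(M[(n - lags + 1):n, , drop = FALSE]))
      Xs[[length(Xs) + 1L]] <- row
      ys <- c(ys, switch(target,
                         isoflurane = sub$conc_pct[n],
                         era = sub$era[n],
                         time = sub$t_start_s[n]))
      ids <- c(ids, sub$animal_id[n])
      ts <- c(ts, sub$t_start_s[n])
    }
  }
  if (length(Xs) == 0) {
    warning("no run of ", lags, " consecutive windows: empty dataset")
    X <- matrix(numeric(0), 0, length(feats) * lags)
  } else {
    X <- do.call(rbind, Xs)
  }
  lag_names <- unlist(lapply(rev(seq_len(lags)) - 1L, function(l) {
    paste0(feats, "_t-", l)
  }))
  colnames(X) <- lag_names
  out <- list(X = X, y = ys, animal_id = ids, t_s = ts,
              feature_names = lag_names, target = target)
  class(out) <- "lagged_dataset"
  out
}

#' Leave-one-animal-out folds
#'
#' @param dataset A `lagged_dataset` with at least 2 animals.
#' @return A list of folds, each `list(animal, train, eval)` with
#'   disjoint row-index vectors; every animal is the evaluation set
#'   exactly once and the union of evaluation sets is the full dataset.
#' @export
loo_folds <- function(dataset) {
  stopifnot(inherits(dataset, "lagged_dataset"))
  animals <- unique(dataset$animal_id)
  if (length(animals) < 2) stop("leave-one-out needs >= 2 animals")
  lapply(animals, function(a) {
    ev <- which(dataset$animal_id == a)
    list(animal = a, train = setdiff(seq_along(dataset$y), ev), eval = ev)
  })
}

#' Fit the gradient-boosted tree regressor
#'
#' Stagewise least-squares boosting of depth-capped regression trees
#' (exact greedy splits, no regularization, no subsampling), i.e. each
#' successive tree fits the residual of the running ensemble and enters
#' with weight `learning_rate`. Backed by xgboost with `lambda = 0`,
#' `gamma = 0`, single-threaded, so fits are deterministic.
#'
#' @param X Numeric input matrix with named columns (NA = missing).
#' @param y Numeric target.
#' @param config An [estimator_config()].
#' @return A list of class `boosted_model` with the fitted booster and
#'   training meta.
#' @export
fit_boosted_regressor <- function(X, y, config = estimator_config()) {
  if (nrow(X) < config$min_train_rows)
    stop("training set has fewer than ", config$min_train_rows, " rows")
  base <- mean(y)
  # fit on an unnamed matrix (features f0..f(p-1) internally); the
  # column-name mapping is kept in the returned model
  dtrain <- xgboost::xgb.DMatrix(unname(X), label = y, nthread = 1)
  params <- list(objective = "reg:squarederror",
                 eta = config$learning_rate,
                 max_depth = config$max_depth,
                 lambda = 0, alpha = 0, gamma = 0,
                 min_child_weight = 1,
                 subsample = 1, colsample_bytree = 1,
                 base_score = base, nthread = 1)
  booster <- xgboost::xgb.train(params = params, data = dtrain,
                                nrounds = config$steps, verbose = 0)
  out <- list(booster = booster, feature_names = colnames(X),
              config = config, base_score = base)
  class(out) <- "boosted_model"
  out
}

#' @export
predict.boosted_model <- function(object, newdata, nsteps = NULL, ...) {
  if (!is.null(colnames(newdata)))
    newdata <- newdata[, object$feature_names, drop = FALSE]
  dm <- xgboost::xgb.DMatrix(unname(newdata), nthread = 1)
  if (is.null(nsteps)) {
    stats::predict(object$booster, dm)
  } else {
    stats::predict(object$booster, dm, iterationrange = c(1, nsteps + 1))
  }
}

#' Regression metrics on a held-out set
#'
#' MAE and the coefficient of determination computed against the
#' evaluation-set mean; fold R^2 can therefore be negative. A
#' zero-variance evaluation target makes R^2 undefined (`NA`).
#'
#' @param y True targets.
#' @param y_hat Predictions.
#' @return A list with `mae` and `r2`.
#' @export
evaluate_regression <- function(y, y_hat) {
  stopifnot(length(y) == length(y_hat), length(y) > 0)
  sst <- sum((y - mean(y))^2)
  list(mae = mean(abs(y_hat - y)),
       r2 = if (sst > 0) 1 - sum((y_hat - y)^2) / sst else NA_real_)
}

#' Nearest-level quantization of predictions
#'
#' Maps each continuous prediction to the nearest discrete
#' concentration level; exact midpoint ties go to the lower level
#' (conservative toward lighter anesthesia).
#'
#' @param y_hat Numeric predictions.
#' @param levels Sorted discrete levels.
#' @return Numeric vector of levels.
#' @export
quantize_predictions <- function(y_hat, levels = c(1.0, 1.5, 2.3)) {
  levels <- sort(levels)
  mids <- (levels[-1] + levels[-length(levels)]) / 2
  idx <- 1L + rowSums(outer(y_hat, mids, ">"))
  levels[idx]
}

#' One-vs-all macro classification metrics
#'
#' Per-class one-vs-all accuracy, precision, recall and F1, averaged
#' unweighted over classes (macro). Classes absent from both truth and
#' prediction are excluded with a warning. Empty-denominator precision
#' or recall for a present class counts as 0.
#'
#' @param truth,pred Vectors of class labels (levels).
#' @param levels The full level set.
#' @return A list with `accuracy`, `precision`, `recall`, `f1`
#'   (macro averages) and `per_class` (data.frame).
#' @export
classification_metrics <- function(truth, pred, levels = c(1.0, 1.5, 2.3)) {
  stopifnot(length(truth) == length(pred))
  present <- levels[levels %in% c(truth, pred)]
  if (length(present) < length(levels))
    warning("class(es) absent from both truth and prediction excluded: ",
            paste(setdiff(levels, present), collapse = ", "))
  per <- lapply(present, function(cl) {
    tp <- sum(truth == cl & pred == cl)
    fp <- sum(truth != cl & pred == cl)
    fn <- sum(truth == cl & pred != cl)
    tn <- sum(truth != cl & pred != cl)
    prec <- if (tp + fp > 0) tp / (tp + fp) else 0
    rec <- if (tp + fn > 0) tp / (tp + fn) else 0
    f1 <- if (prec + rec > 0) 2 * prec * rec / (prec + rec) else 0
    data.frame(class = cl, accuracy = (tp + tn) / length(truth),
               precision = prec, recall = rec, f1 = f1)
  })
  per <- do.call(rbind, per)
  list(accuracy = mean(per$accuracy), precision = mean(per$precision),
       recall = mean(per$recall), f1 = mean(per$f1), per_class = per)
}

#' Gini-gain feature importances
#'
#' Total split gain attributed to each lagged feature, summed over all
#' trees of the ensemble and normalized to sum 1; features never used
#' in a split receive 0. Sorted descending.
#'
#' @param model A `boosted_model`.
#' @return A data.frame with `feature` and `gain`.
#' @export
feature_importances <- function(model) {
  stopifnot(inherits(model, "boosted_model"))
  # total split gain per feature, read from the model's text dump
  dump <- xgboost::xgb.dump(model$booster, with_stats = TRUE)
  splits <- regmatches(dump,
                       regexec("\\[f([0-9]+)<[^]]*\\].*gain=([-0-9.e+]+)",
                               dump))
  splits <- splits[vapply(splits, length, 0L) == 3L]
  gain <- stats::setNames(rep(0, length(model$feature_names)),
                          model$feature_names)
  for (s in splits) {
    k <- as.integer(s[2]) + 1L
    gain[k] <- gain[k] + as.numeric(s[3])
  }
  gain[gain < 0] <- 0    # numerically negative gains carry no importance
  tot <- sum(gain)
  if (tot > 0) gain <- gain / tot
  out <- data.frame(feature = names(gain), gain = unname(gain),
                    stringsAsFactors = FALSE)
  out[order(-out$gain), ]
}

#' Shuffle targets within each animal
#'
#' Permutes the target values across time within every animal,
#' destroying the feature-target association while preserving each
#' animal's target distribution — the null baseline for the estimator.
#'
#' @param dataset A `lagged_dataset`.
#' @param seed Integer seed.
#' @return The dataset with permuted `y`.
#' @export
permute_targets_within_animal <- function(dataset, seed = 1L) {
  stopifnot(inherits(dataset, "lagged_dataset"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  for (a in unique(dataset$animal_id)) {
    sel <- which(dataset$animal_id == a)
    dataset$y[sel] <- dataset$y[sample(sel)]
  }
  dataset
}

# Trailing standard error over the predictions of the past minute
# (k windows), per animal -- the uncertainty band drawn on prediction
# traces.
trailing_se <- function(x, k = 6) {
  vapply(seq_along(x), function(i) {
    v <- x[max(1L, i - k + 1L):i]
    if (length(v) < 2) return(NA_real_)
    stats::sd(v) / sqrt(length(v))
  }, numeric(1))
}

#' Run the full depth-of-anesthesia estimation experiment
#'
#' Leave-one-animal-out cross-validation of the lagged-feature boosted
#' regressor on an assembled dataset: per fold, fit on all other
#' animals, predict the held-out animal, and compute MAE, R^2,
#' quantized classification metrics (isoflurane target only) and
#' Gini-gain importances. Optionally runs the elapsed-time control
#' (an identical regressor trained on elapsed time per fold, its
#' per-fold R^2 Spearman-correlated with the depth-target R^2).
#'
#' @param dataset A `lagged_dataset` (target `"isoflurane"` or
#'   `"era"`).
#' @param config An [estimator_config()].
#' @param time_dataset Optional `lagged_dataset` with target `"time"`
#'   built from the same feature table; when supplied the time control
#'   is computed.
#' @return A list of class `doa_result`: `folds` (per-fold list with
#'   `animal`, `t_s`, `y`, `y_hat`, `y_hat_se`, `mae`, `r2`, optional
#'   `classification`, `importances`), `summary` (mean/sd of each
#'   metric across folds), `importance_matrix` (fold x feature gain)
#'   and optional `time_control` (`rho`, `p`, `time_r2`).
#' @export
run_doa_experiment <- function(dataset, config = estimator_config(),
                               time_dataset = NULL) {
  stopifnot(inherits(dataset, "lagged_dataset"))
  folds <- loo_folds(dataset)
  is_iso <- dataset$target == "isoflurane"
  results <- lapply(folds, function(f) {
    model <- fit_boosted_regressor(dataset$X[f$train, , drop = FALSE],
                                   dataset$y[f$train], config)
    y <- dataset$y[f$eval]
    y_hat <- predict(model, dataset$X[f$eval, , drop = FALSE])
    reg <- evaluate_regression(y, y_hat)
    res <- list(animal = f$animal, t_s = dataset$t_s[f$eval], y = y,
                y_hat = y_hat, y_hat_se = trailing_se(y_hat),
                mae = reg$mae, r2 = reg$r2,
                importances = feature_importances(model))
    if (is_iso) {
      res$classification <- classification_metrics(
        y, quantize_predictions(y_hat, config$levels), config$levels)
    }
    res
  })
  imp_mat <- do.call(rbind, lapply(results, function(r) {
    stats::setNames(r$importances$gain[match(dataset$feature_names,
                                             r$importances$feature)],
                    dataset$feature_names)
  }))
  rownames(imp_mat) <- vapply(results, `[[`, "", "animal")

  summarize <- function(v) c(mean = mean(v, na.rm = TRUE),
                             sd = stats::sd(v, na.rm = TRUE))
  summ <- list(mae = summarize(vapply(results, `[[`, 0, "mae")),
               r2 = summarize(vapply(results, `[[`, 0, "r2")))
  if (is_iso) {
    for (m in c("accuracy", "f1", "precision", "recall")) {
      summ[[m]] <- summarize(vapply(results, function(r)
        r$classification[[m]], 0))
    }
  }
  out <- list(folds = results, summary = summ, importance_matrix = imp_mat,
              target = dataset$target, config = config)

  if (!is.null(time_dataset)) {
    stopifnot(identical(time_dataset$target, "time"))
    if (length(folds) < 3)
      stop("time control needs >= 3 folds")
    tfolds <- loo_folds(time_dataset)
    time_r2 <- vapply(tfolds, function(f) {
      m <- fit_boosted_regressor(time_dataset$X[f$train, , drop = FALSE],
                                 time_dataset$y[f$train], config)
      evaluate_regression(time_dataset$y[f$eval],
                          predict(m, time_dataset$X[f$eval, , drop = FALSE]))$r2
    }, numeric(1))
    doa_r2 <- vapply(results, `[[`, 0, "r2")
    ct <- suppressWarnings(stats::cor.test(time_r2, doa_r2,
                                           method = "spearman"))
    out$time_control <- list(rho = unname(ct$estimate), p = ct$p.value,
                             time_r2 = time_r2, doa_r2 = doa_r2)
  }
  class(out) <- "doa_result"
  out
}

#' @export
print.doa_result <- function(x, ...) {
  cat(sprintf("DoA estimation (%s target), %d LOO folds\n", x$target,
              length(x$folds)))
  for (m in names(x$summary))
    cat(sprintf("  %-9s %.3f +/- %.3f\n", m, x$summary[[m]]["mean"],
                x$summary[[m]]["sd"]))
  if (!is.null(x$time_control))
    cat(sprintf("  time control: Spearman rho = %.3f (p = %.3f)\n",
                x$time_control$rho, x$time_control$p))
  invisible(x)
}
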