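make_toy_table <- function(n_animals = 4, n_seg = 3, n_win = 20,
                           seed = 1) {
  # small hand-built feature table with two informative features
  set.seed(seed)
  rows <- list()
  concs <- c(1.0, 1.5, 2.3)
  for (a in seq_len(n_animals)) {
    for (s in seq_len(n_seg)) {
      conc <- concs[(s - 1) %% 3 + 1]
      for (w in seq_len(n_win)) {
        rows[[length(rows) + 1L]] <- data.frame(
          animal_id = paste0("animal_", a), segment = s, conc_pct = conc,
          window_index = w,
          t_start_s = (s - 1) * n_win * 10 + (w - 1) * 10,
          feat_signal = conc + rnorm(1, 0, 0.05),
          feat_noise = rnorm(1)
        )
      }
    }
  }
  do.call(rbind, rows)
}

test_that("lagged dataset stacks consecutive windows and drops gap rows", {
  ft <- fix_features()
  ds <- assemble_dataset(ft, "isoflurane")
  # 12-window blocks yield 10 rows each (lags = 3)
  expect_equal(nrow(ds$X), 3 * 7 * (12 - 2))
  expect_equal(ncol(ds$X), 3 * length(feature_columns(ft)))
  expect_true(all(ds$y %in% c(1.0, 1.5, 2.3)))
  expect_true(all(grepl("_t-[012]$", colnames(ds$X))))
  # a row's t-0 slice equals the feature table row of its target window
  feats <- feature_columns(ft)
  i <- 17
  row_ft <- ft[ft$animal_id == ds$animal_id[i] &
                 ft$t_start_s == ds$t_s[i], feats]
  expect_equal(unname(ds$X[i, paste0(feats, "_t-0")]),
               unname(unlist(row_ft)))
  # ...and its t-2 slice equals the window two steps earlier
  row_tm2 <- ft[ft$animal_id == ds$animal_id[i] &
                  ft$t_start_s == ds$t_s[i] - 20, feats]
  expect_equal(unname(ds$X[i, paste0(feats, "_t-2")]),
               unname(unlist(row_tm2)))

  # 60-window block -> 58 rows
  tt <- make_toy_table(n_animals = 1, n_seg = 1, n_win = 60)
  expect_equal(nrow(assemble_dataset(tt, "isoflurane")$X), 58)
  # 2-window block -> empty with warning
  t2 <- make_toy_table(n_animals = 1, n_seg = 1, n_win = 2)
  expect_warning(e <- assemble_dataset(t2, "isoflurane"), "empty")
  expect_equal(nrow(e$X), 0)
})

test_that("leave-one-animal-out folds partition the dataset exactly", {
  ds <- assemble_dataset(make_toy_table(), "isoflurane")
  folds <- loo_folds(ds)
  expect_length(folds, 4)
  evals <- lapply(folds, `[[`, "eval")
  expect_equal(sort(unlist(evals)), seq_along(ds$y))
  for (f in folds) {
    expect_length(intersect(f$train, f$eval), 0)
    expect_setequal(c(f$train, f$eval), seq_along(ds$y))
    expect_false(f$animal %in% ds$animal_id[f$train])
  }
  one <- ds
  keep <- one$animal_id == "animal_1"
  one$X <- one$X[keep, ]; one$y <- one$y[keep]
  one$animal_id <- one$animal_id[keep]; one$t_s <- one$t_s[keep]
  expect_error(loo_folds(one), ">= 2 animals")
})

test_that("booster fits residuals stagewise with monotone training loss", {
  ds <- assemble_dataset(make_toy_table(), "isoflurane")
  cfg <- estimator_config()
  model <- fit_boosted_regressor(ds$X, ds$y, cfg)
  p10 <- predict(model, ds$X, nsteps = 10)
  p100 <- predict(model, ds$X)
  expect_lte(mean((p100 - ds$y)^2), mean((p10 - ds$y)^2))

  # constant target -> constant prediction, zero error
  yc <- rep(1.5, nrow(ds$X))
  mc <- fit_boosted_regressor(ds$X, yc, cfg)
  expect_equal(unname(predict(mc, ds$X)), yc, tolerance = 1e-7)

  # noise-free separable toy: y is a threshold of one feature
  set.seed(2)
  X <- matrix(rnorm(400 * 4), 400, 4)
  colnames(X) <- paste0("f", 1:4)
  y <- ifelse(X[, 2] > 0, 2.3, 1.0)
  m <- fit_boosted_regressor(X, y, cfg)
  r2 <- evaluate_regression(y, predict(m, X))$r2
  expect_gt(r2, 0.99)
  imp <- feature_importances(m)
  expect_gt(imp$gain[imp$feature == "f2"], 0.9)

  expect_error(fit_boosted_regressor(X[1:10, ], y[1:10], cfg), "fewer than")
})

test_that("booster agrees with a reference stagewise rpart booster on toy data", {
  skip_if_not_installed("rpart")
  set.seed(8)
  X <- matrix(rnorm(300 * 3), 300, 3)
  colnames(X) <- paste0("f", 1:3)
  y <- 1.5 + 0.8 * (X[, 1] > 0) - 0.5 * (X[, 3] < -0.5) + rnorm(300, 0, 0.01)
  cfg <- estimator_config(steps = 30)
  m <- fit_boosted_regressor(X, y, cfg)
  ref <- reference_booster(X, y, steps = 30, max_depth = 3, lr = 0.1)
  # both stagewise boosters converge to near-identical fits
  expect_gt(cor(predict(m, X), ref$pred), 0.999)
  expect_lt(mean(abs(predict(m, X) - ref$pred)), 0.02)
})

test_that("regression metrics follow their definitions", {
  y <- c(1, 2, 3, 4)
  expect_equal(evaluate_regression(y, y), list(mae = 0, r2 = 1))
  expect_equal(evaluate_regression(y, rep(mean(y), 4))$r2, 0)
  expect_equal(evaluate_regression(y, y + 0.1)$mae, 0.1)
  expect_true(is.na(evaluate_regression(rep(2, 4), c(1, 2, 3, 2))$r2))
})

test_that("quantization maps to the nearest level with lower-tie rule", {
  expect_equal(quantize_predictions(1.2), 1.0)
  expect_equal(quantize_predictions(2.0), 2.3)
  expect_equal(quantize_predictions(1.25), 1.0)   # midpoint -> lower
  expect_equal(quantize_predictions(1.9), 1.5)    # midpoint -> lower
  expect_equal(quantize_predictions(c(-5, 10)), c(1.0, 2.3))
  expect_equal(quantize_predictions(c(1.26, 1.89, 1.91)),
               c(1.5, 1.5, 2.3))
})

test_that("classification metrics match a hand-computed confusion matrix", {
  perfect <- c(1.0, 1.5, 2.3, 1.0)
  cm <- classification_metrics(perfect, perfect)
  expect_equal(cm$accuracy, 1)
  expect_equal(cm$f1, 1)

  # rows true 1.0/1.5/2.3: [[2,0,0],[0,2,0],[2,0,0]]
  truth <- c(1.0, 1.0, 1.5, 1.5, 2.3, 2.3)
  pred <- c(1.0, 1.0, 1.5, 1.5, 1.0, 1.0)
  cm2 <- classification_metrics(truth, pred)
  expect_equal(cm2$recall, (1 + 1 + 0) / 3)
  expect_equal(cm2$per_class$precision[cm2$per_class$class == 1.0], 0.5)

  # all predictions one class, balanced truth -> macro recall 1/3
  pred3 <- rep(1.5, 6)
  cm3 <- classification_metrics(truth, pred3)
  expect_equal(cm3$recall, 1 / 3)

  expect_warning(classification_metrics(c(1, 1), c(1, 1)), "absent")
})

test_that("importances are a normalized distribution over lagged features", {
  ds <- assemble_dataset(make_toy_table(), "isoflurane")
  m <- fit_boosted_regressor(ds$X, ds$y, estimator_config())
  imp <- feature_importances(m)
  expect_equal(sum(imp$gain), 1, tolerance = 1e-9)
  expect_true(all(imp$gain >= 0))
  expect_setequal(imp$feature, colnames(ds$X))
  # the informative feature dominates across its lags
  sig <- grepl("^feat_signal", imp$feature)
  expect_gt(sum(imp$gain[sig]), 0.9)
})

test_that("null importances spread when the target is independent of features", {
  over_half <- 0
  for (s in 1:20) {
    set.seed(s)
    X <- matrix(rnorm(200 * 5), 200, 5)
    colnames(X) <- paste0("f", 1:5)
    y <- rnorm(200)
    m <- fit_boosted_regressor(X, y, estimator_config(steps = 50))
    over_half <- over_half + any(feature_importances(m)$gain > 0.5)
  }
  expect_lte(over_half, 2)
})

test_that("elapsed-time control correlates fold scores correctly", {
  # trivial endpoints of the Spearman correlation
  expect_equal(suppressWarnings(
    cor.test(1:5, 1:5, method = "spearman"))$estimate[[1]], 1)
  # null behavior: independent fold scores rarely reach significance
  set.seed(123)
  sig <- 0
  for (i in 1:100) {
    a <- rnorm(11); b <- rnorm(11)
    p <- suppressWarnings(cor.test(a, b, method = "spearman"))$p.value
    sig <- sig + (p < 0.05)
  }
  expect_lte(sig, 10)

  # integrated: time control runs inside the experiment
  ds <- assemble_dataset(fix_features(), "isoflurane")
  tds <- assemble_dataset(fix_features(), "time")
  res <- run_doa_experiment(ds, estimator_config(), time_dataset = tds)
  expect_length(res$time_control$time_r2, 3)
  expect_true(is.finite(res$time_control$rho))
})

test_that("experiment results are deterministic and leakage-free", {
  ds <- assemble_dataset(fix_features(), "isoflurane")
  r1 <- run_doa_experiment(ds, estimator_config())
  r2 <- run_doa_experiment(ds, estimator_config())
  expect_identical(r1$summary, r2$summary)
  expect_identical(r1$importance_matrix, r2$importance_matrix)
  # each fold's held-out predictions cover exactly that animal's rows
  for (f in r1$folds) {
    expect_length(f$y_hat, sum(ds$animal_id == f$animal))
  }
  expect_false(any(is.na(r1$importance_matrix)))
  # every fold's importances sum to 1
  expect_equal(unname(rowSums(r1$importance_matrix)), rep(1, 3),
               tolerance = 1e-9)
})

test_that("target permutation destroys held-out predictability", {
  ds <- assemble_dataset(fix_features(), "isoflurane")
  perm <- permute_targets_within_animal(ds, seed = 5)
  expect_false(identical(perm$y, ds$y))
  expect_equal(sort(perm$y), sort(ds$y))
  res <- run_doa_experiment(perm, estimator_config())
  expect_lte(res$summary$r2[["mean"]], 0.05)
})
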