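#!/usr/bin/env Rscript
# Estimate the evoked-response attenuation (ERA) target with the same
# lagged-feature boosted regressor under leave-one-animal-out
# cross-validation. ERA estimation is expected to be less stable than
# the isoflurane target (fold R^2 can go negative); the per-fold
# spread of metrics and importances is the point of this run.
# Writes results/era/.

source("analysis/00_config.R")

ft <- data.table::fread(file.path(RESULTS_DIR, "features.tsv"),
                        data.table = FALSE)
stopifnot("era" %in% names(ft))
ds <- assemble_dataset(ft, target = "era", lags = 3)
message("Lagged dataset: ", nrow(ds$X), " rows, target = ERA in [",
        paste(round(range(ds$y), 3), collapse = ", "), "]")

cfg <- estimator_config()
res <- run_doa_experiment(ds, cfg)
print(res)

write_outputs(res, file.path(RESULTS_DIR, "era"),
              config = list(seed = SEED, estimator = unclass(cfg),
                            target = "era"))

fold_r2 <- vapply(res$folds, `[[`, 0, "r2")
message(sprintf("Per-fold R2 spread: min %.3f / median %.3f / max %.3f",
                min(fold_r2), stats::median(fold_r2), max(fold_r2)))
imp <- sort(colMeans(res$importance_matrix), decreasing = TRUE)
message("Top features by mean Gini gain across folds:")
print(round(utils::head(imp, 8), 4))
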