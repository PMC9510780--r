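#!/usr/bin/env Rscript
# Preprocess every recording (zero-phase 50 Hz notch + 0.1 Hz
# high-pass), cut per-concentration blocks, window them into 10 s
# epochs and extract the full feature set per window, plus the
# evoked-response-attenuation (ERA) target. Writes results/features.tsv.

source("analysis/00_config.R")

paths <- list.files(REC_DIR, pattern = "\\.csv$", full.names = TRUE)
stopifnot(length(paths) > 0)
message("Loading ", length(paths), " recordings ...")
recs <- lapply(paths, load_recording)
names(recs) <- vapply(recs, `[[`, "", "animal_id")

message("Extracting per-window features (10 s windows, ",
        DISCARD_MINUTES, " min discard) ...")
ft <- extract_cohort_features(recs, discard_minutes = DISCARD_MINUTES)
ft <- add_era_target(ft, recs, discard_minutes = DISCARD_MINUTES)

write_tsv(ft, file.path(RESULTS_DIR, "features.tsv"))
message("Wrote ", file.path(RESULTS_DIR, "features.tsv"), ": ",
        nrow(ft), " windows x ", length(feature_columns(ft)),
        " features (+ era target)")

agg <- aggregate(ft[c("coherence_5_40", "bsr_contra", "sampen_contra",
                      "lzc_contra", "era")],
                 by = list(conc_pct = ft$conc_pct), mean, na.rm = TRUE)
message("Per-concentration means (pooled over animals):")
print(agg, digits = 3)
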