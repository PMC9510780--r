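#!/usr/bin/env Rscript
# Simulate the synthetic cohort: two-channel ECoG per animal under the
# 7-segment isoflurane protocol, with depth-dependent interhemispheric
# coherence, burst suppression, 1/f background, 50 Hz line noise and
# attenuating whisker-evoked responses. Writes one CSV + JSON sidecar
# per animal under results/recordings/.

source("analysis/00_config.R")

message("Simulating ", N_ANIMALS, " animals, ",
        nrow(PROTOCOL), " x ", SEGMENT_MINUTES, " min segments ...")
recs <- simulate_cohort(N_ANIMALS, PROTOCOL, GEN_CONFIG, seed = SEED)

for (rec in recs) {
  path <- file.path(REC_DIR, paste0(rec$animal_id, ".csv"))
  write_recording(rec, path)
  message("  ", rec$animal_id, ": ",
          length(rec$ch_contra), " samples, ",
          length(rec$stim_onsets), " stimuli, mean depth ",
          round(mean(rec$ground_truth$depth), 3), " -> ", path)
}

# ground-truth depth traces are synthetic-only and do not travel with
# the CSVs; keep the per-animal mean depth per segment for reference
gt <- do.call(rbind, lapply(recs, function(r) {
  t <- (seq_along(r$ground_truth$depth) - 1) / r$sample_rate
  seg <- findInterval(t, r$protocol$start_s)
  data.frame(animal_id = r$animal_id, segment = seg,
             conc_pct = r$protocol$conc_pct[seg],
             depth = r$ground_truth$depth)
}))
gt_summary <- aggregate(depth ~ animal_id + segment + conc_pct, gt, mean)
write_tsv(gt_summary[order(gt_summary$animal_id, gt_summary$segment), ],
          file.path(RESULTS_DIR, "ground_truth_depth.tsv"))
message("Wrote ", file.path(RESULTS_DIR, "ground_truth_depth.tsv"))
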