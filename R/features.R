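#' Feature-extraction settings
#'
#' Collects every constant of the per-window feature set. Defaults:
#' Welch 2 s Hann segments with 50 % overlap (0.5 Hz grid, nine
#' segments per 10 s window), SEF fraction 0.95, aperiodic fit 20-40
#' Hz, canonical EEG bands with the gamma cap at 45 Hz, coherence
#' averaged 5-40 Hz, sample-entropy templates spanning 80 ms with
#' `m = 2` and `r = 0.2 sd`, moving-RMS burst detection.
#'
#' @param segment_s,overlap Welch parameters.
#' @param sef_fraction Spectral-edge power fraction.
#' @param slope_range Aperiodic-fit frequency range, Hz.
#' @param bands Named list of band edges, Hz.
#' @param coherence_range Coherence averaging band, Hz.
#' @param sampen_template_ms,sampen_m,sampen_r_factor Sample-entropy
#'   parameters.
#' @param burst_envelope_ms,burst_thresh_factor,burst_min_off_ms
#'   Burst-detection parameters.
#' @param coherence_on_raw If `TRUE`, coherence is computed on the raw
#'   (unfiltered) channels rather than the preprocessed ones.
#' @return A list of class `features_config`.
#' @export
features_config <- function(segment_s = 2, overlap = 0.5,
                            sef_fraction = 0.95,
                            slope_range = c(20, 40),
                            bands = list(delta = c(0.1, 4),
                                         theta = c(4, 8),
                                         alpha = c(8, 13),
                                         beta = c(13, 30),
                                         gamma = c(30, 45)),
                            coherence_range = c(5, 40),
                            sampen_template_ms = 80, sampen_m = 2,
                            sampen_r_factor = 0.2,
                            burst_envelope_ms = 50,
                            burst_thresh_factor = 0.2,
                            burst_min_off_ms = 100,
                            coherence_on_raw = FALSE) {
  cfg <- as.list(environment())
  class(cfg) <- "features_config"
  cfg
}

window_features_one_channel <- function(x, fs, block_median, cfg) {
  psd <- welch_psd(x, fs, cfg$segment_s, cfg$overlap)
  bp <- band_powers(psd, cfg$bands)
  names(bp) <- paste0("bp_", names(bp))
  c(
    sef95 = spectral_edge_frequency(psd, cfg$sef_fraction),
    slope_20_40 = aperiodic_slope(psd, cfg$slope_range[1],
                                  cfg$slope_range[2]),
    bp,
    sampen = sample_entropy(x, fs, cfg$sampen_template_ms, cfg$sampen_m,
                            cfg$sampen_r_factor),
    lzc = lempel_ziv_complexity(x, block_median)
  )
}

#' Per-window feature table for one recording
#'
#' Runs the full feature pipeline: preprocess (zero-phase notch +
#' high-pass), cut into per-concentration blocks (discarding the head
#' of each segment), split blocks into consecutive non-overlapping
#' windows, and compute every feature per window. Block-level
#' burst-suppression metrics and the block median used as the
#' Lempel-Ziv threshold are computed once per block (per channel) and
#' replicated onto each of its windows. Undefined features are `NA`.
#'
#' @param recording An `ecog_recording`.
#' @param discard_minutes Head of each segment discarded, minutes.
#' @param window_seconds Window length, seconds.
#' @param config A [features_config()].
#' @param preprocess If `TRUE` (default) apply [preprocess_recording()]
#'   first.
#' @return A data.frame (one row per window) with label columns
#'   `animal_id`, `segment`, `conc_pct`, `window_index`, `t_start_s`
#'   followed by the feature columns (channel-specific ones suffixed
#'   `_contra` / `_ipsi`, plus the cross-channel `coherence_5_40`).
#' @export
extract_feature_table <- function(recording, discard_minutes = 5,
                                  window_seconds = 10,
                                  config = features_config(),
                                  preprocess = TRUE) {
  stopifnot(inherits(recording, "ecog_recording"),
            inherits(config, "features_config"))
  fs <- recording$sample_rate
  raw <- recording
  rec <- if (preprocess) preprocess_recording(recording) else recording
  blocks <- segment_blocks(rec, discard_minutes)
  raw_blocks <- if (config$coherence_on_raw) {
    segment_blocks(raw, discard_minutes)
  } else NULL

  rows <- list()
  for (b in seq_along(blocks)) {
    blk <- blocks[[b]]
    med <- list(contra = stats::median(blk$ch_contra),
                ipsi = stats::median(blk$ch_ipsi))
    bmet <- lapply(list(contra = blk$ch_contra, ipsi = blk$ch_ipsi),
                   function(ch) {
                     iv <- detect_bursts(ch, fs, config$burst_envelope_ms,
                                         config$burst_thresh_factor,
                                         config$burst_min_off_ms)
                     burst_suppression_metrics(iv)
                   })
    wins <- window_block(blk, window_seconds)
    raw_wins <- if (!is.null(raw_blocks)) {
      window_block(raw_blocks[[b]], window_seconds)
    } else NULL
    for (w in seq_along(wins)) {
      win <- wins[[w]]
      fc <- window_features_one_channel(win$ch_contra, fs, med$contra, config)
      fi <- window_features_one_channel(win$ch_ipsi, fs, med$ipsi, config)
      names(fc) <- paste0(names(fc), "_contra")
      names(fi) <- paste0(names(fi), "_ipsi")
      coh_src <- if (!is.null(raw_wins)) raw_wins[[w]] else win
      coh <- interhemispheric_coherence(coh_src$ch_contra, coh_src$ch_ipsi,
                                        fs, config$coherence_range[1],
                                        config$coherence_range[2],
                                        config$segment_s, config$overlap)
      row <- data.frame(
        animal_id = win$animal_id,
        segment = win$segment,
        conc_pct = win$conc_pct,
        window_index = win$window_index,
        t_start_s = win$start_s,
        t(fc), t(fi),
        coherence_5_40 = coh,
        bsr_contra = bmet$contra$bsr,
        mean_on_s_contra = bmet$contra$mean_on_s,
        mean_off_s_contra = bmet$contra$mean_off_s,
        bsr_ipsi = bmet$ipsi$bsr,
        mean_on_s_ipsi = bmet$ipsi$mean_on_s,
        mean_off_s_ipsi = bmet$ipsi$mean_off_s,
        stringsAsFactors = FALSE
      )
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Feature columns of a feature table
#'
#' All columns that are signal features (everything except the label
#' columns and any target columns such as `era`).
#'
#' @param feature_table A data.frame from [extract_feature_table()].
#' @return Character vector of feature column names.
#' @export
feature_columns <- function(feature_table) {
  labels <- c("animal_id", "segment", "conc_pct", "window_index",
              "t_start_s", "era")
  setdiff(names(feature_table), labels)
}

#' Feature tables for a cohort
#'
#' Convenience wrapper running [extract_feature_table()] over a list of
#' recordings and row-binding the results.
#'
#' @param recordings List of `ecog_recording`s.
#' @param ... Passed to [extract_feature_table()].
#' @return Combined feature table.
#' @export
extract_cohort_features <- function(recordings, ...) {
  do.call(rbind, lapply(recordings, extract_feature_table, ...))
}
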