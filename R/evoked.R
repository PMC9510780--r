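#' Extract stimulus-locked evoked trials
#'
#' Cuts the signal into `[-0.2, +0.5]` s epochs around each stimulus
#' onset, baseline-corrected by subtracting the pre-stimulus mean so
#' each trial is zero-aligned at t = 0. Onsets too close to the record
#' edges are skipped; the number skipped is returned as an attribute.
#'
#' @param x Numeric signal (uV), normally the contralateral channel.
#' @param stim_onsets Onset times, seconds from signal start.
#' @param sample_rate Sampling rate, Hz.
#' @param window Epoch limits around the onset, seconds
#'   (default `c(-0.2, 0.5)`).
#' @return A matrix (trials x samples) with attributes `onsets` (kept
#'   onset times), `times` (epoch time axis, s) and `n_skipped`; zero
#'   rows when no onset fits.
#' @export
extract_trials <- function(x, stim_onsets, sample_rate,
                           window = c(-0.2, 0.5)) {
  n <- length(x)
  n_pre <- round(-window[1] * sample_rate)
  n_post <- round(window[2] * sample_rate)
  len <- n_pre + n_post + 1L
  times <- (seq_len(len) - 1L - n_pre) / sample_rate
  keep <- logical(length(stim_onsets))
  rows <- list()
  for (k in seq_along(stim_onsets)) {
    i0 <- round(stim_onsets[k] * sample_rate) + 1L  # sample at t = 0
    lo <- i0 - n_pre
    hi <- i0 + n_post
    if (lo < 1L || hi > n) next
    keep[k] <- TRUE
    tr <- x[lo:hi]
    baseline <- mean(tr[seq_len(n_pre)])
    rows[[length(rows) + 1L]] <- tr - baseline
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    matrix(numeric(0), 0, len)
  attr(out, "onsets") <- stim_onsets[keep]
  attr(out, "times") <- times
  attr(out, "n_skipped") <- sum(!keep)
  out
}

#' Maximum evoked-response amplitude of one trial
#'
#' Largest absolute deflection of the baseline-corrected trial in the
#' post-stimulus interval `(0, 0.5]` s.
#'
#' @param trial Numeric trial samples (one row of [extract_trials()]).
#' @param times Epoch time axis, seconds (the `times` attribute).
#' @return Amplitude in uV.
#' @export
trial_max_amplitude <- function(trial, times) {
  post <- times > 0
  if (!any(post)) return(0)
  max(abs(trial[post]))
}

#' Evoked-response attenuation (ERA) series
#'
#' Trailing moving average (default 10 stimuli) of the
#' stimulus-by-stimulus maximum evoked amplitudes, divided by the mean
#' amplitude over all stimuli delivered during `reference_conc` blocks
#' (1.0 % isoflurane), giving a unitless ratio that averages 1 in the
#' reference blocks.
#'
#' @param amplitudes Per-stimulus maximum amplitudes (uV).
#' @param onsets Per-stimulus onset times, seconds.
#' @param conc Per-stimulus administered concentration (percent).
#' @param window_stimuli Moving-average length in stimuli.
#' @param reference_conc Reference concentration (default 1.0).
#' @return A data.frame with `onset_s`, `amplitude`, `era` and
#'   attribute `reference` (uV).
#' @export
era_series <- function(amplitudes, onsets, conc, window_stimuli = 10,
                       reference_conc = 1.0) {
  stopifnot(length(amplitudes) == length(onsets),
            length(conc) == length(onsets))
  ref_sel <- abs(conc - reference_conc) < 1e-9
  if (!any(ref_sel))
    stop("cannot normalize: no stimuli in ", reference_conc, " % blocks")
  reference <- mean(amplitudes[ref_sel])
  if (reference <= 0) stop("reference amplitude is not positive")
  ord <- order(onsets)
  amps <- amplitudes[ord]
  ma <- vapply(seq_along(amps), function(k) {
    mean(amps[max(1L, k - window_stimuli + 1L):k])
  }, numeric(1))
  out <- data.frame(onset_s = onsets[ord], amplitude = amps,
                    era = ma / reference)
  attr(out, "reference") <- reference
  out
}

#' Compute the ERA series for one recording
#'
#' Full evoked pipeline on the contralateral channel of a (normally
#' preprocessed) recording: keep stimuli falling inside the analysis
#' blocks (the discarded first minutes of each segment contribute
#' neither trials nor the 1.0 % reference), extract trials, take
#' per-stimulus maximum amplitudes, and form the ERA ratio.
#'
#' @param recording An `ecog_recording`.
#' @param discard_minutes Head of each segment excluded, minutes.
#' @param window_stimuli Moving-average length in stimuli.
#' @param reference_conc Reference concentration, percent.
#' @param preprocess Apply [preprocess_recording()] first (default
#'   TRUE).
#' @return An [era_series()] data.frame.
#' @export
compute_era <- function(recording, discard_minutes = 5,
                        window_stimuli = 10, reference_conc = 1.0,
                        preprocess = TRUE) {
  stopifnot(inherits(recording, "ecog_recording"))
  rec <- if (preprocess) preprocess_recording(recording) else recording
  proto <- rec$protocol
  fs <- rec$sample_rate
  on <- rec$stim_onsets
  seg <- findInterval(on, proto$start_s)
  in_block <- on >= proto$start_s[seg] + discard_minutes * 60 &
    on + 0.5 <= proto$end_s[seg]
  on <- on[in_block]
  if (length(on) == 0) stop("no stimuli inside the analysis blocks")
  conc <- proto$conc_pct[seg[in_block]]
  trials <- extract_trials(rec$ch_contra, on, fs)
  kept <- attr(trials, "onsets")
  conc <- conc[on %in% kept]
  times <- attr(trials, "times")
  amps <- apply(trials, 1, trial_max_amplitude, times = times)
  era_series(amps, kept, conc, window_stimuli, reference_conc)
}

#' Append the ERA target to a cohort feature table
#'
#' Resamples each animal's ERA series onto the 10 s feature-window
#' grid: every window takes the most recent ERA value available at its
#' end (windows before the first stimulus take the first value).
#'
#' @param feature_table Cohort table from [extract_cohort_features()].
#' @param recordings The same recordings, named or ordered as their
#'   `animal_id`s appear in the table.
#' @param discard_minutes,window_stimuli,reference_conc,preprocess
#'   Passed to [compute_era()].
#' @param window_seconds Feature-window length, seconds.
#' @return The feature table with an `era` column (a target, not a
#'   feature: [feature_columns()] excludes it).
#' @export
add_era_target <- function(feature_table, recordings, discard_minutes = 5,
                           window_stimuli = 10, reference_conc = 1.0,
                           window_seconds = 10, preprocess = TRUE) {
  ids <- vapply(recordings, `[[`, "", "animal_id")
  feature_table$era <- NA_real_
  for (i in seq_along(recordings)) {
    es <- compute_era(recordings[[i]], discard_minutes, window_stimuli,
                      reference_conc, preprocess)
    sel <- feature_table$animal_id == ids[i]
    w_end <- feature_table$t_start_s[sel] + window_seconds
    idx <- findInterval(w_end, es$onset_s)
    idx[idx < 1L] <- 1L
    feature_table$era[sel] <- es$era[idx]
  }
  feature_table
}
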