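#' Preprocess a two-channel recording
#'
#' Applies the standard preprocessing cascade to both channels: a
#' zero-phase 50 Hz notch (Q = 30) followed by a zero-phase first-order
#' Butterworth high-pass at 0.1 Hz. Both filters are forward-backward,
#' so the cascade introduces no phase distortion and the order of the
#' two stages is immaterial.
#'
#' @param recording An `ecog_recording`.
#' @param notch_hz,notch_q Notch center frequency (Hz) and quality.
#' @param highpass_hz,highpass_order High-pass cutoff (Hz) and order.
#' @return The recording with filtered channels and attribute
#'   `preprocessed = TRUE`.
#' @export
preprocess_recording <- function(recording, notch_hz = 50, notch_q = 30,
                                 highpass_hz = 0.1, highpass_order = 1) {
  stopifnot(inherits(recording, "ecog_recording"))
  fs <- recording$sample_rate
  for (ch in c("ch_contra", "ch_ipsi")) {
    x <- notch_filter(recording[[ch]], fs, center = notch_hz,
                      quality = notch_q)
    recording[[ch]] <- highpass_filter(x, fs, cutoff = highpass_hz,
                                       order = highpass_order)
  }
  attr(recording, "preprocessed") <- TRUE
  recording
}

#' Cut a recording into per-concentration analysis blocks
#'
#' One block per protocol segment, with the first `discard_minutes`
#' of each segment removed to skip the transient that follows a
#' concentration switch (a 15-min segment yields a 10-min block under
#' the default 5-min discard).
#'
#' @param recording An `ecog_recording` (normally preprocessed).
#' @param discard_minutes Minutes discarded at the head of every
#'   segment (default 5).
#' @return A list of `ecog_block` objects, each a list with
#'   `animal_id`, `segment`, `conc_pct`, `start_s`, `end_s`,
#'   `sample_rate`, `ch_contra`, `ch_ipsi`.
#' @export
segment_blocks <- function(recording, discard_minutes = 5) {
  stopifnot(inherits(recording, "ecog_recording"))
  if (discard_minutes < 0) stop("`discard_minutes` must be >= 0")
  proto <- recording$protocol
  fs <- recording$sample_rate
  n <- length(recording$ch_contra)
  discard_s <- discard_minutes * 60
  blocks <- vector("list", nrow(proto))
  for (k in seq_len(nrow(proto))) {
    start_s <- proto$start_s[k] + discard_s
    end_s <- proto$end_s[k]
    if (start_s >= end_s)
      stop(sprintf("segment %d (%.0f s) shorter than the %.0f s discard",
                   k, proto$end_s[k] - proto$start_s[k], discard_s))
    i0 <- round(start_s * fs) + 1L
    i1 <- min(n, round(end_s * fs))
    blk <- list(
      animal_id = recording$animal_id,
      segment = k,
      conc_pct = proto$conc_pct[k],
      start_s = start_s,
      end_s = i1 / fs,
      sample_rate = fs,
      ch_contra = recording$ch_contra[i0:i1],
      ch_ipsi = recording$ch_ipsi[i0:i1]
    )
    class(blk) <- "ecog_block"
    blocks[[k]] <- blk
  }
  blocks
}

#' Split a block into consecutive non-overlapping windows
#'
#' Returns `floor(duration / window_seconds)` windows of exactly
#' `window_seconds * sample_rate` samples; any trailing remainder is
#' dropped so all windows are identically sized.
#'
#' @param block An `ecog_block`.
#' @param window_seconds Window length, seconds (default 10).
#' @return A list of `ecog_window` objects, each with `animal_id`,
#'   `segment`, `conc_pct`, `window_index` (1-based within block),
#'   `start_s` (absolute), `sample_rate`, `ch_contra`, `ch_ipsi`.
#' @export
window_block <- function(block, window_seconds = 10) {
  stopifnot(inherits(block, "ecog_block"))
  fs <- block$sample_rate
  wlen <- round(window_seconds * fs)
  n <- length(block$ch_contra)
  if (n < wlen) stop("block shorter than one window")
  n_win <- n %/% wlen
  lapply(seq_len(n_win), function(w) {
    i0 <- (w - 1L) * wlen + 1L
    i1 <- w * wlen
    win <- list(
      animal_id = block$animal_id,
      segment = block$segment,
      conc_pct = block$conc_pct,
      window_index = w,
      start_s = block$start_s + (w - 1L) * window_seconds,
      sample_rate = fs,
      ch_contra = block$ch_contra[i0:i1],
      ch_ipsi = block$ch_ipsi[i0:i1]
    )
    class(win) <- "ecog_window"
    win
  })
}
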