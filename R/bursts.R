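# Burst-suppression detection via a moving-RMS envelope with a
# percentile-anchored threshold and minimum-duration merging.

moving_rms <- function(x, win_len) {
  n <- length(x)
  win_len <- max(1L, min(n, win_len))
  cs <- cumsum(c(0, x^2))
  half <- win_len %/% 2
  lo <- pmax(0L, seq_len(n) - 1L - half)
  hi <- pmin(n, seq_len(n) - 1L - half + win_len)
  sqrt((cs[hi + 1L] - cs[lo + 1L]) / (hi - lo))
}

#' Detect burst (on) and suppression (off) intervals
#'
#' Classifies every sample by a moving-RMS envelope (default 50 ms):
#' samples whose envelope falls below `thresh_factor` times the block's
#' 90th-percentile envelope are suppression ("off"); off-runs shorter
#' than `min_off_ms` are merged back into the surrounding burst. The
#' result is an alternating sequence of intervals covering the block.
#'
#' @param x Numeric block samples (uV).
#' @param sample_rate Sampling rate, Hz.
#' @param envelope_ms Moving-RMS window, milliseconds.
#' @param thresh_factor Threshold as a fraction of the 90th-percentile
#'   envelope.
#' @param min_off_ms Minimum credible suppression duration,
#'   milliseconds.
#' @return A data.frame of class `burst_intervals` with `start_s`,
#'   `end_s` (seconds from block start) and `state` ("on"/"off"),
#'   contiguous, non-overlapping, alternating.
#' @export
detect_bursts <- function(x, sample_rate, envelope_ms = 50,
                          thresh_factor = 0.2, min_off_ms = 100) {
  n <- length(x)
  if (n < sample_rate) stop("block must be at least 1 s long")
  env <- moving_rms(x, round(envelope_ms / 1000 * sample_rate))
  thr <- thresh_factor * stats::quantile(env, 0.9, names = FALSE)
  off <- env <= thr      # <=, so an isoelectric (all-zero) block is all off
  # run-length representation; drop short off-runs
  r <- rle(off)
  min_len <- min_off_ms / 1000 * sample_rate
  r$values[r$values & r$lengths < min_len] <- FALSE
  off <- inverse.rle(r)
  r <- rle(off)
  ends <- cumsum(r$lengths)
  starts <- c(0L, ends[-length(ends)])
  iv <- data.frame(
    start_s = starts / sample_rate,
    end_s = ends / sample_rate,
    state = ifelse(r$values, "off", "on"),
    stringsAsFactors = FALSE
  )
  class(iv) <- c("burst_intervals", "data.frame")
  iv
}

#' Burst-suppression summary metrics
#'
#' @param intervals A `burst_intervals` data.frame covering one block.
#' @return A list with `bsr` (fraction of time suppressed), `mean_on_s`
#'   and `mean_off_s` (mean interval durations, 0 when a state never
#'   occurs).
#' @export
burst_suppression_metrics <- function(intervals) {
  stopifnot(inherits(intervals, "burst_intervals"))
  dur <- intervals$end_s - intervals$start_s
  total <- sum(dur)
  off <- intervals$state == "off"
  list(
    bsr = if (total > 0) sum(dur[off]) / total else 0,
    mean_on_s = if (any(!off)) mean(dur[!off]) else 0,
    mean_off_s = if (any(off)) mean(dur[off]) else 0
  )
}
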