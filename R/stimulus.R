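#' Raised-cosine whisker deflection pulse
#'
#' One full cycle of `x(t) = A/2 * (1 - cos(2 pi f t))` for `t` in
#' `[0, 1/f]`, the displacement waveform delivered by the piezo
#' actuator: it starts and ends at zero, peaks at `A`, and its peak
#' velocity is `A * pi * f` (113.1 mm/s for a 300 um, 120 Hz pulse).
#'
#' @param amplitude Peak displacement in micrometers.
#' @param frequency Pulse frequency in Hz; the pulse lasts one period.
#' @param sample_rate Waveform sample rate in Hz; must exceed twice the
#'   pulse frequency.
#' @return A list with `t` (seconds, from 0 through 1/f inclusive) and
#'   `x` (displacement, um).
#' @export
raised_cosine_pulse <- function(amplitude, frequency, sample_rate) {
  if (!is.finite(amplitude) || amplitude < 0)
    stop("`amplitude` must be a nonnegative number")
  if (!is.finite(frequency) || frequency <= 0)
    stop("`frequency` must be positive")
  if (!is.finite(sample_rate) || sample_rate <= 2 * frequency)
    stop("`sample_rate` must exceed twice `frequency`")
  t <- seq(0, 1 / frequency, by = 1 / sample_rate)
  if (t[length(t)] < 1 / frequency) t <- c(t, 1 / frequency)
  x <- amplitude / 2 * (1 - cos(2 * pi * frequency * t))
  list(t = t, x = x)
}

#' Stimulus onset times for an on/off pulse train
#'
#' Whisker stimuli are delivered as a constant-rate train that alternates
#' between stimulus-on and stimulus-off periods (the study uses a 1 Hz
#' train with 2 s on / 2 s off). Onsets are placed at `1/pulse_rate`
#' spacing from the start of each on-period; no onsets fall in
#' off-periods.
#'
#' @param total_duration Total schedule length in seconds.
#' @param pulse_rate Pulses per second during on-periods (Hz).
#' @param on_period,off_period Durations of the alternating on and off
#'   periods, seconds.
#' @return Numeric vector of onset times in seconds (possibly empty).
#' @export
make_stimulus_train <- function(total_duration, pulse_rate = 1,
                                on_period = 2, off_period = 2) {
  if (!is.finite(total_duration) || total_duration < 0)
    stop("`total_duration` must be >= 0")
  if (any(!is.finite(c(pulse_rate, on_period, off_period))) ||
      pulse_rate <= 0 || on_period <= 0 || off_period <= 0)
    stop("rate and periods must be positive")
  if (on_period < 1 / pulse_rate)
    stop("`on_period` shorter than one pulse interval")
  if (total_duration == 0) return(numeric(0))
  cycle <- on_period + off_period
  starts <- seq(0, total_duration, by = cycle)
  onsets <- unlist(lapply(starts, function(s) {
    o <- seq(s, s + on_period, by = 1 / pulse_rate)
    o[o < s + on_period]           # on-window is [s, s + on_period)
  }))
  sort(onsets[onsets < total_duration])
}
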