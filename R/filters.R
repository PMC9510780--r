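# Zero-phase IIR filtering: odd-reflection padding plus steady-state
# initial conditions, applied forward and backward. The recursion runs
# in C++ (src/filters.cpp); coefficient design uses signal::butter and a
# biquad notch designed here.

# Steady-state filter state for a unit step input (direct form II
# transposed), so that filtering a constant c from state zi * c is
# transient-free.
lfilter_zi <- function(b, a) {
  n <- max(length(a), length(b))
  b <- c(b, rep(0, n - length(b)))
  a <- c(a, rep(0, n - length(a)))
  if (a[1] != 1) {
    b <- b / a[1]
    a <- a / a[1]
  }
  if (n == 1) return(numeric(0))
  A <- rbind(-a[2:n], cbind(diag(1, n - 2), rep(0, n - 2)))
  B <- b[2:n] - b[1] * a[2:n]
  solve(diag(1, n - 1) - t(A), B)
}

#' Zero-phase IIR filtering
#'
#' Applies the filter `(b, a)` forward and backward with odd-reflection
#' padding and step-steady-state initial conditions, giving zero phase
#' lag and squared magnitude response. Edge-padding length defaults to
#' `3 * max(length(a), length(b))`.
#'
#' @param b,a Numerator / denominator filter coefficients.
#' @param x Numeric signal.
#' @param padlen Reflection pad length in samples (clamped to
#'   `length(x) - 1`).
#' @return Filtered signal, same length as `x`.
#' @keywords internal
filtfilt_zi <- function(b, a, x, padlen = 3 * max(length(a), length(b))) {
  n <- length(x)
  if (n < 2) return(x)
  padlen <- min(n - 1, max(1, padlen))
  zi <- lfilter_zi(b, a)
  ext <- c(2 * x[1] - x[(padlen + 1):2], x,
           2 * x[n] - x[(n - 1):(n - padlen)])
  y <- .lfilter_cpp(b, a, ext, zi * ext[1])
  y <- rev(.lfilter_cpp(b, a, rev(y), zi * y[length(y)]))
  y[(padlen + 1):(padlen + n)]
}

# Biquad notch design (second-order IIR with a unit-circle zero at the
# center frequency and -3 dB bandwidth center/Q).
design_notch <- function(center, sample_rate, quality) {
  w0 <- 2 * pi * center / sample_rate
  beta <- tan(w0 / quality / 2)
  gain <- 1 / (1 + beta)
  list(b = gain * c(1, -2 * cos(w0), 1),
       a = c(1, -2 * gain * cos(w0), 2 * gain - 1))
}

#' Zero-phase notch filter for line-noise removal
#'
#' Forward-backward second-order notch at `center` Hz with quality
#' factor `quality` (bandwidth `center/quality`). Steady-state rejection
#' at the center frequency is essentially complete; brief transients
#' remain within a few tenths of a second of the record edges, as for
#' any zero-phase IIR.
#'
#' @param x Numeric signal (microvolts).
#' @param sample_rate Sampling rate, Hz.
#' @param center Notch center frequency, Hz (default 50, European mains).
#' @param quality Dimensionless quality factor (default 30).
#' @return Filtered signal, same length as `x`.
#' @export
notch_filter <- function(x, sample_rate, center = 50, quality = 30) {
  if (!is.finite(center) || center <= 0 || center >= sample_rate / 2)
    stop("`center` must lie strictly below the Nyquist frequency")
  if (!is.finite(quality) || quality <= 0)
    stop("`quality` must be positive")
  f <- design_notch(center, sample_rate, quality)
  filtfilt_zi(f$b, f$a, x)
}

#' Zero-phase Butterworth high-pass filter
#'
#' Forward-backward Butterworth high-pass (default first order, 0.1 Hz)
#' removing DC offset and slow drift.
#'
#' @param x Numeric signal (microvolts).
#' @param sample_rate Sampling rate, Hz.
#' @param cutoff Cutoff frequency, Hz (default 0.1).
#' @param order Butterworth order (default 1).
#' @return Filtered signal, same length as `x`.
#' @export
highpass_filter <- function(x, sample_rate, cutoff = 0.1, order = 1) {
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= sample_rate / 2)
    stop("`cutoff` must lie strictly below the Nyquist frequency")
  bf <- signal::butter(order, cutoff / (sample_rate / 2), type = "high")
  # the filter's time constant is ~1/(2 pi cutoff); pad accordingly so
  # edge transients of slow high-pass filters die inside the padding
  filtfilt_zi(bf$b, bf$a, x,
              padlen = min(length(x) - 1, round(3 * sample_rate / cutoff)))
}

# Zero-phase Butterworth band-pass, used by the synthetic generator to
# band-limit the shared oscillatory source.
bandpass_filter <- function(x, sample_rate, f_lo, f_hi, order = 4) {
  bf <- signal::butter(order, c(f_lo, f_hi) / (sample_rate / 2),
                       type = "pass")
  filtfilt_zi(bf$b, bf$a, x)
}
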