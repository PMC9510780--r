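# Welch spectral estimation and the spectral features derived from it.
# Undefined features (zero power, too few bins) are returned as NA so
# that downstream tables record them as missing, never as silent zeros.

welch_segments <- function(n, seg_len, step) {
  starts <- seq(1L, n - seg_len + 1L, by = step)
  starts
}

# Shared Welch machinery: averaged auto-(and optionally cross-)spectra
# over mean-detrended, Hann-tapered, 50 %-overlapping segments.
# One-sided density scaling: integrating the PSD over frequency
# approximates the signal variance.
welch_raw <- function(x, y = NULL, sample_rate, segment_s = 2,
                      overlap = 0.5) {
  n <- length(x)
  seg_len <- round(segment_s * sample_rate)
  if (seg_len > n) stop("Welch segment longer than the window")
  if (seg_len < 2) stop("Welch segment too short")
  step <- max(1L, round(seg_len * (1 - overlap)))
  starts <- welch_segments(n, seg_len, step)
  k <- 0:(seg_len - 1)
  w <- 0.5 * (1 - cos(2 * pi * k / seg_len))   # periodic Hann
  norm <- sample_rate * sum(w^2)
  n_f <- seg_len %/% 2 + 1L
  freq <- (0:(n_f - 1)) * sample_rate / seg_len
  sxx <- numeric(n_f)
  syy <- if (!is.null(y)) numeric(n_f) else NULL
  sxy <- if (!is.null(y)) complex(n_f) else NULL
  for (s in starts) {
    xs <- x[s:(s + seg_len - 1L)]
    X <- stats::fft(w * (xs - mean(xs)))[1:n_f]
    sxx <- sxx + Re(X * Conj(X))
    if (!is.null(y)) {
      ys <- y[s:(s + seg_len - 1L)]
      Y <- stats::fft(w * (ys - mean(ys)))[1:n_f]
      syy <- syy + Re(Y * Conj(Y))
      sxy <- sxy + X * Conj(Y)
    }
  }
  one_sided <- rep(2, n_f)
  one_sided[1] <- 1
  if (seg_len %% 2 == 0) one_sided[n_f] <- 1
  K <- length(starts)
  out <- list(freq = freq, sxx = sxx * one_sided / (norm * K),
              n_segments = K)
  if (!is.null(y)) {
    out$syy <- syy * one_sided / (norm * K)
    out$sxy <- sxy * one_sided / (norm * K)
  }
  out
}

#' Welch power spectral density of one window
#'
#' Averaged periodogram over Hann-tapered, mean-detrended segments
#' (default 2 s, 50 % overlap: nine segments per 10 s window at a
#' 0.5 Hz grid). Density scaling: the trapezoidal integral of the PSD
#' over frequency approximates the window variance.
#'
#' @param x Numeric signal (uV).
#' @param sample_rate Sampling rate, Hz.
#' @param segment_s Welch segment length, seconds (default 2).
#' @param overlap Fractional segment overlap (default 0.5).
#' @return A list of class `welch_psd` with `freq` (Hz), `power`
#'   (uV^2/Hz) and `n_segments`.
#' @export
welch_psd <- function(x, sample_rate, segment_s = 2, overlap = 0.5) {
  wr <- welch_raw(x, NULL, sample_rate, segment_s, overlap)
  out <- list(freq = wr$freq, power = wr$sxx, n_segments = wr$n_segments)
  class(out) <- "welch_psd"
  out
}

#' Spectral edge frequency
#'
#' Smallest grid frequency below which at least `fraction` of the total
#' spectral power is contained (SEF95 for the default 0.95).
#'
#' @param psd A `welch_psd`.
#' @param fraction Power fraction in (0, 1].
#' @return Frequency in Hz, or `NA` if the PSD carries no power.
#' @export
spectral_edge_frequency <- function(psd, fraction = 0.95) {
  stopifnot(inherits(psd, "welch_psd"), fraction > 0, fraction <= 1)
  tot <- sum(psd$power)
  if (!is.finite(tot) || tot <= 0) return(NA_real_)
  cum <- cumsum(psd$power) / tot
  psd$freq[which(cum >= fraction)[1]]
}

#' Aperiodic (1/f) slope of the PSD
#'
#' Least-squares slope of `log10(power)` versus `log10(frequency)`
#' restricted to `[f_lo, f_hi]` (default 20-40 Hz, above the
#' oscillatory bands and below the notch).
#'
#' @param psd A `welch_psd`.
#' @param f_lo,f_hi Fit range, Hz.
#' @return Unitless log-log slope, or `NA` if fewer than 3 bins or
#'   nonpositive power in range.
#' @export
aperiodic_slope <- function(psd, f_lo = 20, f_hi = 40) {
  stopifnot(inherits(psd, "welch_psd"))
  sel <- psd$freq >= f_lo & psd$freq <= f_hi
  if (sum(sel) < 3) return(NA_real_)
  p <- psd$power[sel]
  if (any(p <= 0)) return(NA_real_)
  lf <- log10(psd$freq[sel])
  lp <- log10(p)
  sum((lf - mean(lf)) * (lp - mean(lp))) / sum((lf - mean(lf))^2)
}

#' Band powers from a PSD
#'
#' Trapezoidal integral of the PSD over each canonical EEG band:
#' delta 0.1-4, theta 4-8, alpha 8-13, beta 13-30, gamma 30-45 Hz
#' (the gamma cap keeps clear of the 50 Hz notch).
#'
#' @param psd A `welch_psd`.
#' @param bands Named list of `c(lo, hi)` band edges in Hz.
#' @return Named numeric vector of band powers (uV^2).
#' @export
band_powers <- function(psd,
                        bands = list(delta = c(0.1, 4), theta = c(4, 8),
                                     alpha = c(8, 13), beta = c(13, 30),
                                     gamma = c(30, 45))) {
  stopifnot(inherits(psd, "welch_psd"))
  vapply(bands, function(b) {
    sel <- psd$freq >= b[1] & psd$freq <= b[2]
    if (sum(sel) < 2) return(0)
    f <- psd$freq[sel]
    p <- psd$power[sel]
    sum(diff(f) * (p[-1] + p[-length(p)]) / 2)
  }, numeric(1))
}

#' Interhemispheric magnitude-squared coherence
#'
#' Welch magnitude-squared coherence `|Sxy|^2 / (Sxx * Syy)` between
#' the two channels, arithmetically averaged over grid bins in
#' `[f_lo, f_hi]` (default 5-40 Hz). At least two Welch segments are
#' required; a single-segment estimate is identically 1 and is
#' rejected.
#'
#' @param x,y Channel signals of equal length (uV).
#' @param sample_rate Sampling rate, Hz.
#' @param f_lo,f_hi Averaging band, Hz.
#' @param segment_s,overlap Welch parameters as in [welch_psd()].
#' @return Scalar coherence in `[0, 1]`.
#' @export
interhemispheric_coherence <- function(x, y, sample_rate, f_lo = 5,
                                       f_hi = 40, segment_s = 2,
                                       overlap = 0.5) {
  if (length(x) != length(y)) stop("channels must have equal length")
  wr <- welch_raw(x, y, sample_rate, segment_s, overlap)
  if (wr$n_segments < 2)
    stop("coherence needs >= 2 Welch segments (single-segment estimate is degenerate)")
  sel <- wr$freq >= f_lo & wr$freq <= f_hi
  denom <- wr$sxx[sel] * wr$syy[sel]
  coh <- ifelse(denom > 0, Mod(wr$sxy[sel])^2 / denom, 0)
  mean(pmin(1, coh))
}
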