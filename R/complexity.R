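#' Sample entropy of a signal window
#'
#' `SampEn = -ln(A/B)` where `B` counts template pairs matching at `m`
#' points and `A` those also matching at the `(m+1)`-th point, under
#' the Chebyshev distance with tolerance `r = r_factor * sd(x)`.
#' Templates are lag-embedded so that the `m`-point span covers
#' `template_ms` (80 ms = 20 samples at 250 Hz with `m = 2` gives a lag
#' of 10 samples); self-matches are excluded.
#'
#' @param x Numeric window (uV).
#' @param sample_rate Sampling rate, Hz.
#' @param template_ms Temporal span of one template, milliseconds.
#' @param m Embedding dimension (default 2).
#' @param r_factor Tolerance as a fraction of the window SD.
#' @return Sample entropy in nats; `NA` when no template matches exist
#'   (undefined) and `0` for a constant signal with positive tolerance.
#' @export
sample_entropy <- function(x, sample_rate, template_ms = 80, m = 2,
                           r_factor = 0.2) {
  n <- length(x)
  lag <- max(1L, round(template_ms / 1000 * sample_rate / m))
  if (n <= (m + 1) * lag) stop("window too short for the template span")
  r <- r_factor * stats::sd(x)
  if (!is.finite(r)) return(NA_real_)
  if (r == 0) {
    # constant signal with r_factor > 0 -> all templates match exactly
    if (r_factor > 0 && length(unique(x)) == 1L) return(0)
    return(NA_real_)
  }
  cnt <- .sampen_counts_cpp(as.numeric(x), as.integer(m), as.integer(lag), r)
  B <- cnt[1]; A <- cnt[2]
  if (B == 0 || A == 0) return(NA_real_)
  -log(A / B)
}

#' Lempel-Ziv (LZ76) complexity of a binarized window
#'
#' The window is binarized against `threshold` (sample > threshold ->
#' 1); the threshold must be the median of the parent signal block, not
#' of the window, so that windows of one block share a common
#' reference. The binary sequence is parsed with the LZ76
#' exhaustive-history scheme (terminal incomplete word counted as one
#' word) and the word count `C` is normalized as `C * log2(n) / n`,
#' which is ~1 for fair-coin noise and window-length invariant.
#'
#' @param x Numeric window (uV).
#' @param threshold Binarization threshold (uV), the parent block
#'   median.
#' @return Normalized LZ76 complexity (unitless).
#' @export
lempel_ziv_complexity <- function(x, threshold) {
  n <- length(x)
  if (n == 0) stop("empty window")
  s <- as.integer(x > threshold)
  C <- .lz76_cpp(s)
  C * log2(n) / n
}
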