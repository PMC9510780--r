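#' Build a piecewise-constant isoflurane protocol
#'
#' An anesthesia protocol is an ordered sequence of constant-concentration
#' segments. The study design this package targets uses seven 15-minute
#' segments at 1.5, 2.3, 1.0, 1.5, 1.0, 2.3 and 1.5 % isoflurane.
#'
#' @param concentrations Numeric vector of administered isoflurane
#'   concentrations in percent, one per segment, in delivery order.
#' @param segment_minutes Duration of every segment in minutes (scalar).
#' @return An object of class `anesthesia_protocol`: a data.frame with
#'   columns `segment` (1-based index), `conc_pct`, `start_s`, `end_s`,
#'   plus attribute `total_s`.
#' @examples
#' make_protocol(c(1.5, 2.3, 1.0, 1.5, 1.0, 2.3, 1.5), 15)
#' @export
make_protocol <- function(concentrations, segment_minutes) {
  if (length(concentrations) == 0L)
    stop("`concentrations` must be a nonempty numeric vector")
  if (!is.numeric(concentrations) || any(!is.finite(concentrations)) ||
      any(concentrations <= 0))
    stop("concentrations must be finite and > 0")
  if (!is.numeric(segment_minutes) || length(segment_minutes) != 1L ||
      !is.finite(segment_minutes) || segment_minutes <= 0)
    stop("`segment_minutes` must be a single positive number")
  dur <- segment_minutes * 60
  n <- length(concentrations)
  proto <- data.frame(
    segment = seq_len(n),
    conc_pct = as.numeric(concentrations),
    start_s = (seq_len(n) - 1) * dur,
    end_s = seq_len(n) * dur
  )
  attr(proto, "total_s") <- n * dur
  class(proto) <- c("anesthesia_protocol", "data.frame")
  proto
}

#' Total duration of a protocol in seconds
#' @param protocol An `anesthesia_protocol`.
#' @return Scalar seconds.
#' @export
protocol_duration <- function(protocol) {
  stopifnot(inherits(protocol, "anesthesia_protocol"))
  attr(protocol, "total_s")
}

#' Administered concentration at given times
#'
#' @param protocol An `anesthesia_protocol`.
#' @param t Numeric vector of times in seconds from protocol start.
#'   Times at a segment boundary belong to the later segment; times at
#'   or beyond the protocol end take the last segment's concentration.
#' @return Numeric vector of concentrations (percent isoflurane).
#' @export
protocol_concentration_at <- function(protocol, t) {
  stopifnot(inherits(protocol, "anesthesia_protocol"))
  idx <- findInterval(t, protocol$start_s, rightmost.closed = FALSE)
  idx[idx < 1L] <- 1L
  idx[idx > nrow(protocol)] <- nrow(protocol)
  protocol$conc_pct[idx]
}

#' @export
print.anesthesia_protocol <- function(x, ...) {
  cat(sprintf("Anesthesia protocol: %d segments, %.1f min total\n",
              nrow(x), attr(x, "total_s") / 60))
  print.data.frame(x, row.names = FALSE)
  invisible(x)
}
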