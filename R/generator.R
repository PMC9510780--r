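#' Configuration for the synthetic ECoG generator
#'
#' Bundles every knob of the two-channel synthetic ECoG model with
#' field-realistic defaults for mouse epidural recordings. The hidden
#' depth-of-anesthesia `d` in `[0, 1]` is a clipped linear map of the
#' administered concentration; every anesthetic modulation is a function
#' of `d`:
#'
#' * interhemispheric coupling: both channels receive a shared 5-40 Hz
#'   band-limited source with amplitude weight `sqrt(rho(d))` and an
#'   independent band-limited source with weight `sqrt(1 - rho(d))`,
#'   where `rho(d) = rho_lo + (rho_hi - rho_lo) d`; the long-run
#'   magnitude-squared coherence of the oscillatory component is
#'   `rho(d)^2` (diluted by the independent 1/f background),
#' * burst suppression: an alternating-exponential (semi-Markov) gate
#'   with mean on-duration `burst_mean_on_s` and mean off-duration
#'   `burst_mean_off_s_per_depth * d`; during off-states all
#'   non-line-noise components are scaled to `suppression_scale`,
#' * evoked responses: a damped half-sine kernel at each stimulus onset
#'   with peak `evoked_amplitude_uv * (1 - evoked_attenuation * d)` on
#'   the contralateral channel (and `evoked_ipsi_fraction` of that on
#'   the ipsilateral channel).
#'
#' The background is 1/f-shaped Gaussian noise (log-log PSD slope
#' `-aperiodic_exponent`) plus a fixed-amplitude mains sinusoid.
#'
#' @param sample_rate Sampling rate, Hz (default 250).
#' @param depth_c_lo,depth_c_hi Concentrations (percent) mapped to depth
#'   0 and 1; `d = clip((c - depth_c_lo)/(depth_c_hi - depth_c_lo), 0, 1)`.
#' @param transition_tau_s Time constant of the first-order exponential
#'   approach of depth to its new target after a concentration switch,
#'   seconds; 0 gives instantaneous transitions.
#' @param rho_lo,rho_hi Shared-variance mixing weight of the 5-40 Hz
#'   oscillatory source at depth 0 and 1 (each in `[0, 1)`,
#'   nondecreasing).
#' @param osc_band Band of the oscillatory sources, Hz.
#' @param shared_rms_uv RMS of the oscillatory component per channel, uV.
#' @param background_rms_uv RMS of the 1/f background per channel, uV.
#' @param aperiodic_exponent 1/f exponent of the background PSD
#'   (power ~ f^-exponent), default 2.
#' @param line_amplitude_uv,line_freq Mains sinusoid amplitude (uV) and
#'   frequency (Hz).
#' @param burst_mean_on_s Mean burst (on) duration, seconds.
#' @param burst_mean_off_s_per_depth Mean suppression (off) duration per
#'   unit depth, seconds; mean off at depth `d` is this value times `d`.
#' @param suppression_scale Amplitude factor applied to non-line
#'   components during suppression (default 0.05).
#' @param evoked_amplitude_uv Evoked-response kernel peak at depth 0, uV.
#' @param evoked_latency_s,evoked_width_s Kernel latency and width, s.
#' @param evoked_attenuation Linear attenuation slope of the evoked peak
#'   versus depth (peak scales by `1 - evoked_attenuation * d`).
#' @param evoked_ipsi_fraction Fraction of the evoked kernel mixed into
#'   the ipsilateral channel.
#' @param stim_pulse_rate,stim_on_s,stim_off_s Stimulus-train parameters
#'   (Hz, s, s); set `stim_pulse_rate = 0` to disable stimulation.
#' @param seed Integer RNG seed.
#' @return A list of class `generator_config`.
#' @export
generator_config <- function(sample_rate = 250,
                             depth_c_lo = 0.8, depth_c_hi = 2.5,
                             transition_tau_s = 60,
                             rho_lo = 0.25, rho_hi = 0.85,
                             osc_band = c(5, 40),
                             shared_rms_uv = 25,
                             background_rms_uv = 30,
                             aperiodic_exponent = 2,
                             line_amplitude_uv = 5, line_freq = 50,
                             burst_mean_on_s = 4,
                             burst_mean_off_s_per_depth = 2.5,
                             suppression_scale = 0.05,
                             evoked_amplitude_uv = 150,
                             evoked_latency_s = 0.025,
                             evoked_width_s = 0.04,
                             evoked_attenuation = 0.8,
                             evoked_ipsi_fraction = 0.3,
                             stim_pulse_rate = 1,
                             stim_on_s = 2, stim_off_s = 2,
                             seed = 1L) {
  cfg <- as.list(environment())
  if (cfg$sample_rate <= 2 * max(cfg$osc_band, 45))
    stop("sample_rate must exceed twice the highest analysis frequency")
  if (cfg$rho_lo > cfg$rho_hi)
    stop("rho must be nondecreasing in depth (rho_lo <= rho_hi)")
  if (any(c(cfg$rho_lo, cfg$rho_hi) < 0) || any(c(cfg$rho_lo, cfg$rho_hi) >= 1))
    stop("rho weights must lie in [0, 1)")
  if (cfg$burst_mean_off_s_per_depth < 0 || cfg$burst_mean_on_s <= 0)
    stop("burst durations must be positive (mean off >= 0)")
  if (cfg$depth_c_hi <= cfg$depth_c_lo)
    stop("depth_c_hi must exceed depth_c_lo")
  class(cfg) <- "generator_config"
  cfg
}

#' Map administered concentration to hidden depth
#' @param config A `generator_config`.
#' @param conc Concentration(s), percent isoflurane.
#' @return Depth value(s) in `[0, 1]`.
#' @export
depth_from_concentration <- function(config, conc) {
  d <- (conc - config$depth_c_lo) / (config$depth_c_hi - config$depth_c_lo)
  pmin(1, pmax(0, d))
}

# 1/f^(exponent) shaped Gaussian noise via spectral shaping of white
# noise; returned with unit variance.
one_over_f_noise <- function(n, sample_rate, exponent) {
  w <- stats::rnorm(n)
  X <- stats::fft(w)
  f <- c(0, seq_len(n - 1)) * sample_rate / n
  f <- pmin(f, sample_rate - f)      # two-sided frequency magnitudes
  scale <- ifelse(f > 0, f^(-exponent / 2), 0)
  x <- Re(stats::fft(X * scale, inverse = TRUE)) / n
  as.numeric(scale(x))
}

# Alternating-exponential burst gate. Returns a logical vector, TRUE
# where the signal is suppressed. Mean off duration follows the
# instantaneous depth trace at the moment each off-state is entered.
burst_gate <- function(n, sample_rate, depth, mean_on, mean_off_per_depth) {
  suppressed <- logical(n)
  if (mean_off_per_depth <= 0) return(suppressed)
  i <- 1L
  on_state <- TRUE
  while (i <= n) {
    if (on_state) {
      dur <- stats::rexp(1, 1 / mean_on)
    } else {
      mo <- mean_off_per_depth * depth[i]
      if (mo <= 0) { on_state <- TRUE; next }
      dur <- stats::rexp(1, 1 / mo)
    }
    len <- max(1L, round(dur * sample_rate))
    j <- min(n, i + len - 1L)
    if (!on_state) suppressed[i:j] <- TRUE
    i <- j + 1L
    on_state <- !on_state
  }
  suppressed
}

# Damped half-sine evoked kernel, peak normalized to 1, preceded by
# `latency` seconds of silence.
evoked_kernel <- function(sample_rate, latency, width) {
  n_lat <- round(latency * sample_rate)
  n_w <- max(2L, round(width * sample_rate))
  tau <- seq(0, 1, length.out = n_w)
  k <- sin(pi * tau) * exp(-2 * tau)
  c(rep(0, n_lat), k / max(k))
}

#' Simulate a two-channel synthetic ECoG recording
#'
#' Generates contralateral and ipsilateral ECoG traces under the model
#' described in [generator_config()], driven by an anesthesia protocol.
#' The recording carries its hidden ground truth (per-sample depth and
#' suppression gate), available only for synthetic data.
#'
#' @param config A `generator_config`.
#' @param protocol An `anesthesia_protocol`.
#' @param animal_id Character label for the simulated animal.
#' @return A list of class `ecog_recording` with elements `ch_contra`,
#'   `ch_ipsi` (uV), `sample_rate`, `stim_onsets` (s), `protocol`,
#'   `animal_id`, and `ground_truth` (list: `depth`, `suppressed`,
#'   per-sample).
#' @export
simulate_recording <- function(config, protocol, animal_id = "animal_1") {
  stopifnot(inherits(config, "generator_config"),
            inherits(protocol, "anesthesia_protocol"))
  fs <- config$sample_rate
  total_s <- protocol_duration(protocol)
  n <- round(total_s * fs)
  if (n < fs) stop("protocol too short to simulate")

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  t <- (seq_len(n) - 1) / fs
  conc <- protocol_concentration_at(protocol, t)
  d_target <- depth_from_concentration(config, conc)
  if (config$transition_tau_s > 0) {
    alpha <- 1 / (fs * config$transition_tau_s)
    depth <- .lfilter_cpp(alpha, c(1, -(1 - alpha)), d_target,
                          (1 - alpha) * d_target[1])
  } else {
    depth <- d_target
  }

  rho <- config$rho_lo + (config$rho_hi - config$rho_lo) * depth

  band <- function() {
    x <- bandpass_filter(stats::rnorm(n), fs,
                         config$osc_band[1], config$osc_band[2])
    as.numeric(scale(x))
  }
  shared <- band()
  osc1 <- config$shared_rms_uv * (sqrt(rho) * shared + sqrt(1 - rho) * band())
  osc2 <- config$shared_rms_uv * (sqrt(rho) * shared + sqrt(1 - rho) * band())

  bg1 <- config$background_rms_uv *
    one_over_f_noise(n, fs, config$aperiodic_exponent)
  bg2 <- config$background_rms_uv *
    one_over_f_noise(n, fs, config$aperiodic_exponent)

  line1 <- config$line_amplitude_uv *
    sin(2 * pi * config$line_freq * t + stats::runif(1, 0, 2 * pi))
  line2 <- config$line_amplitude_uv *
    sin(2 * pi * config$line_freq * t + stats::runif(1, 0, 2 * pi))

  if (config$stim_pulse_rate > 0) {
    onsets <- make_stimulus_train(total_s, config$stim_pulse_rate,
                                  config$stim_on_s, config$stim_off_s)
  } else {
    onsets <- numeric(0)
  }
  ev1 <- numeric(n)
  if (length(onsets) > 0 && config$evoked_amplitude_uv > 0) {
    kern <- evoked_kernel(fs, config$evoked_latency_s, config$evoked_width_s)
    for (o in onsets) {
      i0 <- round(o * fs) + 1L
      i1 <- min(n, i0 + length(kern) - 1L)
      if (i0 > n) next
      amp <- config$evoked_amplitude_uv *
        (1 - config$evoked_attenuation * depth[i0])
      ev1[i0:i1] <- ev1[i0:i1] + amp * kern[seq_len(i1 - i0 + 1L)]
    }
  }
  ev2 <- config$evoked_ipsi_fraction * ev1

  suppressed <- burst_gate(n, fs, depth, config$burst_mean_on_s,
                           config$burst_mean_off_s_per_depth)
  gate <- ifelse(suppressed, config$suppression_scale, 1)

  rec <- list(
    ch_contra = gate * (osc1 + bg1 + ev1) + line1,
    ch_ipsi = gate * (osc2 + bg2 + ev2) + line2,
    sample_rate = fs,
    stim_onsets = onsets,
    protocol = protocol,
    animal_id = animal_id,
    ground_truth = list(depth = depth, suppressed = suppressed)
  )
  class(rec) <- "ecog_recording"
  rec
}

#' Simulate a cohort of synthetic animals
#'
#' Runs [simulate_recording()] once per animal with per-animal seeds
#' derived from `seed` (seed + 1000 * (i - 1)), so cohorts are
#' reproducible and animals mutually independent.
#'
#' @param n_animals Number of animals.
#' @param protocol An `anesthesia_protocol` shared by all animals.
#' @param config A `generator_config`; its `seed` field is overridden
#'   per animal.
#' @param seed Integer base seed.
#' @return A named list of `ecog_recording`s (`animal_1`, ...).
#' @export
simulate_cohort <- function(n_animals, protocol, config = generator_config(),
                            seed = 1L) {
  stopifnot(n_animals >= 1)
  recs <- lapply(seq_len(n_animals), function(i) {
    cfg <- config
    cfg$seed <- as.integer(seed + 1000 * (i - 1))
    simulate_recording(cfg, protocol, animal_id = paste0("animal_", i))
  })
  names(recs) <- vapply(recs, `[[`, "", "animal_id")
  recs
}

#' @export
print.ecog_recording <- function(x, ...) {
  cat(sprintf(
    "ECoG recording '%s': 2 channels x %d samples @ %g Hz (%.1f min), %d stimuli\n",
    x$animal_id, length(x$ch_contra), x$sample_rate,
    length(x$ch_contra) / x$sample_rate / 60, length(x$stim_onsets)))
  invisible(x)
}
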