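test_that("Welch PSD conserves power (Parseval) and localizes sinusoids", {
  fs <- 250
  set.seed(99)
  ints <- replicate(50, {
    p <- welch_psd(rnorm(2500), fs)
    sum(diff(p$freq) * (p$power[-1] + p$power[-length(p$power)]) / 2)
  })
  expect_lt(abs(mean(ints) - 1), 0.15)

  a <- 2
  x <- a * sin(2 * pi * 10 * (0:2499) / fs)
  p <- welch_psd(x, fs)
  expect_equal(p$freq[which.max(p$power)], 10)
  tot <- sum(diff(p$freq) * (p$power[-1] + p$power[-length(p$power)]) / 2)
  expect_equal(tot, a^2 / 2, tolerance = 0.02)

  p0 <- welch_psd(rep(0, 2500), fs)
  expect_true(all(p0$power == 0))
  expect_equal(p0$n_segments, 9)
  expect_error(welch_psd(rnorm(100), fs, segment_s = 2), "longer")
})

test_that("spectral edge frequency follows the cumulative power", {
  fs <- 250
  set.seed(1)
  sefs <- replicate(100, spectral_edge_frequency(welch_psd(rnorm(2500), fs)))
  expect_lt(abs(mean(sefs) - 0.95 * 125), 0.5)  # one 0.5 Hz bin

  pm <- welch_psd(sin(2 * pi * 10 * (0:2499) / fs), fs)
  expect_equal(spectral_edge_frequency(pm), 10, tolerance = 0.51)

  psd <- structure(list(freq = c(0, 5, 10, 15), power = c(0, 0, 3, 0),
                        n_segments = 9), class = "welch_psd")
  expect_equal(spectral_edge_frequency(psd), 10)
  expect_equal(spectral_edge_frequency(psd, fraction = 1), 10)
  zero <- structure(list(freq = 0:3, power = rep(0, 4), n_segments = 9),
                    class = "welch_psd")
  expect_true(is.na(spectral_edge_frequency(zero)))
})

test_that("aperiodic slope recovers exact power laws", {
  f <- seq(0, 125, by = 0.5)
  mk <- function(p) structure(list(freq = f, power = p, n_segments = 9),
                              class = "welch_psd")
  p2 <- ifelse(f > 0, f^-2, 0)
  expect_equal(aperiodic_slope(mk(p2)), -2, tolerance = 1e-9)
  expect_equal(aperiodic_slope(mk(rep(1, length(f)))), 0, tolerance = 1e-12)
  expect_true(is.na(aperiodic_slope(mk(rep(0, length(f))))))
})

test_that("band powers integrate the PSD over disjoint bands", {
  fs <- 250
  x <- sin(2 * pi * 10 * (0:2499) / fs)
  p <- welch_psd(x, fs)
  bp <- band_powers(p)
  expect_named(bp, c("delta", "theta", "alpha", "beta", "gamma"))
  tot <- sum(diff(p$freq) * (p$power[-1] + p$power[-length(p$power)]) / 2)
  expect_gt(bp[["alpha"]] / tot, 0.98)
  expect_lt(sum(bp[names(bp) != "alpha"]) / tot, 0.02)
  expect_true(all(band_powers(welch_psd(rep(0, 2500), fs)) == 0))
  set.seed(2)
  pr <- welch_psd(rnorm(2500), fs)
  bpr <- band_powers(pr)
  totr <- sum(diff(pr$freq) * (pr$power[-1] + pr$power[-length(pr$power)]) / 2)
  expect_lte(sum(bpr), totr + 1e-12)
})

test_that("coherence is exact for identical channels and ~1/K for independent ones", {
  fs <- 250
  set.seed(3)
  x <- rnorm(2500)
  expect_equal(interhemispheric_coherence(x, x, fs), 1, tolerance = 1e-9)
  # magnitude-squared coherence ignores a pure delay
  d <- 5
  expect_gt(interhemispheric_coherence(x[1:2400], x[(1 + d):(2400 + d)], fs),
            0.98)
  cohs <- replicate(100,
    interhemispheric_coherence(rnorm(2500), rnorm(2500), fs))
  expect_lt(abs(mean(cohs) - 1 / 9), 0.04)   # K = 9 Welch segments
  expect_true(all(cohs >= 0 & cohs <= 1))
  expect_error(interhemispheric_coherence(rnorm(100), rnorm(100), fs,
                                          segment_s = 0.4),
               "degenerate")
  expect_error(interhemispheric_coherence(rnorm(100), rnorm(200), fs),
               "equal length")
})

test_that("burst detection recovers a known amplitude gate", {
  fs <- 250
  set.seed(4)
  t <- (0:(60 * fs - 1)) / fs
  gate <- (t %% 2) < 1                       # 1 s on / 1 s off
  x <- rnorm(length(t)) * ifelse(gate, 1, 0.02)
  iv <- detect_bursts(x, fs)
  m <- burst_suppression_metrics(iv)
  expect_lt(abs(m$bsr - 0.5), 0.05)
  expect_lt(abs(m$mean_on_s - 1), 0.2)
  expect_lt(abs(m$mean_off_s - 1), 0.2)

  sine <- sin(2 * pi * 10 * t)
  ivs <- detect_bursts(sine, fs)
  expect_equal(burst_suppression_metrics(ivs)$bsr, 0)

  ivz <- detect_bursts(rep(0, 10 * fs), fs)
  expect_equal(burst_suppression_metrics(ivz)$bsr, 1)
})

test_that("burst intervals are contiguous, alternating, and metrics are exact", {
  rec <- fix_cohort()[[1]]
  blk <- segment_blocks(preprocess_recording(rec), 1)[[2]]  # 2.3 % block
  iv <- detect_bursts(blk$ch_contra, blk$sample_rate)
  expect_equal(iv$start_s[-1], iv$end_s[-nrow(iv)])
  expect_equal(iv$start_s[1], 0)
  expect_equal(iv$end_s[nrow(iv)],
               length(blk$ch_contra) / blk$sample_rate)
  if (nrow(iv) > 1) expect_true(all(iv$state[-1] != iv$state[-nrow(iv)]))

  manual <- structure(data.frame(start_s = c(0, 2, 8),
                                 end_s = c(2, 8, 10),
                                 state = c("on", "off", "on")),
                      class = c("burst_intervals", "data.frame"))
  m <- burst_suppression_metrics(manual)
  expect_equal(m$bsr, 0.6)
  expect_equal(m$mean_on_s, 2)
  expect_equal(m$mean_off_s, 6)
})

test_that("feature table has the expected shape and stable schema", {
  ft <- fix_features()
  # 3 animals x 7 blocks x 12 windows
  expect_equal(nrow(ft), 3 * 7 * 12)
  expect_true(all(table(ft$animal_id) == 84))
  per_animal <- split(ft, ft$animal_id)
  for (a in per_animal) expect_identical(names(a), names(per_animal[[1]]))
  expect_true(all(c("coherence_5_40", "sampen_contra", "lzc_ipsi",
                    "bsr_contra", "sef95_ipsi", "bp_gamma_contra")
                  %in% names(ft)))
  expect_true(all(ft$coherence_5_40 >= 0 & ft$coherence_5_40 <= 1))
  expect_true(all(ft$bsr_contra >= 0 & ft$bsr_contra <= 1))
  expect_false(any(is.na(ft$coherence_5_40)))
  bp_cols <- grep("^bp_", names(ft), value = TRUE)
  expect_true(all(as.matrix(ft[bp_cols]) >= 0))
  expect_true(all(ft$sampen_contra >= 0, na.rm = TRUE))
})

test_that("sample entropy of a shuffled suppressed signal exceeds the original", {
  fs <- 250
  wins <- 0
  for (s in 1:10) {
    set.seed(s)
    t <- (0:2499) / fs
    gate <- ifelse((t %% 2) < 1, 1, 0.05)
    x <- rnorm(2500) * gate
    orig <- sample_entropy(x, fs)
    shuf <- sample_entropy(sample(x), fs)
    wins <- wins + (shuf > orig)
  }
  expect_equal(wins, 10)
})

test_that("feature central values are monotone over a 5-level depth grid", {
  feats <- c("coherence_5_40", "bsr_contra", "sampen_contra", "lzc_contra")
  signs <- c(1, 1, -1, -1)
  concs <- c(1.0, 1.3, 1.6, 1.95, 2.3)
  rhos <- matrix(NA_real_, 3, length(feats),
                 dimnames = list(NULL, feats))
  for (i in 1:3) {
    fv <- do.call(rbind, lapply(concs, function(cc) {
      cfg <- generator_config(transition_tau_s = 0,
                              seed = 100 * i + round(10 * cc))
      rec <- simulate_recording(cfg, make_protocol(cc, 200 / 60))
      extract_feature_table(rec, discard_minutes = 0)
    }))
    m <- aggregate(fv[feats], list(conc = fv$conc_pct), mean, na.rm = TRUE)
    d <- depth_from_concentration(generator_config(), m$conc)
    rhos[i, ] <- vapply(feats, function(f)
      cor(m[[f]], d, method = "spearman"), numeric(1))
  }
  mean_rho <- colMeans(rhos)
  for (k in seq_along(feats)) {
    expect_gt(signs[k] * mean_rho[k], 0.8)
    expect_true(all(sign(rhos[, k]) == signs[k]))
  }
})
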