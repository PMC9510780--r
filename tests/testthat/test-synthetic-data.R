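test_that("protocol construction lays out segments in order", {
  p <- make_protocol(c(1.5, 2.3, 1.0, 1.5, 1.0, 2.3, 1.5), 15)
  expect_equal(nrow(p), 7)
  expect_equal(protocol_duration(p), 105 * 60)
  expect_equal(p$conc_pct, c(1.5, 2.3, 1.0, 1.5, 1.0, 2.3, 1.5))

  p1 <- make_protocol(1.0, 1)
  expect_equal(protocol_duration(p1), 60)
  p2 <- make_protocol(c(1.0, 2.3), 2)
  expect_equal(p2$start_s[2], 120)
  # boundary sample belongs to the later segment
  expect_equal(protocol_concentration_at(p2, c(0, 119.9, 120, 200)),
               c(1.0, 1.0, 2.3, 2.3))

  expect_error(make_protocol(numeric(0), 15), "nonempty")
  expect_error(make_protocol(c(1, 2), 0), "positive")
})

test_that("raised-cosine pulse has the printed duration and kinematics", {
  pulse <- raised_cosine_pulse(300, 120, 200000)
  expect_equal(max(pulse$t), 1 / 120, tolerance = 1e-9)  # 8.3 ms
  expect_equal(round(1000 * max(pulse$t), 1), 8.3)
  expect_lt(abs(pulse$x[1]), 1e-9)
  expect_lt(abs(pulse$x[length(pulse$x)]), 1e-6)
  expect_equal(max(pulse$x), 300, tolerance = 1e-6)
  # peak |velocity| = A*pi*f = 113.1 mm/s
  v <- diff(pulse$x) / diff(pulse$t) / 1000   # um/s -> mm/s
  expect_equal(max(abs(v)), 300 * pi * 120 / 1000, tolerance = 1e-3)
  expect_equal(round(max(abs(v)), 1), 113.1)

  z <- raised_cosine_pulse(0, 120, 10000)
  expect_true(all(z$x == 0))
  expect_error(raised_cosine_pulse(300, 120, 200), "sample_rate")
})

test_that("stimulus train places onsets only inside on-periods", {
  expect_equal(make_stimulus_train(8, 1, 2, 2), c(0, 1, 4, 5))
  expect_equal(make_stimulus_train(2, 1, 2, 2), c(0, 1))
  expect_equal(make_stimulus_train(0, 1, 2, 2), numeric(0))
  expect_error(make_stimulus_train(8, 1, 0.5, 2), "pulse interval")

  on <- make_stimulus_train(600, 1, 2, 2)
  phase <- on %% 4
  expect_true(all(phase < 2))              # never in an off-window
  expect_true(all(diff(on) > 0))
})

test_that("generator is deterministic and honors its seed", {
  proto <- make_protocol(c(1.0, 2.3), 0.5)
  cfg <- scaled_config(seed = 42)
  r1 <- simulate_recording(cfg, proto)
  r2 <- simulate_recording(cfg, proto)
  expect_identical(r1$ch_contra, r2$ch_contra)
  expect_identical(r1$ch_ipsi, r2$ch_ipsi)
  expect_identical(r1$ground_truth, r2$ground_truth)
  r3 <- simulate_recording(scaled_config(seed = 43), proto)
  expect_false(identical(r1$ch_contra, r3$ch_contra))
})

test_that("coherence rises with the shared-source mixing weight", {
  proto <- make_protocol(1.5, 2)
  coh_at <- function(rho, seed) {
    cfg <- generator_config(rho_lo = rho, rho_hi = rho,
                            transition_tau_s = 0,
                            burst_mean_off_s_per_depth = 0,
                            evoked_amplitude_uv = 0, seed = seed)
    rec <- simulate_recording(cfg, proto)
    ft <- extract_feature_table(rec, discard_minutes = 0)
    mean(ft$coherence_5_40)
  }
  lo <- vapply(1:10, function(s) coh_at(0.2, s), numeric(1))
  hi <- vapply(1:10, function(s) coh_at(0.7, s), numeric(1))
  expect_true(all(hi > lo))
  expect_lt(t.test(hi, lo, alternative = "greater")$p.value, 0.01)
})

test_that("independent channels (rho = 0) give near-zero coherence", {
  cfg <- generator_config(rho_lo = 0, rho_hi = 0, transition_tau_s = 0,
                          burst_mean_off_s_per_depth = 0,
                          evoked_amplitude_uv = 0, seed = 8)
  rec <- simulate_recording(cfg, make_protocol(1.5, 2))
  ft <- extract_feature_table(rec, discard_minutes = 0)
  # estimator floor for 9 Welch segments is ~1/9
  expect_lt(mean(ft$coherence_5_40), 0.2)
})

test_that("realized suppression fraction matches the renewal expectation", {
  proto <- make_protocol(2.3, 5)
  cfg0 <- generator_config(transition_tau_s = 0)
  d <- depth_from_concentration(cfg0, 2.3)
  mo <- cfg0$burst_mean_off_s_per_depth * d
  expected <- mo / (mo + cfg0$burst_mean_on_s)
  fracs <- vapply(1:10, function(s) {
    rec <- simulate_recording(generator_config(transition_tau_s = 0,
                                               seed = s), proto)
    mean(rec$ground_truth$suppressed)
  }, numeric(1))
  expect_lt(abs(mean(fracs) - expected), 3 * sd(fracs) / sqrt(10))
})

test_that("no suppression is generated when mean off-duration is zero", {
  cfg <- generator_config(burst_mean_off_s_per_depth = 0, seed = 3)
  rec <- simulate_recording(cfg, make_protocol(2.3, 1))
  expect_true(all(!rec$ground_truth$suppressed))
})

test_that("background PSD recovers the configured aperiodic exponent", {
  cfg <- generator_config(shared_rms_uv = 0, line_amplitude_uv = 0,
                          evoked_amplitude_uv = 0,
                          burst_mean_off_s_per_depth = 0,
                          transition_tau_s = 0, aperiodic_exponent = 2,
                          seed = 5)
  rec <- simulate_recording(cfg, make_protocol(1.5, 1000 / 60))
  ft <- extract_feature_table(rec, discard_minutes = 0, preprocess = FALSE)
  expect_gte(nrow(ft), 100)
  expect_lt(abs(mean(ft$slope_20_40_contra) - (-2)), 0.3)
  expect_lt(abs(mean(ft$slope_20_40_ipsi) - (-2)), 0.3)
})

test_that("depth map is a clipped linear ramp of concentration", {
  cfg <- generator_config()
  expect_equal(depth_from_concentration(cfg, 0.8), 0)
  expect_equal(depth_from_concentration(cfg, 2.5), 1)
  expect_equal(depth_from_concentration(cfg, 0.5), 0)
  expect_equal(depth_from_concentration(cfg, 3.0), 1)
  d <- depth_from_concentration(cfg, c(1.0, 1.5, 2.3))
  expect_true(all(diff(d) > 0))
  expect_equal(d[2], (1.5 - 0.8) / (2.5 - 0.8))
})

test_that("config validation rejects inconsistent settings", {
  expect_error(generator_config(rho_lo = 0.9, rho_hi = 0.2), "nondecreasing")
  expect_error(generator_config(rho_hi = 1), "\\[0, 1\\)")
  expect_error(generator_config(sample_rate = 80), "twice")
  expect_error(generator_config(depth_c_hi = 0.5), "exceed")
})
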