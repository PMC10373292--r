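test_that("analytic APD truths are exact for a triangular AP", {
  # colinear crossing targets degenerate the decay to one straight line
  s <- synth_ap_trace(upstroke_ms = 1e-9, apd30_ms = 60, apd90_ms = 180,
                      beat_period_ms = 1000, n_beats = 2)
  expect_equal(s$apd_fn(0.30), 60)
  expect_equal(s$apd_fn(0.90), 180)
  expect_equal(s$apd_fn(0.30) / s$apd_fn(0.90), 1 / 3)
  # arbitrary fraction on the same line: level 1 - f at 1 - 0.3*(t/60)
  expect_equal(s$apd_fn(0.45), 90)
})

test_that("beats are spaced at exactly the requested period", {
  s <- synth_ap_trace(beat_period_ms = 1000, n_beats = 5)
  expect_equal(nrow(s$truth), 5L)
  expect_equal(diff(s$truth$activation_ms), rep(1000, 4))
  expect_equal(s$truth$beat_period_ms[1:4], rep(1000, 4))
  expect_true(is.na(s$truth$beat_period_ms[5L]))
})

test_that("inconsistent AP shapes are rejected", {
  expect_error(synth_ap_trace(apd30_ms = 300, apd90_ms = 250), "apd30")
  expect_error(synth_ap_trace(apd90_ms = 950, beat_period_ms = 1000),
               "fit inside")
  expect_error(synth_ap_trace(amplitude = 0), "amplitude")
})

test_that("trace generation is seed-deterministic", {
  a <- synth_ap_trace(noise_sd = 0.05, seed = 7)
  b <- synth_ap_trace(noise_sd = 0.05, seed = 7)
  expect_identical(a$value, b$value)
})

test_that("plane-wave electrograms carry the kinematic activation delays", {
  act <- plane_wave_activation(n_rows = 4, n_cols = 4, pitch_mm = 1,
                               velocity_cm_s = 40, angle_deg = 0)
  # 1 mm at 40 cm/s = 0.4 mm/ms -> 2.5 ms per electrode column
  row1 <- act[act$row == 1, ]
  expect_equal(diff(row1$t_ms[order(row1$col)]), rep(2.5, 3))
  es <- synth_electrograms(act)
  expect_s3_class(es, "electrogram_set")
  expect_equal(ncol(es$traces), 16L)
  fp <- fp_features(es)
  m <- merge(fp[fp$beat == 1, ], act, by = "electrode")
  expect_lt(max(abs((m$spike_time_ms - m$t_ms) -
                      mean(m$spike_time_ms - m$t_ms))), 1)
})

test_that("electrodes with no activation are emitted flat and flagged", {
  act <- plane_wave_activation(n_rows = 2, n_cols = 2)
  act$t_ms[4L] <- NA
  es <- synth_electrograms(act)
  expect_equal(sum(es$quality == "flat"), 1L)
  flat <- which(es$quality == "flat")
  expect_true(all(es$traces[, flat] == 0))
})

test_that("spike amplitude is linear in the upstroke-slope gain", {
  act <- plane_wave_activation(n_rows = 2, n_cols = 2)
  e1 <- synth_electrograms(act, spike_amp_uv = 500)
  e2 <- synth_electrograms(act, spike_amp_uv = 1000)
  expect_equal(max(e2$traces[, 1L]) / max(e1$traces[, 1L]), 2,
               tolerance = 1e-9)
})
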