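test_that("spike detection recovers plane-wave activation delays", {
  act <- plane_wave_activation(velocity_cm_s = 40)
  es <- synth_electrograms(act)
  fp <- fp_features(es)
  expect_equal(length(unique(fp$electrode)), 16L)
  m <- merge(fp[fp$beat == 1, ], act, by = "electrode")
  offs <- m$spike_time_ms - m$t_ms
  expect_lt(max(abs(offs - mean(offs))), 1)    # within one sample
})

test_that("flat traces yield no spikes and an explicit flag", {
  out <- detect_spikes(rep(0, 1000), seq(0, by = 1, length.out = 1000))
  expect_equal(nrow(out), 0L)
  expect_equal(attr(out, "flag"), "no_spikes")
})

test_that("spike amplitude scales with the forward-model gain", {
  act <- plane_wave_activation(n_rows = 2, n_cols = 2)
  f1 <- fp_features(synth_electrograms(act, spike_amp_uv = 400))
  f2 <- fp_features(synth_electrograms(act, spike_amp_uv = 800))
  expect_equal(f2$amplitude_uv / f1$amplitude_uv, rep(2, nrow(f1)),
               tolerance = 1e-6)
})

test_that("FPD finds the repolarization deflection regardless of polarity", {
  tt <- seq(0, 1000, by = 1)
  spike <- -1000 * (tt - 100) / 2 * exp(0.5 - (tt - 100)^2 / 8)
  twave <- 100 * exp(-(tt - 290)^2 / (2 * 15^2))
  up <- measure_fpd(spike + twave, tt, 100, Inf)
  dn <- measure_fpd(spike - twave, tt, 100, Inf)
  expect_equal(up$fpd_ms, 190, tolerance = 1)
  expect_equal(dn$fpd_ms, up$fpd_ms, tolerance = 1e-6)
  # T-wave below the noise floor: flagged missing
  tiny <- measure_fpd(spike + 0.01 * twave, tt, 100, Inf,
                      noise_floor_uv = 10)
  expect_true(is.na(tiny$fpd_ms))
  expect_equal(tiny$quality, "no_t_wave")
})

test_that("Fridericia correction is exact closed form", {
  expect_identical(fridericia(300, 1000), 300)
  expect_equal(fridericia(270, 729), 300, tolerance = 1e-12)
  expect_equal(fridericia(300, 8000), 150, tolerance = 1e-12)
  expect_error(fridericia(-1, 1000), "positive")
  expect_error(fridericia(300, 0), "positive")
  # invariance when fpd and the cube root of the period scale together
  expect_equal(fridericia(300 * 2, 1000 * 8), fridericia(300, 1000))
})

test_that("conduction velocity is recovered from a noiseless plane fit", {
  act <- plane_wave_activation(velocity_cm_s = 40)
  cv <- conduction_velocity(act)
  expect_equal(cv$velocity_cm_s, 40, tolerance = 0.5)
  expect_lt(cv$residual_rms_ms, 1e-9)
  expect_equal(cv$n_electrodes, 16L)
  expect_equal(as.numeric(cv$direction), c(1, 0), tolerance = 1e-9)
})

test_that("degenerate electrode geometries are flagged", {
  col <- data.frame(x_mm = 1:5, y_mm = 2 * (1:5) + 1, t_ms = 1:5)
  expect_error(conduction_velocity(col), "collinear")
  flat <- plane_wave_activation(); flat$t_ms <- 10
  out <- conduction_velocity(flat)
  expect_equal(out$quality, "unresolvable")
  expect_true(is.na(out$velocity_cm_s))
})

test_that("vehicle-adjusted drug deltas obey the ratio contract", {
  base <- data.frame(electrode = sprintf("e%d", 1:6),
                     beat_period_ms = 600, fpdc_ms = 250)
  # null effect: all deltas 1
  d0 <- paired_drug_delta(base, base, base, base)
  expect_true(all(abs(d0$by_electrode$ratio_delta - 1) < 1e-12))
  # halved beat period, vehicle unchanged
  post <- base; post$beat_period_ms <- 300
  d1 <- paired_drug_delta(base, post, base, base)
  expect_equal(d1$summary$median_ratio_delta[
    d1$summary$metric == "beat_period_ms"], 0.5)
  # shared drift cancels through the vehicle
  drift <- base; drift[, -1] <- base[, -1] * 1.1
  d2 <- paired_drug_delta(base, drift, base, drift)
  expect_true(all(abs(d2$by_electrode$ratio_delta - 1) < 1e-12))
  # unmatched electrodes are reported
  bad <- base; bad$electrode[1] <- "zz"
  expect_error(paired_drug_delta(base, bad, base, base), "unmatched")
})
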