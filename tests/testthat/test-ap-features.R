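test_that("beat detection recovers generator activations and spacing", {
  s <- synth_ap_trace(beat_period_ms = 1000, n_beats = 5)
  acts <- detect_beats(s$value, s$time_ms)
  expect_length(acts, 5L)
  expect_true(all(abs(diff(acts) - 1000) <= 5))
  expect_true(all(abs(acts - s$truth$activation_ms) <= 5))
})

test_that("a flat trace yields no beats, with a flag rather than an error", {
  out <- detect_beats(rep(2, 400), seq(0, by = 5, length.out = 400))
  expect_length(out, 0L)
  expect_equal(attr(out, "flag"), "no_beats")
})

test_that("events closer than the refractory bound merge to the larger one", {
  # two interleaved generators 400 ms apart; the second has half amplitude
  t1 <- synth_ap_trace(apd30_ms = 60, apd90_ms = 150,
                       beat_period_ms = 800, n_beats = 3, pre_ms = 200)
  t2 <- synth_ap_trace(amplitude = 0.5, apd30_ms = 60, apd90_ms = 150,
                       beat_period_ms = 800, n_beats = 3, pre_ms = 600)
  n <- min(length(t1$value), length(t2$value))
  x <- t1$value[1:n] + t2$value[1:n]
  acts <- detect_beats(x, t1$time_ms[1:n], min_period_ms = 500)
  expect_length(acts, 3L)
  expect_true(all(abs(acts - t1$truth$activation_ms) <= 5))
})

test_that("APD of a triangular AP matches the linear geometry", {
  # instantaneous upstroke, linear repolarization over D = 200 ms;
  # pre_ms places the jump midway between samples so the discrete
  # max-derivative activation coincides with the analytic one
  s <- synth_ap_trace(upstroke_ms = 1e-9, apd30_ms = 60, apd90_ms = 180,
                      beat_period_ms = 1000, n_beats = 3, pre_ms = 197.5)
  tf <- trace_features(s$value, s$time_ms)
  expect_true(all(abs(tf$apd30_ms - 60) <= 2.5))
  expect_true(all(abs(tf$apd90_ms - 180) <= 2.5))
  expect_true(all(abs(tf$apd_ratio - 1 / 3) < 0.03))
})

test_that("a square pulse has equal APDs at every fraction and ratio one", {
  tt <- seq(0, 3000, by = 5)
  x <- as.numeric((tt %% 1000) >= 100 & (tt %% 1000) < 350)  # width 250
  a30 <- compute_apd(x, tt, 100, 0.30, next_activation_ms = 1100)
  a90 <- compute_apd(x, tt, 100, 0.90, next_activation_ms = 1100)
  expect_equal(a30$apd_ms, a90$apd_ms, tolerance = 0.05)
  expect_equal(a30$apd_ms, 250, tolerance = 5)
})

test_that("beats with no crossing before the next activation are flagged", {
  tt <- seq(0, 900, by = 5)
  x <- ifelse(tt >= 100, 1, 0)       # never repolarizes
  out <- compute_apd(x, tt, 100, 0.9, next_activation_ms = 800)
  expect_true(is.na(out$apd_ms))
  expect_equal(out$quality, "no_crossing")
})

test_that("beat periods are successive activation differences", {
  expect_equal(beat_period(c(0, 640, 1280)), c(640, 640))
  out <- beat_period(123)
  expect_length(out, 0L)
  expect_equal(attr(out, "flag"), "too_few_beats")
  set.seed(6)
  jit <- cumsum(1000 + runif(20, -50, 50))
  expect_true(abs(mean(beat_period(jit)) - 1000) < 50)
})

test_that("features are invariant under declared polarity inversion", {
  s <- synth_ap_trace(apd30_ms = 120, apd90_ms = 260, noise_sd = 0.02,
                      beat_period_ms = 1000, n_beats = 4, seed = 8)
  up <- trace_features(s$value, s$time_ms)
  dn <- trace_features(-s$value, s$time_ms, polarity = -1)
  expect_equal(up$apd30_ms, dn$apd30_ms, tolerance = 1e-9)
  expect_equal(up$apd90_ms, dn$apd90_ms, tolerance = 1e-9)
  expect_equal(up$activation_ms, dn$activation_ms, tolerance = 1e-9)
})

test_that("APD is monotone in the repolarization fraction for random shapes", {
  set.seed(9)
  for (i in 1:15) {
    a90 <- runif(1, 140, 380)
    a30 <- runif(1, 0.35, 0.6) * a90
    s <- synth_ap_trace(apd30_ms = a30, apd90_ms = a90, upstroke_ms = 15,
                        beat_period_ms = 1000, n_beats = 3,
                        noise_sd = runif(1, 0, 0.05), seed = i)
    tf <- trace_features(s$value, s$time_ms,
                         fractions = c(0.2, 0.3, 0.5, 0.7, 0.9))
    apd_cols <- c("apd20_ms", "apd30_ms", "apd50_ms", "apd70_ms",
                  "apd90_ms")
    for (b in seq_len(nrow(tf)))
      expect_true(all(diff(as.numeric(tf[b, apd_cols])) >= 0))
  }
})

test_that("trace summaries exclude flagged beats and carry identifiers", {
  s <- synth_ap_trace(apd30_ms = 100, apd90_ms = 220,
                      beat_period_ms = 900, n_beats = 4)
  tf <- trace_features(s$value, s$time_ms)
  row <- summarize_trace(tf, id = list(line = "L1", protocol = "spont",
                                       N = 2L, n = 5L))
  expect_equal(row$n_beats, 4L)
  expect_equal(row$line, "L1")
  expect_equal(row$apd90_ms_mean, mean(tf$apd90_ms), tolerance = 1e-9)
  # flag one beat: summaries use the remaining ones
  tf2 <- tf; tf2$quality[2L] <- "flagged"; tf2$apd90_ms[2L] <- 1e6
  row2 <- summarize_trace(tf2, id = list(protocol = "x", N = 1, n = 1))
  expect_equal(row2$n_flagged, 1L)
  expect_lt(row2$apd90_ms_mean, 1000)
})
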