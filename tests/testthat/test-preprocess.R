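mk_movie <- function(mat_t, H = 1L, W = 1L, dt = 5) {
  # mat_t: vector (single pixel) or T x P matrix laid out into H x W
  if (is.null(dim(mat_t))) mat_t <- matrix(mat_t, ncol = 1L)
  arr <- array(mat_t, c(nrow(mat_t), H, W))
  fluor_movie(arr, dt)
}

test_that("sliding-window normalization maps ranges to [0,1] and guards zero range", {
  cst <- mk_movie(rep(7, 50))
  out <- sliding_window_normalize(cst, 10)
  expect_true(all(out$frames == 0))
  sq <- mk_movie(rep(c(10, 20), 50))
  nn <- sliding_window_normalize(sq, 10)
  expect_setequal(unique(as.vector(nn$frames)), c(0, 1))
  # brute-force windowed min-max oracle on a rough random trace
  set.seed(1)
  x <- cumsum(rnorm(80))
  mm <- oracle_window_minmax(x, 21)
  expected <- ifelse(mm[, 2] > mm[, 1], (x - mm[, 1]) / (mm[, 2] - mm[, 1]), 0)
  got <- sliding_window_normalize(mk_movie(x), 21)$frames[, 1, 1]
  expect_equal(got, expected, tolerance = 1e-12)
})

test_that("sliding-window normalization is invariant to per-pixel affine maps", {
  set.seed(2)
  x <- sin(seq(0, 20, length.out = 120)) + rnorm(120, sd = 0.1)
  a <- sliding_window_normalize(mk_movie(x), 30)$frames
  b <- sliding_window_normalize(mk_movie(3.7 * x + 11), 30)$frames
  expect_equal(a, b, tolerance = 1e-10)
  expect_error(sliding_window_normalize(mk_movie(x), 200), "exceeds")
})

test_that("masked Gaussian smoothing preserves constants and mass", {
  arr <- array(3.3, c(2, 20, 20))
  mask <- matrix(TRUE, 20, 20); mask[1:4, 1:6] <- FALSE
  mv <- fluor_movie(arr, 5, mask = mask)
  sm <- spatial_gaussian(mv, 1.5)
  expect_equal(sm$frames[1, , ][mask], rep(3.3, sum(mask)),
               tolerance = 1e-9)
  # identity at sigma 0
  expect_identical(spatial_gaussian(mv, 0)$frames, arr)
  # single interior bright pixel: blur is mass-preserving
  arr2 <- array(0, c(2, 31, 31)); arr2[, 16, 16] <- 1
  sm2 <- spatial_gaussian(fluor_movie(arr2, 5), 2)
  expect_equal(sum(sm2$frames[1, , ]), 1, tolerance = 1e-6)
})

test_that("zero-phase band-pass preserves in-band tones and removes drift", {
  fs <- 200
  tt <- seq(0, 10, by = 1 / fs)
  tone <- sin(2 * pi * 10 * tt)
  y <- bandpass(tone, filter_spec(taper = "none"), fs = fs)
  mid <- 400:1600
  expect_lt(abs(max(abs(y[mid])) - 1), 0.02)
  cc <- stats::ccf(y[mid], tone[mid], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  drift <- sin(2 * pi * 0.1 * tt)
  yd <- bandpass(drift, filter_spec(taper = "none"), fs = fs)
  expect_gt(1 - max(abs(yd[mid])), 0.95)
  expect_equal(bandpass(rep(0, 500), fs = fs), rep(0, 500))
  expect_error(bandpass(tone, filter_spec(band_high_hz = 120), fs = fs),
               "Nyquist")
})

test_that("band-passing a movie flags filter edge frames as untrusted", {
  set.seed(3)
  arr <- array(rnorm(1000 * 4), c(1000, 2, 2))
  mv <- bandpass(fluor_movie(arr, 5), filter_spec())
  # 2 periods of the 1 Hz low cut at 200 Hz sampling = 400 frames per end
  expect_true(all(c(1:400, 601:1000) %in% mv$untrusted_frames))
  expect_false(500 %in% mv$untrusted_frames)
  expect_match(tail(mv$provenance, 1), "bandpass")
})

test_that("truncated Fourier re-synthesis keeps the dominant components", {
  fs <- 200; tt <- seq(0, 5 - 1 / fs, by = 1 / fs)
  x <- 2 * sin(2 * pi * 4 * tt) + sin(2 * pi * 9 * tt)
  rec <- smooth_recompose(x, fs, k = 2)
  expect_lt(sum((rec - x)^2) / sum(x^2), 1e-8)
  # white noise, k = 1: the result is the single largest-magnitude bin
  set.seed(4)
  n <- rnorm(1000)
  r1 <- smooth_recompose(n, fs, k = 1)
  sp <- Mod(stats::fft(n))[1:501]
  f_dom <- (which.max(sp) - 1) / 1000 * fs
  spr <- Mod(stats::fft(r1))[1:501]
  expect_equal((which.max(spr) - 1) / 1000 * fs, f_dom)
  # full spectrum: identity
  rid <- smooth_recompose(n, fs, k = 501)
  expect_equal(as.numeric(rid), n, tolerance = 1e-9)
  expect_error(smooth_recompose(n, fs, k = 0), "positive")
})

test_that("ROI traces average unmasked pixels only", {
  arr <- array(0, c(3, 4, 4))
  arr[, 1, 1] <- c(1, 2, 3); arr[, 1, 2] <- c(3, 4, 5)
  mask <- matrix(TRUE, 4, 4); mask[1, 2] <- FALSE
  mv <- fluor_movie(arr, 5, mask = mask)
  single <- extract_trace(mv, list(row = 1, col = 1, height = 1, width = 1))
  expect_equal(single$value, c(1, 2, 3))
  # rectangle covering both pixels: masked one is excluded
  both <- extract_trace(mv, list(row = 1, col = 1, height = 1, width = 2))
  expect_equal(both$value, c(1, 2, 3))
  mv2 <- fluor_movie(arr, 5)
  both2 <- extract_trace(mv2, list(row = 1, col = 1, height = 1, width = 2))
  expect_equal(both2$value, c(2, 3, 4))
  expect_error(extract_trace(mv, list(row = 1, col = 2, height = 1,
                                      width = 1)), "mask")
})

test_that("the conditioning chain is deterministic and records provenance", {
  set.seed(5)
  arr <- array(rnorm(150 * 36, mean = 100, sd = 5), c(150, 6, 6))
  mv <- fluor_movie(arr, 5)
  spec <- filter_spec(norm_window_frames = 50)
  p1 <- preprocess_movie(mv, spec)
  p2 <- preprocess_movie(mv, spec)
  expect_identical(p1$frames, p2$frames)
  expect_equal(sum(grepl("sliding_window_normalize", p1$provenance)), 1L)
  expect_equal(sum(grepl("spatial_gaussian", p1$provenance)), 1L)
  expect_equal(sum(grepl("bandpass", p1$provenance)), 1L)
})
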