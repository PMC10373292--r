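mk_det <- function(frame, row, col, chirality = 1L) {
  data.frame(frame = frame, row = row, col = col,
             chirality = as.integer(chirality))
}

test_that("a stationary singularity forms one track with full lifetime", {
  det <- mk_det(1:20, rep(10, 20), rep(12, 20))
  tr <- track_singularities(det, frame_interval_ms = 5)
  ts <- track_summary(tr)
  expect_equal(nrow(ts), 1L)
  expect_equal(ts$lifetime_ms, 19 * 5)
  expect_equal(ts$n_detections, 20L)
})

test_that("displacements beyond the link bound start a new track", {
  det <- mk_det(1:10, c(rep(10, 5), rep(50, 5)), rep(10, 10))
  tr <- track_singularities(det, max_link_px = 10, frame_interval_ms = 5)
  expect_equal(nrow(track_summary(tr)), 2L)
})

test_that("tracks never adopt detections of the opposite chirality", {
  # two singularities crossing paths with opposite chirality
  f <- 1:11
  det <- rbind(mk_det(f, 10 + f, 20, +1L),
               mk_det(f, 22 - f, 20, -1L))
  tr <- track_singularities(det, max_link_px = 10, frame_interval_ms = 5)
  ts <- track_summary(tr)
  expect_equal(nrow(ts), 2L)
  for (id in ts$track_id) {
    chir <- tr$chirality[tr$track_id == id]
    expect_length(unique(chir), 1L)
  }
})

test_that("gaps up to the bound are bridged, longer gaps split tracks", {
  det <- mk_det(c(1:5, 8:12), rep(7, 10), rep(7, 10))
  tr <- track_singularities(det, max_gap_frames = 2L,
                            frame_interval_ms = 5)
  expect_equal(nrow(track_summary(tr)), 1L)
  tr2 <- track_singularities(det, max_gap_frames = 1L,
                             frame_interval_ms = 5)
  expect_equal(nrow(track_summary(tr2)), 2L)
})

test_that("rotor summaries aggregate lifetimes with sample statistics", {
  det <- rbind(mk_det(1:201, rep(10, 201), rep(10, 201), +1L),
               mk_det(1:401, rep(40, 401), rep(40, 401), -1L))
  tr <- track_singularities(det, frame_interval_ms = 5)
  rep <- rotor_report(tr, n_frames_analyzed = 401L)
  expect_equal(rep$track_count, 2L)
  expect_equal(rep$singularity_lifetime_mean_ms, mean(c(1000, 2000)))
  expect_equal(rep$singularity_lifetime_sd_ms, stats::sd(c(1000, 2000)),
               tolerance = 1e-9)
  expect_equal(rep$singularity_lifetime_sd_ms, 707.1, tolerance = 1e-3)
  expect_equal(rep$dominant_track_fraction, 1)
  empty <- rotor_report(track_singularities(mk_det(integer(), numeric(),
                                                   numeric(), integer())))
  expect_equal(empty$total_detections, 0L)
  expect_equal(empty$track_count, 0L)
})

test_that("a traversing plane wave yields one wavefront of kinematic lifetime", {
  # phase plane wave: activation isophase sweeps across 64 columns at
  # 2 px/frame
  H <- 48; W <- 64; Tn <- 60; v <- 2
  arr <- array(0, c(Tn, H, W))
  cc <- matrix(seq_len(W), H, W, byrow = TRUE)
  for (t in seq_len(Tn))
    arr[t, , ] <- atan2(sin(0.5 + 0.22 * (v * t - cc)),
                        cos(0.5 + 0.22 * (v * t - cc)))
  pm <- structure(list(phase = arr, mask = matrix(TRUE, H, W),
                       frame_interval_ms = 5,
                       untrusted_frames = integer()),
                  class = "phase_movie")
  wf <- extract_wavefronts(pm, min_size = 5)
  per_frame <- table(wf$fronts$frame)
  expect_true(stats::median(per_frame) <= 2)
  main <- wf$tracks[which.max(wf$tracks$lifetime_ms), ]
  # a front needs ~ W/v frames to cross and leave the field; the wrapped
  # phase re-enters periodically, so check the dominant track only
  expect_gt(main$lifetime_ms / 5, 10)
})

test_that("an inactive phase movie contains no wavefronts", {
  arr <- array(0.1, c(10, 24, 24))
  pm <- structure(list(phase = arr, mask = matrix(TRUE, 24, 24),
                       frame_interval_ms = 5,
                       untrusted_frames = integer()),
                  class = "phase_movie")
  wf <- extract_wavefronts(pm)
  expect_equal(nrow(wf$fronts), 0L)
  expect_equal(nrow(wf$tracks), 0L)
})
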