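test_that("Hilbert phase advances at the oscillation frequency", {
  fs <- 200; f <- 2
  tt <- seq(0, 10 - 1 / fs, by = 1 / fs)
  arr <- array(0, c(length(tt), 1, 2))
  arr[, 1, 1] <- sin(2 * pi * f * tt)
  arr[, 1, 2] <- sin(2 * pi * f * (tt - 1 / (4 * f)))  # quarter-period lag
  pm <- instantaneous_phase(fluor_movie(arr, 5))
  expect_true(all(pm$phase > -pi & pm$phase <= pi))
  mid <- 300:1700
  unwrapped <- cumsum(c(pm$phase[mid[1], 1, 1],
                        atan2(sin(diff(pm$phase[mid, 1, 1])), cos(diff(pm$phase[mid, 1, 1])))))
  slope <- stats::coef(stats::lm(unwrapped ~ tt[mid]))[2L]
  expect_lt(abs(slope - 2 * pi * f) / (2 * pi * f), 0.01)
  dphi <- atan2(sin(pm$phase[mid, 1, 1] - pm$phase[mid, 1, 2]), cos(pm$phase[mid, 1, 1] - pm$phase[mid, 1, 2]))
  expect_lt(max(abs(dphi - pi / 2)), 0.05)
})

test_that("all-zero pixels are masked out with sentinel phase", {
  arr <- array(0, c(100, 2, 2))
  arr[, 1, 1] <- sin(seq_len(100) / 5)
  pm <- instantaneous_phase(fluor_movie(arr, 5))
  expect_false(pm$mask[2, 2])
  expect_true(all(is.na(pm$phase[, 2, 2])))
  expect_true(pm$mask[1, 1])
})

test_that("a single planted vortex is localized with the correct winding", {
  ph <- make_vortex_field(64, 64,
                          data.frame(row = 32.5, col = 32.5, charge = 1L))
  det <- detect_singularities(ph)
  expect_equal(nrow(det), 1L)
  expect_lt(sqrt((det$row - 32.5)^2 + (det$col - 32.5)^2), 1)
  expect_equal(det$chirality, 1L)
  expect_lt(abs(abs(det$inner_sum) - 2 * pi), 0.1)
  expect_lt(abs(abs(det$outer_sum) - 2 * pi), 0.1)
})

test_that("a planar phase ramp contains no singularities", {
  ph <- make_vortex_field(64, 64, data.frame(row = numeric(),
                                             col = numeric(),
                                             charge = integer()),
                          ramp = 0.2)
  expect_equal(nrow(detect_singularities(ph)), 0L)
})

test_that("a vortex-antivortex pair is resolved with opposite chiralities", {
  ph <- make_vortex_field(64, 64,
                          data.frame(row = c(32.5, 32.5),
                                     col = c(22.5, 42.5),
                                     charge = c(1L, -1L)))
  det <- detect_singularities(ph)
  expect_equal(nrow(det), 2L)
  expect_setequal(det$chirality, c(-1L, 1L))
  det <- det[order(det$col), ]
  expect_lt(abs(det$col[1] - 22.5), 1.5)
  expect_lt(abs(det$col[2] - 42.5), 1.5)
})

test_that("candidates whose rings leave the mask are skipped", {
  ph <- make_vortex_field(32, 32,
                          data.frame(row = 16.5, col = 16.5, charge = 1L))
  mask <- matrix(TRUE, 32, 32)
  mask[10:23, 10:23] <- FALSE       # mask out the core region
  expect_equal(nrow(detect_singularities(ph, mask)), 0L)
  # vortex too close to the border: outer ring exits the image
  ph2 <- make_vortex_field(32, 32,
                           data.frame(row = 2.5, col = 2.5, charge = 1L))
  det2 <- detect_singularities(ph2)
  expect_equal(nrow(det2), 0L)
})

test_that("detector equals the plaquette winding oracle on random fields", {
  set.seed(10)
  for (i in 1:8) {
    vort <- random_vortices(sample(0:3, 1), 64, 64)
    ph <- make_vortex_field(64, 64, vort, ramp = runif(1, 0, 0.1))
    truth <- oracle_plaquette_charges(ph)
    det <- detect_singularities(ph)
    # compare away from borders where rings cannot be evaluated
    inside <- truth[truth$row > 5 & truth$row < 60 &
                      truth$col > 5 & truth$col < 60, ]
    expect_equal(nrow(det), nrow(inside))
    if (nrow(inside) > 0) {
      for (j in seq_len(nrow(inside))) {
        d <- sqrt((det$row - inside$row[j])^2 +
                    (det$col - inside$col[j])^2)
        expect_lt(min(d), 1)
        expect_equal(det$chirality[which.min(d)],
                     as.integer(inside$charge[j]))
      }
    }
  }
})
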