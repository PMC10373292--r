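test_that("parameter and protocol validation enforce physical bounds", {
  expect_error(medium_params(grid_height = 8), "at least 16")
  expect_error(medium_params(dt_sim = 2, dx = 0.5, diffusion = 0.1),
               "stability bound")
  expect_error(medium_params(kinetics = list(k = 8, a = 0.7, eps0 = 0.002,
                                             mu1 = 0.2, mu2 = 0.3)),
               "'a'")
  expect_error(stimulus_protocol("point_burst", period_ms = -1, count = 10),
               "period_ms")
  p <- medium_params(grid_height = 32, grid_width = 32)
  bad <- stimulus_protocol("planar_s1",
                           region = list(row = 30, col = 1, height = 10,
                                         width = 3))
  expect_error(simulate_medium(p, bad, 100), "outside the grid")
})

test_that("planar wave has no tips and activation increases along propagation", {
  p <- medium_params(grid_height = 48, grid_width = 48)
  sim <- simulate_medium(p, stimulus_protocol("planar_s1"), 500)
  expect_equal(nrow(sim$ground_truth$tip_trajectory), 0L)
  at <- sim$ground_truth$activation_times[[1L]]
  mid <- at[24, ]
  expect_true(all(is.finite(mid)))
  expect_true(all(diff(mid[4:45]) > 0))   # strictly increasing along x
  expect_true(sim$ground_truth$plane_velocity_cm_s > 5)
  expect_true(all(sim$u >= 0 & sim$u <= 1))
})

test_that("identical parameters and seed give bit-identical voltage stacks", {
  p <- medium_params(grid_height = 32, grid_width = 32, seed = 11)
  s1 <- simulate_medium(p, stimulus_protocol("planar_s1"), 300,
                        compute_tips = FALSE)
  s2 <- simulate_medium(p, stimulus_protocol("planar_s1"), 300,
                        compute_tips = FALSE)
  expect_identical(s1$u, s2$u)
})

test_that("plane-wave speed scales as the square root of diffusion", {
  cv <- vapply(c(0.1, 0.2), function(D) {
    p <- medium_params(grid_height = 24, grid_width = 96, dx = 0.6,
                       dt_sim = 0.2, diffusion = D)
    sim <- simulate_medium(p, stimulus_protocol("planar_s1"), 700,
                           compute_tips = FALSE)
    sim$ground_truth$plane_velocity_cm_s
  }, 0)
  expect_lt(abs(cv[2L] / cv[1L] - sqrt(2)) / sqrt(2), 0.10)
})

test_that("cross-field stimulation sustains a spiral seen by the tip oracle", {
  p <- medium_params()
  sim <- simulate_medium(p, stimulus_protocol("cross_field_s2",
                                              onset_ms = 650), 3000)
  tips <- sim$ground_truth$tip_trajectory
  expect_gt(nrow(tips), 0L)
  expect_true(all(tips$chirality %in% c(-1L, 1L)))
  # at least one tip in every frame from shortly after S2 to the end:
  # more than two full rotations of sustained reentry
  frames_with_tip <- unique(tips$frame)
  post <- seq(ceiling(900 / 5), dim(sim$u)[1L])
  expect_gt(mean(post %in% frames_with_tip), 0.95)
  expect_gt(max(tips$time_ms) - min(tips$time_ms), 2000)
})

test_that("the tip oracle reports a vanishing net charge for a vortex pair field", {
  # two counter-rotating contours crossing: build u fields directly from
  # two successive rotating patterns around two cores
  H <- 64
  rr <- matrix(seq_len(H), H, H); cc <- t(rr)
  mk <- function(ang) {
    a1 <- atan2(rr - 20, cc - 32) - ang
    a2 <- -(atan2(rr - 44, cc - 32)) - ang
    0.5 + 0.25 * cos(a1) + 0.25 * cos(a2)
  }
  u <- array(0, c(3, H, H))
  for (i in 1:3) u[i, , ] <- mk(0.3 * i)
  tips <- find_tips_isopotential(u)
  expect_gt(nrow(tips), 0L)
  expect_equal(sum(tips$chirality[tips$frame == 2]), 0L)
})
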