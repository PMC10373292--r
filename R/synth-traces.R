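#' Analytic action-potential trace with closed-form APD truth
#'
#' Builds a piecewise-analytic action potential whose repolarization passes
#' exactly through the requested APD30 and APD90 crossing times, so the
#' true duration at any repolarization fraction is available in closed
#' form. One beat is: baseline, a raised-cosine upstroke of `upstroke_ms`
#' (maximal dF/dt exactly at the upstroke midpoint, which is therefore the
#' analytic activation time), then a slowly declining plateau down to
#' `plateau_level`, and finally one straight rapid-repolarization segment
#' that passes through (activation + apd30_ms, 70% amplitude) and
#' (activation + apd90_ms, 10% amplitude) and continues at the same slope
#' to baseline — the plateau/phase-3 geometry of a cardiac optical AP,
#' with both measured crossing levels on the steep phase.
#'
#' @param baseline resting level, a.u.
#' @param amplitude AP amplitude above baseline, a.u. (> 0).
#' @param upstroke_ms upstroke duration, ms.
#' @param apd30_ms,apd90_ms target durations at 30% and 90% repolarization,
#'   ms; requires `upstroke_ms / 2 < apd30_ms < apd90_ms` and a plateau of
#'   positive length (`apd30_ms` not too close to the upstroke).
#' @param plateau_level amplitude fraction at which the slow plateau hands
#'   over to the straight rapid-repolarization segment (in (0.7, 1)).
#' @param beat_period_ms interval between successive activations, ms; must
#'   exceed `apd90_ms + tail_ms`.
#' @param n_beats number of beats.
#' @param frame_interval_ms sampling interval, ms.
#' @param noise_sd additive Gaussian noise SD, a.u.
#' @param seed noise seed.
#' @param pre_ms quiescent padding before the first activation, ms.
#' @return list of class `synth_ap`: `time_ms`, `value`,
#'   `frame_interval_ms`, and `truth` (data.frame with one row per beat:
#'   activation_ms, apd30_ms, apd90_ms, apd_ratio, beat_period_ms) plus
#'   `apd_fn(fraction)` giving the exact APD at any fraction in (0, 1).
#' @export
synth_ap_trace <- function(baseline = 0, amplitude = 1, upstroke_ms = 10,
                           apd30_ms = 100, apd90_ms = 250,
                           plateau_level = 0.75,
                           beat_period_ms = 1000, n_beats = 5L,
                           frame_interval_ms = 5, noise_sd = 0, seed = 1L,
                           pre_ms = 200) {
  if (amplitude <= 0) stop("amplitude must be positive", call. = FALSE)
  if (apd30_ms >= apd90_ms)
    stop("apd30_ms must be smaller than apd90_ms", call. = FALSE)
  if (plateau_level <= 0.7 || plateau_level >= 1)
    stop("plateau_level must lie in (0.7, 1)", call. = FALSE)

  # beat-local shape, time measured from the activation reference = the
  # upstroke midpoint (the max-dF/dt point of the raised-cosine ramp).
  # Decay knots (ms from activation) and levels (fraction of amplitude);
  # the APDx crossing level is 1 - x. The segment between plateau_level
  # and 0 is one straight line through both crossing targets.
  half_up <- upstroke_ms / 2
  s3 <- 0.6 / (apd90_ms - apd30_ms)           # phase-3 slope, amp/ms
  t_knee <- apd30_ms - (plateau_level - 0.7) / s3
  t_end <- apd90_ms + 0.1 / s3
  if (upstroke_ms < 0 || half_up >= t_knee)
    stop("upstroke_ms too long: no room for a plateau before phase 3",
         call. = FALSE)
  if (t_end >= beat_period_ms)
    stop("beat must fit inside beat_period_ms", call. = FALSE)
  knots <- c(half_up, t_knee, apd30_ms, apd90_ms, t_end)
  levels <- c(1, plateau_level, 0.7, 0.1, 0)
  shape <- function(t_local) {        # t_local relative to activation
    y <- numeric(length(t_local))
    up <- t_local >= -half_up & t_local < half_up
    if (upstroke_ms > 0)
      y[up] <- 0.5 - 0.5 * cos(pi * (t_local[up] + half_up) / upstroke_ms)
    dec <- t_local >= half_up & t_local <= knots[5L]
    y[dec] <- stats::approx(knots, levels, xout = t_local[dec])$y
    y
  }
  apd_fn <- function(fraction) {
    stopifnot(all(fraction > 0), all(fraction < 1))
    lev <- 1 - fraction
    vapply(lev, function(l) {
      # first down-crossing of level l after the peak
      for (i in 1:4) {
        if (levels[i] >= l && levels[i + 1L] <= l) {
          return(knots[i] + (levels[i] - l) /
                   (levels[i] - levels[i + 1L]) * (knots[i + 1L] - knots[i]))
        }
      }
      NA_real_
    }, 0)
  }

  total_ms <- pre_ms + n_beats * beat_period_ms
  time_ms <- seq(0, total_ms, by = frame_interval_ms)
  activations <- pre_ms + (seq_len(n_beats) - 1L) * beat_period_ms
  value <- rep(0, length(time_ms))
  for (a in activations) value <- value + shape(time_ms - a)
  value <- baseline + amplitude * value
  if (noise_sd > 0) {
    set.seed(seed)
    value <- value + stats::rnorm(length(value), sd = noise_sd)
  }
  truth <- data.frame(
    activation_ms = activations,
    apd30_ms = apd_fn(0.30), apd90_ms = apd_fn(0.90),
    apd_ratio = apd_fn(0.30) / apd_fn(0.90),
    beat_period_ms = c(diff(activations), NA_real_))
  structure(list(time_ms = time_ms, value = value,
                 frame_interval_ms = frame_interval_ms,
                 truth = truth, apd_fn = apd_fn),
            class = "synth_ap")
}

#' Activation times of an ideal plane wave over an electrode grid
#'
#' Kinematic helper: activation time at each electrode of a regular grid
#' crossed by a plane wave of given speed and direction, optionally with
#' Gaussian timing jitter. Useful as ground truth for conduction-velocity
#' recovery tests without running the full reaction-diffusion model.
#'
#' @param n_rows,n_cols electrode grid size.
#' @param pitch_mm electrode spacing, mm.
#' @param velocity_cm_s wave speed, cm/s.
#' @param angle_deg propagation direction, degrees from the +column axis.
#' @param t0_ms activation time at the grid origin, ms.
#' @param jitter_sd_ms SD of additive Gaussian timing noise, ms.
#' @param seed jitter seed.
#' @return data.frame: electrode, row, col, x_mm, y_mm, t_ms.
#' @export
plane_wave_activation <- function(n_rows = 4L, n_cols = 4L, pitch_mm = 1,
                                  velocity_cm_s = 40, angle_deg = 0,
                                  t0_ms = 10, jitter_sd_ms = 0, seed = 1L) {
  stopifnot(velocity_cm_s > 0, pitch_mm > 0)
  g <- expand.grid(row = seq_len(n_rows), col = seq_len(n_cols))
  x <- (g$col - 1L) * pitch_mm
  y <- (g$row - 1L) * pitch_mm
  th <- angle_deg * pi / 180
  v_mm_ms <- velocity_cm_s / 100          # cm/s = 10 mm/s = 0.01 mm/ms
  t <- t0_ms + (x * cos(th) + y * sin(th)) / v_mm_ms
  if (jitter_sd_ms > 0) {
    set.seed(seed)
    t <- t + stats::rnorm(length(t), sd = jitter_sd_ms)
  }
  data.frame(electrode = sprintf("r%dc%d", g$row, g$col),
             row = g$row, col = g$col, x_mm = x, y_mm = y, t_ms = t)
}

#' Synthesize extracellular electrograms from activation ground truth
#'
#' Places, for every electrode, a biphasic depolarization spike at the
#' local activation time (amplitude proportional to the local upstroke
#' slope) and a low-amplitude repolarization deflection ("T-wave") at
#' activation + APD90. Input is either a `medium_sim` (electrode positions
#' are sampled from its ground-truth activation maps) or a plain activation
#' table as produced by [plane_wave_activation()].
#'
#' @param x a `medium_sim` object or a data.frame with columns `electrode`,
#'   `row`, `col`, `x_mm`, `y_mm`, `t_ms` (one row per electrode per beat).
#' @param electrodes for the `medium_sim` path: data.frame with `row`,
#'   `col` pixel positions; default a centered 4x4 grid.
#' @param pitch_mm electrode pitch recorded in the geometry metadata.
#' @param duration_ms trace length, ms; default covers the last event.
#' @param sample_interval_ms electrogram sampling interval, ms.
#' @param spike_amp_uv depolarization spike amplitude for a unit upstroke
#'   slope, microvolts.
#' @param t_wave_amp_uv repolarization deflection amplitude, microvolts.
#' @param t_wave_at_ms T-wave latency after activation when APD90 ground
#'   truth is absent, ms.
#' @param spike_width_ms width parameter of the biphasic spike, ms.
#' @param noise_sd_uv additive Gaussian noise SD, microvolts.
#' @param seed noise seed.
#' @return an [electrogram_set()].
#' @export
synth_electrograms <- function(x, electrodes = NULL, pitch_mm = 1,
                               duration_ms = NULL, sample_interval_ms = 1,
                               spike_amp_uv = 1000, t_wave_amp_uv = 120,
                               t_wave_at_ms = 250, spike_width_ms = 2,
                               noise_sd_uv = 0, seed = 1L) {
  if (inherits(x, "medium_sim")) {
    H <- x$params$grid_height; W <- x$params$grid_width
    if (is.null(electrodes)) {
      rr <- round(seq(H * 0.3, H * 0.7, length.out = 4L))
      cc <- round(seq(W * 0.3, W * 0.7, length.out = 4L))
      electrodes <- expand.grid(row = rr, col = cc)
    }
    if (any(electrodes$row < 1 | electrodes$row > H |
            electrodes$col < 1 | electrodes$col > W))
      stop("electrode positions outside the simulation grid", call. = FALSE)
    gt <- x$ground_truth
    ev <- do.call(rbind, lapply(seq_len(nrow(electrodes)), function(i) {
      r <- electrodes$row[i]; c <- electrodes$col[i]
      acts <- vapply(gt$activation_times, function(m) m[r, c], 0)
      apds <- vapply(gt$true_apd90, function(m) m[r, c], 0)
      ok <- is.finite(acts)
      if (!any(ok)) return(NULL)
      data.frame(electrode = sprintf("r%dc%d", r, c),
                 row = r, col = c,
                 x_mm = (c - 1) * x$params$dx, y_mm = (r - 1) * x$params$dx,
                 t_ms = acts[ok],
                 apd90_ms = ifelse(is.finite(apds[ok]), apds[ok],
                                   t_wave_at_ms),
                 slope = 1)
    }))
    geom <- data.frame(electrode = sprintf("r%dc%d", electrodes$row,
                                           electrodes$col),
                       row = electrodes$row, col = electrodes$col,
                       x_mm = (electrodes$col - 1) * x$params$dx,
                       y_mm = (electrodes$row - 1) * x$params$dx)
    pitch_mm <- x$params$dx
  } else {
    ev <- x
    if (!all(c("electrode", "t_ms") %in% names(ev)))
      stop("activation table must name electrode and t_ms", call. = FALSE)
    if (is.null(ev$apd90_ms)) ev$apd90_ms <- t_wave_at_ms
    if (is.null(ev$slope)) ev$slope <- 1
    geom <- unique(ev[, intersect(c("electrode", "row", "col", "x_mm",
                                    "y_mm"), names(ev))])
  }
  if (is.null(duration_ms))
    duration_ms <- max(ev$t_ms + ev$apd90_ms, na.rm = TRUE) + 200
  time_ms <- seq(0, duration_ms, by = sample_interval_ms)

  # biphasic spike: derivative of a Gaussian; T-wave: broad Gaussian bump
  spike <- function(t, t0, a)
    -a * (t - t0) / spike_width_ms *
      exp(0.5 - (t - t0)^2 / (2 * spike_width_ms^2))
  twave <- function(t, t0, a) a * exp(-(t - t0)^2 / (2 * 15^2))

  traces <- sapply(geom$electrode, function(el) {
    y <- numeric(length(time_ms))
    evi <- ev[ev$electrode == el & is.finite(ev$t_ms), , drop = FALSE]
    if (nrow(evi) == 0L) return(y)
    for (i in seq_len(nrow(evi))) {
      y <- y + spike(time_ms, evi$t_ms[i], spike_amp_uv * evi$slope[i]) +
        twave(time_ms, evi$t_ms[i] + evi$apd90_ms[i], t_wave_amp_uv)
    }
    y
  })
  flat <- apply(traces, 2L, function(y) all(y == 0))
  if (noise_sd_uv > 0) {
    set.seed(seed)
    traces <- traces + matrix(stats::rnorm(length(traces),
                                           sd = noise_sd_uv), nrow(traces))
  }
  electrogram_set(time_ms = time_ms, traces = traces, geometry = geom,
                  pitch_mm = pitch_mm,
                  quality = ifelse(flat, "flat", "ok"))
}
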