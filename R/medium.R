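#' Parameters of the excitable-medium simulator
#'
#' Bundles the grid geometry, integration step and Aliev-Panfilov kinetics
#' used by [simulate_medium()]. The two-variable Aliev-Panfilov model
#' describes a normalized transmembrane variable `u` in \[0, 1\] and a
#' recovery variable `v`:
#' \deqn{\partial_t u = D \nabla^2 u + [k u (u - a)(1 - u) - u v]/\tau}
#' \deqn{\partial_t v = \epsilon(u, v) [-v - k u (u - a - 1)]/\tau}
#' with \eqn{\epsilon(u, v) = \epsilon_0 + \mu_1 v / (u + \mu_2)}. Kinetics
#' constants are dimensionless; `time_scale_ms` maps one model time unit to
#' milliseconds so that all user-facing times are in ms.
#'
#' @param grid_height,grid_width grid size in pixels (>= 16).
#' @param dx spatial step, mm per pixel.
#' @param dt_sim integration step, ms. Must satisfy the explicit-Euler
#'   diffusion stability bound `dt_sim <= dx^2 / (4 * diffusion)`.
#' @param diffusion isotropic diffusion coefficient, mm^2/ms.
#' @param kinetics named list with dimensionless constants `k`, `a`, `eps0`,
#'   `mu1`, `mu2`; `a` must lie in (0, 0.5), all others strictly positive.
#' @param time_scale_ms milliseconds per Aliev-Panfilov time unit.
#' @param seed integer seed carried in the object so downstream stochastic
#'   stages (optics noise) can derive reproducible streams.
#' @return an object of class `medium_params`.
#' @export
medium_params <- function(grid_height = 128L, grid_width = 128L,
                          dx = 0.6, dt_sim = 0.25, diffusion = 0.1,
                          kinetics = list(k = 8, a = 0.1, eps0 = 0.002,
                                          mu1 = 0.2, mu2 = 0.3),
                          time_scale_ms = 12.9, seed = 1L) {
  if (grid_height < 16 || grid_width < 16)
    stop("grid dimensions must be at least 16 pixels", call. = FALSE)
  if (dx <= 0 || dt_sim <= 0 || diffusion <= 0 || time_scale_ms <= 0)
    stop("dx, dt_sim, diffusion and time_scale_ms must be positive",
         call. = FALSE)
  if (dt_sim > dx^2 / (4 * diffusion))
    stop(sprintf(
      "dt_sim = %g ms violates the stability bound dx^2/(4 D) = %g ms",
      dt_sim, dx^2 / (4 * diffusion)), call. = FALSE)
  needed <- c("k", "a", "eps0", "mu1", "mu2")
  if (!all(needed %in% names(kinetics)))
    stop("kinetics must name k, a, eps0, mu1, mu2", call. = FALSE)
  kin <- lapply(kinetics[needed], as.numeric)
  if (kin$a <= 0 || kin$a >= 0.5)
    stop("kinetics constant 'a' must lie in (0, 0.5)", call. = FALSE)
  if (any(unlist(kin) <= 0))
    stop("all kinetics constants must be strictly positive", call. = FALSE)
  structure(list(grid_height = as.integer(grid_height),
                 grid_width = as.integer(grid_width),
                 dx = dx, dt_sim = dt_sim, diffusion = diffusion,
                 kinetics = kin, time_scale_ms = time_scale_ms,
                 seed = as.integer(seed)),
            class = "medium_params")
}

#' Stimulation protocol for the excitable medium
#'
#' @param kind `"planar_s1"` (edge-strip pulses driving plane waves),
#'   `"cross_field_s2"` (one planar S1 followed by a half-field S2 timed into
#'   the S1 refractory tail, the classic spiral-induction protocol), or
#'   `"point_burst"` (burst pacing from a small central site; 10 Hz for 30 s
#'   corresponds to `period_ms = 100`, `count = 300`).
#' @param onset_ms time of the first pulse (for `cross_field_s2`, the S2
#'   time; the S1 is delivered at t = 0), ms.
#' @param period_ms inter-pulse interval, ms; required when `count > 1`.
#' @param count number of pulses.
#' @param region stimulated rectangle as `list(row, col, height, width)` in
#'   pixels (1-based); `NULL` selects a kind-specific default (left edge
#'   strip for planar S1, lower-left quadrant for S2, central 5x5 square for
#'   point bursts).
#' @return an object of class `stimulus_protocol`.
#' @export
stimulus_protocol <- function(kind = c("planar_s1", "cross_field_s2",
                                       "point_burst"),
                              onset_ms = 0, period_ms = NA_real_,
                              count = 1L, region = NULL) {
  kind <- match.arg(kind)
  count <- as.integer(count)
  if (count > 1 && (!is.finite(period_ms) || period_ms <= 0))
    stop("period_ms must be positive when count > 1", call. = FALSE)
  if (!is.null(region)) {
    if (!all(c("row", "col", "height", "width") %in% names(region)))
      stop("region must name row, col, height, width", call. = FALSE)
  }
  structure(list(kind = kind, onset_ms = onset_ms, period_ms = period_ms,
                 count = count, region = region),
            class = "stimulus_protocol")
}

default_region <- function(kind, H, W) {
  switch(kind,
    planar_s1 = list(row = 1L, col = 1L, height = H, width = 3L),
    cross_field_s2 = list(row = H %/% 2 + 1L, col = 1L,
                          height = H - H %/% 2, width = W %/% 2),
    point_burst = {
      r0 <- H %/% 2 - 2L; c0 <- W %/% 2 - 2L
      list(row = r0, col = c0, height = 5L, width = 5L)
    })
}

check_region <- function(region, H, W) {
  if (region$row < 1 || region$col < 1 ||
      region$row + region$height - 1 > H ||
      region$col + region$width - 1 > W)
    stop("stimulus region lies outside the grid", call. = FALSE)
  region
}

# 5-point Laplacian with no-flux (mirrored) boundaries, units 1/dx^2
laplacian_noflux <- function(u, dx) {
  H <- nrow(u); W <- ncol(u)
  (u[c(1L, seq_len(H - 1L)), ] + u[c(seq_len(H - 1L) + 1L, H), ] +
   u[, c(1L, seq_len(W - 1L))] + u[, c(seq_len(W - 1L) + 1L, W)] -
   4 * u) / dx^2
}

#' Simulate an excitable monolayer
#'
#' Integrates the Aliev-Panfilov reaction-diffusion system with forward
#' Euler on a no-flux grid, delivers the requested stimulus protocol, and
#' records ground truth: per-pixel activation times (upward crossings of
#' u = 0.5, linearly interpolated between saved frames), per-pixel APD90
#' (time above u = 0.1 per beat), the spiral-tip trajectory from the
#' isopotential-intersection oracle ([find_tips_isopotential()]), and the
#' plane-wave velocity for planar protocols (linear regression of first-beat
#' activation time on propagation distance).
#'
#' @param params a [medium_params()] object.
#' @param protocol a [stimulus_protocol()] object.
#' @param duration_ms total simulated time, ms. Must cover at least one
#'   stimulus period.
#' @param dt_save_ms interval between saved voltage frames, ms.
#' @param compute_tips logical; run the tip oracle on the saved stack.
#' @return a list of class `medium_sim` with elements `u` (T x H x W array
#'   of the saved transmembrane variable, values in \[0, 1\]), `times_ms`,
#'   `ground_truth` (list: `activation_times`, `true_apd90`,
#'   `tip_trajectory`, `plane_velocity_cm_s`), `params`, `protocol`.
#' @export
simulate_medium <- function(params, protocol, duration_ms,
                            dt_save_ms = 5, compute_tips = TRUE) {
  stopifnot(inherits(params, "medium_params"),
            inherits(protocol, "stimulus_protocol"))
  if (is.finite(protocol$period_ms) && duration_ms < protocol$period_ms)
    stop("duration_ms must cover at least one stimulus period", call. = FALSE)
  H <- params$grid_height; W <- params$grid_width
  dx <- params$dx; dt <- params$dt_sim; D <- params$diffusion
  kin <- params$kinetics; tau <- params$time_scale_ms
  region <- check_region(protocol$region %||%
                           default_region(protocol$kind, H, W), H, W)
  rr <- region$row:(region$row + region$height - 1L)
  cc <- region$col:(region$col + region$width - 1L)

  # pulse schedule: (time, rows, cols); S1 of the cross-field protocol is a
  # planar edge pulse at t = 0, the S2 uses the protocol region at onset_ms
  pulse_dur <- 2                       # ms each pulse holds u at 1
  sched <- if (protocol$kind == "cross_field_s2") {
    s1 <- default_region("planar_s1", H, W)
    list(list(t = 0, rows = s1$row:(s1$row + s1$height - 1L),
              cols = s1$col:(s1$col + s1$width - 1L)),
         list(t = protocol$onset_ms, rows = rr, cols = cc))
  } else {
    onsets <- protocol$onset_ms +
      (seq_len(protocol$count) - 1L) * ifelse(protocol$count > 1L,
                                              protocol$period_ms, 0)
    lapply(onsets, function(t0) list(t = t0, rows = rr, cols = cc))
  }

  n_steps <- ceiling(duration_ms / dt)
  save_every <- max(1L, round(dt_save_ms / dt))
  n_save <- floor(n_steps / save_every) + 1L
  u <- matrix(0, H, W); v <- matrix(0, H, W)
  u_stack <- array(NA_real_, c(n_save, H, W))
  times_ms <- numeric(n_save)
  u_stack[1L, , ] <- u
  k <- kin$k; a <- kin$a; eps0 <- kin$eps0; mu1 <- kin$mu1; mu2 <- kin$mu2

  # ground-truth bookkeeping at the save cadence
  u_prev_save <- u
  beat_count <- matrix(0L, H, W)
  act_times <- list()        # [[beat]] H x W activation time (ms)
  rep_times <- list()        # [[beat]] H x W end of u > 0.1 (ms)
  si <- 1L
  for (step in seq_len(n_steps)) {
    t_now <- (step - 1L) * dt
    lap <- laplacian_noflux(u, dx)
    f_u <- (k * u * (u - a) * (1 - u) - u * v) / tau
    f_v <- ((eps0 + mu1 * v / (u + mu2)) * (-v - k * u * (u - a - 1))) / tau
    u <- u + dt * (D * lap + f_u)
    v <- v + dt * f_v
    for (p in sched)
      if (t_now >= p$t && t_now < p$t + pulse_dur) u[p$rows, p$cols] <- 1
    u[u < 0] <- 0; u[u > 1] <- 1

    if (step %% save_every == 0L) {
      si <- si + 1L
      t_save <- step * dt
      u_stack[si, , ] <- u
      times_ms[si] <- t_save
      up <- u >= 0.5 & u_prev_save < 0.5
      if (any(up)) {
        idx <- which(up)
        frac <- (0.5 - u_prev_save[idx]) / (u[idx] - u_prev_save[idx])
        tact <- t_save - dt_save_ms * (1 - frac)
        for (b in sort(unique(beat_count[idx] + 1L))) {
          if (length(act_times) < b) {
            act_times[[b]] <- matrix(NA_real_, H, W)
            rep_times[[b]] <- matrix(NA_real_, H, W)
          }
          sel <- beat_count[idx] + 1L == b
          act_times[[b]][idx[sel]] <- tact[sel]
        }
        beat_count[idx] <- beat_count[idx] + 1L
      }
      dn <- u < 0.1 & u_prev_save >= 0.1
      if (any(dn)) {
        idx <- which(dn)
        frac <- (u_prev_save[idx] - 0.1) / (u_prev_save[idx] - u[idx])
        trep <- t_save - dt_save_ms * (1 - frac)
        bsel <- beat_count[idx]
        for (b in sort(unique(bsel[bsel > 0L]))) {
          sel <- bsel == b
          rep_times[[b]][idx[sel]] <- trep[sel]
        }
      }
      u_prev_save <- u
    }
  }
  times_ms <- times_ms[seq_len(si)]
  u_stack <- u_stack[seq_len(si), , , drop = FALSE]

  apd90 <- lapply(seq_along(act_times), function(b)
    rep_times[[b]] - act_times[[b]])
  tips <- if (compute_tips)
    find_tips_isopotential(u_stack, times_ms) else
    data.frame(frame = integer(), row = numeric(), col = numeric(),
               chirality = integer(), time_ms = numeric())

  pv <- NA_real_
  if (protocol$kind == "planar_s1" && length(act_times) >= 1L) {
    at <- act_times[[1L]]
    cols <- col(at)[!is.na(at)]
    tms <- at[!is.na(at)]
    if (length(tms) > 10 && stats::sd(tms) > 0) {
      fit <- stats::lm(tms ~ I(cols * dx))    # slope ms/mm
      sl <- coef(fit)[2L]
      if (is.finite(sl) && abs(sl) > 1e-9) pv <- 100 / abs(sl)  # cm/s
    }
  }

  structure(list(u = u_stack, times_ms = times_ms,
                 ground_truth = list(activation_times = act_times,
                                     true_apd90 = apd90,
                                     tip_trajectory = tips,
                                     plane_velocity_cm_s = pv),
                 params = params, protocol = protocol),
            class = "medium_sim")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Spiral-tip oracle by isopotential-line intersection
#'
#' Locates spiral-wave tips independently of any phase-based machinery: a
#' tip at frame t is a point where the u = `u_iso` isoline at time t crosses
#' the u = `u_iso` isoline at time t - 1 (previous saved frame). For each
#' 2x2 pixel cell through which both isolines pass, the two marching-squares
#' contour segments are intersected exactly; only genuine crossings are
#' reported. Chirality is the sign of the z-component of the cross product
#' of the two spatial gradients (the sense in which the isoline rotates),
#' with +1 denoting counter-clockwise rotation in (row, col) axes.
#'
#' @param u_stack T x H x W array of the transmembrane variable.
#' @param times_ms frame times, ms (defaults to frame indices).
#' @param u_iso isopotential level, default 0.5.
#' @return data.frame with columns frame, row, col (sub-pixel, 1-based),
#'   chirality (+1/-1), time_ms.
#' @export
find_tips_isopotential <- function(u_stack, times_ms = NULL, u_iso = 0.5) {
  Tn <- dim(u_stack)[1L]; H <- dim(u_stack)[2L]; W <- dim(u_stack)[3L]
  if (is.null(times_ms)) times_ms <- seq_len(Tn) - 1
  out <- vector("list", Tn)
  for (t in 2:Tn) {
    f1 <- u_stack[t, , ] - u_iso
    f0 <- u_stack[t - 1L, , ] - u_iso
    # 2x2 cells crossed by both contours
    cs1 <- cell_crossed(f1); cs0 <- cell_crossed(f0)
    cand <- which(cs1 & cs0, arr.ind = TRUE)
    if (nrow(cand) == 0L) next
    hits <- matrix(numeric(0), 0L, 2L)
    chir <- integer(0)
    for (i in seq_len(nrow(cand))) {
      r <- cand[i, 1L]; c <- cand[i, 2L]
      s1 <- contour_segment(f1, r, c)
      s0 <- contour_segment(f0, r, c)
      if (is.null(s1) || is.null(s0)) next
      p <- segment_intersection(s1, s0)
      if (is.null(p)) next
      g1 <- c(f1[r + 1L, c] - f1[r, c] + f1[r + 1L, c + 1L] - f1[r, c + 1L],
              f1[r, c + 1L] - f1[r, c] + f1[r + 1L, c + 1L] - f1[r + 1L, c]) / 2
      g0 <- c(f0[r + 1L, c] - f0[r, c] + f0[r + 1L, c + 1L] - f0[r, c + 1L],
              f0[r, c + 1L] - f0[r, c] + f0[r + 1L, c + 1L] - f0[r + 1L, c]) / 2
      cz <- g0[1L] * g1[2L] - g0[2L] * g1[1L]
      if (cz == 0) next
      hits <- rbind(hits, c(r + p[1L], c + p[2L]))
      chir <- c(chir, as.integer(sign(cz)))
    }
    if (nrow(hits) == 0L) next
    keep <- cluster_points(hits)
    out[[t]] <- data.frame(frame = t,
                           row = vapply(keep, function(ix) mean(hits[ix, 1L]), 0),
                           col = vapply(keep, function(ix) mean(hits[ix, 2L]), 0),
                           chirality = vapply(keep, function(ix)
                             as.integer(sign(sum(chir[ix]))), 0L),
                           time_ms = times_ms[t])
  }
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(frame = integer(), row = numeric(), col = numeric(),
                      chirality = integer(), time_ms = numeric())
  res[res$chirality != 0L, , drop = FALSE]
}

# TRUE at (r, c) when the zero contour of f crosses the cell
# [r, r+1] x [c, c+1]
cell_crossed <- function(f) {
  H <- nrow(f); W <- ncol(f)
  a <- f[-H, -W] > 0; b <- f[-1L, -W] > 0
  d <- f[-H, -1L] > 0; e <- f[-1L, -1L] > 0
  s <- a + b + d + e
  s > 0L & s < 4L
}

# marching-squares segment of the zero contour inside cell (r, c); returns
# 2x2 matrix of (drow, dcol) offsets in [0,1]^2 or NULL for the ambiguous
# saddle case
contour_segment <- function(f, r, c) {
  v <- c(f[r, c], f[r, c + 1L], f[r + 1L, c + 1L], f[r + 1L, c])  # tl tr br bl
  pos <- v > 0
  if (sum(pos) %in% c(0L, 4L)) return(NULL)
  if (sum(pos) == 2L && pos[1L] == pos[3L]) return(NULL)  # saddle: skip
  # edge crossings: edges (1:tl-tr, 2:tr-br, 3:br-bl, 4:bl-tl)
  pts <- list()
  edge <- function(va, vb, pa, pb) {
    if ((va > 0) != (vb > 0)) {
      t <- va / (va - vb)
      pts[[length(pts) + 1L]] <<- pa + t * (pb - pa)
    }
  }
  edge(v[1L], v[2L], c(0, 0), c(0, 1))
  edge(v[2L], v[3L], c(0, 1), c(1, 1))
  edge(v[3L], v[4L], c(1, 1), c(1, 0))
  edge(v[4L], v[1L], c(1, 0), c(0, 0))
  if (length(pts) != 2L) return(NULL)
  rbind(pts[[1L]], pts[[2L]])
}

# intersection point of two segments (each 2x2: rows = endpoints), or NULL
segment_intersection <- function(s1, s2) {
  p <- s1[1L, ]; r <- s1[2L, ] - s1[1L, ]
  q <- s2[1L, ]; s <- s2[2L, ] - s2[1L, ]
  den <- r[1L] * s[2L] - r[2L] * s[1L]
  if (abs(den) < 1e-12) return(NULL)
  qp <- q - p
  t <- (qp[1L] * s[2L] - qp[2L] * s[1L]) / den
  w <- (qp[1L] * r[2L] - qp[2L] * r[1L]) / den
  if (t < -1e-9 || t > 1 + 1e-9 || w < -1e-9 || w > 1 + 1e-9) return(NULL)
  p + t * r
}

# group points closer than `radius` px (single-linkage); returns index sets
cluster_points <- function(pts, radius = 2) {
  n <- nrow(pts)
  if (n == 1L) return(list(1L))
  d <- as.matrix(stats::dist(pts))
  grp <- seq_len(n)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n)
    if (d[i, j] <= radius) grp[grp == grp[j]] <- grp[i]
  lapply(unique(grp), function(g) which(grp == g))
}
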