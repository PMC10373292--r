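#' Instantaneous phase movie via the Hilbert transform
#'
#' Builds the analytic signal of every pixel trace (FFT construction: the
#' negative-frequency half of the spectrum is zeroed and the positive half
#' doubled) and takes its argument, giving the instantaneous phase wrapped
#' to (-pi, pi]. Input traces should be band-passed and mean-free; any
#' residual per-pixel mean is removed. All-zero pixels are masked out and
#' carry the sentinel `NA`.
#'
#' @param movie a band-passed [fluor_movie()].
#' @return object of class `phase_movie`: `phase` (T x H x W radians),
#'   `mask`, `frame_interval_ms`, `untrusted_frames`.
#' @export
instantaneous_phase <- function(movie) {
  stopifnot(inherits(movie, "fluor_movie"))
  d <- dim(movie$frames)
  m <- flatten_frames(movie$frames)
  m <- sweep(m, 2L, colMeans(m))
  dead <- apply(m, 2L, function(x) all(abs(x) < 1e-12))
  n <- d[1L]
  sp <- stats::mvfft(m)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[c(1L, n / 2 + 1L)] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2)] <- 2
  }
  analytic <- stats::mvfft(sp * h, inverse = TRUE) / n
  ph <- atan2(Im(analytic), Re(analytic))
  # wrap convention (-pi, pi]: atan2 returns [-pi, pi]; fold -pi to pi
  ph[ph <= -pi] <- pi
  ph[, dead] <- NA_real_
  mask <- movie$mask
  mask[matrix(dead, d[2L], d[3L])] <- FALSE
  structure(list(phase = unflatten_frames(ph, d), mask = mask,
                 frame_interval_ms = movie$frame_interval_ms,
                 untrusted_frames = movie$untrusted_frames),
            class = "phase_movie")
}

#' @export
print.phase_movie <- function(x, ...) {
  d <- dim(x$phase)
  cat(sprintf("<phase_movie> %d frames of %dx%d @ %g ms (%d untrusted)\n",
              d[1L], d[2L], d[3L], x$frame_interval_ms,
              length(x$untrusted_frames)))
  invisible(x)
}

# Bresenham circle offsets of radius r, ordered counter-clockwise by angle
ring_offsets <- function(r) {
  pts <- list()
  x <- 0L; y <- r; d <- 3L - 2L * r
  while (x <= y) {
    pts[[length(pts) + 1L]] <- c(x, y)
    if (d < 0L) d <- d + 4L * x + 6L else {
      d <- d + 4L * (x - y) + 10L; y <- y - 1L
    }
    x <- x + 1L
  }
  oct <- do.call(rbind, pts)
  all8 <- rbind(oct,
                cbind(oct[, 2L], oct[, 1L]),
                cbind(oct[, 2L], -oct[, 1L]),
                cbind(oct[, 1L], -oct[, 2L]),
                cbind(-oct[, 1L], -oct[, 2L]),
                cbind(-oct[, 2L], -oct[, 1L]),
                cbind(-oct[, 2L], oct[, 1L]),
                cbind(-oct[, 1L], oct[, 2L]))
  all8 <- unique(all8)
  ang <- atan2(all8[, 1L], all8[, 2L])
  all8[order(ang), , drop = FALSE]    # (drow, dcol), CCW
}

wrap_phase <- function(x) {
  out <- (x + pi) %% (2 * pi) - pi
  out[out <= -pi] <- pi
  out
}

# cumulative wrapped phase difference around one ring, evaluated at every
# pixel simultaneously via shifted matrices; NA where the ring touches a
# masked or out-of-bounds pixel
ring_winding <- function(ph, mask, offs) {
  H <- nrow(ph); W <- ncol(ph)
  pad <- max(abs(offs))
  big <- matrix(NA_real_, H + 2L * pad, W + 2L * pad)
  big[pad + (1:H), pad + (1:W)] <- ifelse(mask, ph, NA_real_)
  shift_mat <- function(dr, dc)
    big[pad + (1:H) + dr, pad + (1:W) + dc]
  n <- nrow(offs)
  acc <- matrix(0, H, W)
  prev <- shift_mat(offs[n, 1L], offs[n, 2L])
  for (i in seq_len(n)) {
    cur <- shift_mat(offs[i, 1L], offs[i, 2L])
    acc <- acc + wrap_phase(cur - prev)
    prev <- cur
  }
  acc
}

#' Detect phase singularities by the double-ring criterion
#'
#' At every pixel the wrapped phase differences are accumulated along two
#' concentric discrete (Bresenham) rings. A singularity is reported where
#' the cumulative difference exceeds `threshold` in magnitude on both rings
#' with equal sign (an ideal singularity winds by 2 pi; the default
#' threshold pi tolerates discretization). Connected clusters of candidate
#' pixels are reduced to a single detection located at the cluster
#' centroid (sub-pixel; every pixel whose rings encircle the core is a
#' candidate, so the centroid estimates the core position far better than
#' any single tied pixel); the reported ring sums are those of the
#' largest-magnitude pixel, ties broken by smallest row then column.
#' Pixels whose rings leave the mask or the image are never candidates.
#'
#' @param phase_frame H x W phase matrix in (-pi, pi].
#' @param mask logical H x W tissue mask.
#' @param r_inner,r_outer ring radii in pixels, `r_inner < r_outer`.
#' @param threshold winding magnitude required on both rings, radians.
#' @return data.frame: row, col, chirality (+1/-1), inner_sum, outer_sum.
#' @export
detect_singularities <- function(phase_frame, mask = NULL,
                                 r_inner = 2L, r_outer = 4L,
                                 threshold = pi) {
  if (r_inner >= r_outer)
    stop("r_inner must be smaller than r_outer", call. = FALSE)
  if (is.null(mask)) mask <- matrix(TRUE, nrow(phase_frame),
                                    ncol(phase_frame))
  s_in <- ring_winding(phase_frame, mask, ring_offsets(r_inner))
  s_out <- ring_winding(phase_frame, mask, ring_offsets(r_outer))
  cand <- !is.na(s_in) & !is.na(s_out) &
    abs(s_in) > threshold & abs(s_out) > threshold &
    sign(s_in) == sign(s_out)
  empty <- data.frame(row = integer(), col = integer(),
                      chirality = integer(), inner_sum = numeric(),
                      outer_sum = numeric())
  if (!any(cand)) return(empty)
  comp <- label_components(cand)
  rows <- lapply(seq_len(max(comp)), function(g) {
    ix <- which(comp == g, arr.ind = TRUE)
    score <- abs(s_in[comp == g])
    best <- order(-score, ix[, 1L], ix[, 2L])[1L]
    r <- ix[best, 1L]; c <- ix[best, 2L]
    data.frame(row = mean(ix[, 1L]), col = mean(ix[, 2L]),
               chirality = as.integer(sign(s_in[r, c])),
               inner_sum = s_in[r, c], outer_sum = s_out[r, c])
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# 8-connected component labelling of a logical matrix (two-pass union-find)
label_components <- function(bw) {
  H <- nrow(bw); W <- ncol(bw)
  lab <- matrix(0L, H, W)
  parent <- integer(0)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  nxt <- 0L
  for (c in seq_len(W)) for (r in seq_len(H)) {
    if (!bw[r, c]) next
    nb <- integer(0)
    for (dd in list(c(-1L, 0L), c(0L, -1L), c(-1L, -1L), c(-1L, 1L))) {
      rr <- r + dd[1L]; cc <- c + dd[2L]
      if (rr >= 1L && rr <= H && cc >= 1L && cc <= W && lab[rr, cc] > 0L)
        nb <- c(nb, lab[rr, cc])
    }
    if (length(nb) == 0L) {
      nxt <- nxt + 1L
      parent[nxt] <- nxt
      lab[r, c] <- nxt
    } else {
      roots <- vapply(unique(nb), find, 0L)
      m <- min(roots)
      lab[r, c] <- m
      for (rt in roots) parent[rt] <- m
    }
  }
  if (nxt == 0L) return(lab)
  roots <- vapply(seq_len(nxt), find, 0L)
  relab <- match(roots, unique(roots))
  lab[lab > 0L] <- relab[lab[lab > 0L]]
  lab
}

#' Detect phase singularities in every trusted frame of a phase movie
#'
#' @param pmovie a `phase_movie`.
#' @param ... passed to [detect_singularities()].
#' @param include_untrusted analyze flagged edge frames too (default off).
#' @return data.frame with a `frame` column prepended; `time_ms` attached.
#' @export
detect_singularities_movie <- function(pmovie, ...,
                                       include_untrusted = FALSE) {
  stopifnot(inherits(pmovie, "phase_movie"))
  Tn <- dim(pmovie$phase)[1L]
  frames <- seq_len(Tn)
  if (!include_untrusted)
    frames <- setdiff(frames, pmovie$untrusted_frames)
  out <- lapply(frames, function(t) {
    det <- detect_singularities(pmovie$phase[t, , ], pmovie$mask, ...)
    if (nrow(det) == 0L) return(NULL)
    cbind(frame = t, det,
          time_ms = (t - 1L) * pmovie$frame_interval_ms)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(frame = integer(), row = integer(), col = integer(),
                      chirality = integer(), inner_sum = numeric(),
                      outer_sum = numeric(), time_ms = numeric())
  res
}
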