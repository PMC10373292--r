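#' Filter specification for optical conditioning
#'
#' @param band_low_hz,band_high_hz Butterworth pass band, Hz. Must satisfy
#'   `0 < band_low_hz < band_high_hz < ` Nyquist of the movie.
#' @param order filter order (applied forward and reverse, so the effective
#'   attenuation is doubled).
#' @param zero_phase apply the filter forward then reverse (filtfilt).
#' @param taper `"hanning"` (raised-cosine ends before filtering) or
#'   `"none"`.
#' @param gaussian_sigma_px spatial Gaussian SD, pixels.
#' @param norm_window_frames sliding-window normalization length, frames.
#' @return object of class `filter_spec`.
#' @export
filter_spec <- function(band_low_hz = 1, band_high_hz = 30, order = 4L,
                        zero_phase = TRUE, taper = c("hanning", "none"),
                        gaussian_sigma_px = 1, norm_window_frames = 100L) {
  taper <- match.arg(taper)
  if (band_low_hz <= 0 || band_high_hz <= band_low_hz)
    stop("need 0 < band_low_hz < band_high_hz", call. = FALSE)
  if (order < 1L) stop("order must be >= 1", call. = FALSE)
  if (norm_window_frames < 2L)
    stop("norm_window_frames must be >= 2", call. = FALSE)
  structure(list(band_low_hz = band_low_hz, band_high_hz = band_high_hz,
                 order = as.integer(order), zero_phase = zero_phase,
                 taper = taper, gaussian_sigma_px = gaussian_sigma_px,
                 norm_window_frames = as.integer(norm_window_frames)),
            class = "filter_spec")
}

# frames as T x P matrix (pixels in columns)
flatten_frames <- function(frames) {
  d <- dim(frames)
  dim(frames) <- c(d[1L], d[2L] * d[3L])
  frames
}
unflatten_frames <- function(mat, d) {
  dim(mat) <- d
  mat
}

# sliding min/max over a centered window truncated at the ends, computed
# with a sparse-table (doubling) scheme: O(T P log W)
rolling_extreme <- function(mat, window, fun = pmin) {
  Tn <- nrow(mat)
  half_lo <- (window - 1L) %/% 2L          # frames before the center
  half_hi <- window - 1L - half_lo
  # f[t, ] = extreme over [t, t + 2^J - 1] clipped at T
  J <- 0L
  while (2L^(J + 1L) <= window) J <- J + 1L
  f <- mat
  len <- 1L
  while (len < 2L^J) {
    shifted <- f[pmin(seq_len(Tn) + len, Tn), , drop = FALSE]
    f <- fun(f, shifted)
    len <- len * 2L
  }
  # interior: window [t - half_lo, t + half_hi]; the two power-of-two
  # blocks [lo, lo+2^J-1] U [hi-2^J+1, hi] cover it exactly when its
  # length is in [2^J, 2^(J+1)]
  lo <- pmax(seq_len(Tn) - half_lo, 1L)
  hi <- pmin(seq_len(Tn) + half_hi, Tn)
  a <- f[lo, , drop = FALSE]
  b <- f[pmax(hi - 2L^J + 1L, 1L), , drop = FALSE]
  out <- fun(a, b)
  # truncated end windows shorter than 2^J would overrun; compute those
  # rows directly
  short <- which(hi - lo + 1L < 2L^J)
  for (t in short)
    out[t, ] <- Reduce(fun, lapply(lo[t]:hi[t], function(k) mat[k, ]))
  out
}

#' Sliding-window normalization
#'
#' Per pixel, each frame is rescaled to the range of its centered window of
#' `window` frames (truncated at the movie ends):
#' `(F - min_w) / (max_w - min_w)`. Output lies in \[0, 1\] wherever the
#' window has non-zero range; constant stretches map to 0. The rescaling is
#' invariant to per-pixel affine gain and offset, which is what lets it
#' amplify weak optical signals uniformly across the field.
#'
#' @param movie a [fluor_movie()].
#' @param window window length in frames (>= 2, <= number of frames).
#' @return normalized [fluor_movie()].
#' @export
sliding_window_normalize <- function(movie, window = 100L) {
  stopifnot(inherits(movie, "fluor_movie"))
  d <- dim(movie$frames)
  if (window > d[1L])
    stop("normalization window exceeds movie length", call. = FALSE)
  if (window < 2L) stop("window must be >= 2", call. = FALSE)
  m <- flatten_frames(movie$frames)
  mn <- rolling_extreme(m, window, pmin)
  mx <- rolling_extreme(m, window, pmax)
  rng <- mx - mn
  out <- (m - mn) / ifelse(rng > 0, rng, 1)
  out[rng == 0] <- 0
  movie$frames <- unflatten_frames(out, d)
  movie$provenance <- c(movie$provenance,
                        sprintf("sliding_window_normalize(window=%d)",
                                as.integer(window)))
  movie
}

gaussian_kernel_matrix <- function(n, sigma) {
  # n x n banded matrix applying a 1-D Gaussian along one axis
  idx <- seq_len(n)
  K <- outer(idx, idx, function(i, j) exp(-(i - j)^2 / (2 * sigma^2)))
  K[abs(outer(idx, idx, "-")) > ceiling(4 * sigma)] <- 0
  K   # unnormalized; the normalized convolution divides by the mask blur
}

#' Masked spatial Gaussian smoothing
#'
#' Per-frame separable Gaussian convolution as normalized convolution:
#' masked pixels neither contribute to nor receive smoothed values, and
#' edge effects are removed by dividing by the smoothed mask
#' (`G*(F.M) / G*M`). `sigma_px = 0` is the identity.
#'
#' @param movie a [fluor_movie()].
#' @param sigma_px Gaussian SD in pixels (>= 0).
#' @return smoothed [fluor_movie()].
#' @export
spatial_gaussian <- function(movie, sigma_px = 1) {
  stopifnot(inherits(movie, "fluor_movie"))
  if (sigma_px < 0) stop("sigma_px must be >= 0", call. = FALSE)
  if (sigma_px == 0) {
    movie$provenance <- c(movie$provenance, "spatial_gaussian(sigma=0)")
    return(movie)
  }
  d <- dim(movie$frames)
  Kr <- gaussian_kernel_matrix(d[2L], sigma_px)
  Kc <- gaussian_kernel_matrix(d[3L], sigma_px)
  M <- movie$mask * 1
  denom <- Kr %*% M %*% t(Kc)
  out <- array(0, d)
  for (t in seq_len(d[1L])) {
    f <- movie$frames[t, , ] * M
    sm <- (Kr %*% f %*% t(Kc)) / denom
    sm[!movie$mask] <- movie$frames[t, , ][!movie$mask]
    out[t, , ] <- sm
  }
  movie$frames <- out
  movie$provenance <- c(movie$provenance,
                        sprintf("spatial_gaussian(sigma=%g)", sigma_px))
  movie
}

butter_bandpass <- function(spec, fs) {
  nyq <- fs / 2
  if (spec$band_high_hz >= nyq)
    stop(sprintf("band_high_hz (%g) must be below Nyquist (%g Hz)",
                 spec$band_high_hz, nyq), call. = FALSE)
  signal::butter(spec$order,
                 c(spec$band_low_hz, spec$band_high_hz) / nyq,
                 type = "pass")
}

filtfilt_trace <- function(x, flt, taper) {
  n <- length(x)
  x <- x - mean(x)
  if (taper == "hanning") {
    # raised-cosine ramp over the outer 10% of each end; interior untouched
    m <- max(2L, floor(0.1 * n))
    ramp <- 0.5 - 0.5 * cos(pi * (0:(m - 1L)) / m)
    env <- rep(1, n)
    env[1:m] <- ramp
    env[(n - m + 1L):n] <- rev(ramp)
    x <- x * env
  }
  signal::filtfilt(flt, x)
}

#' Zero-phase Butterworth band-pass
#'
#' Applies an `order`-th Butterworth band-pass forward and then reverse
#' (zero net phase shift, squared magnitude response), after mean removal
#' and optional Hanning tapering of the trace ends. Filter edge artifacts
#' are confined to the first and last `ceil(2 fs / band_low_hz)` samples,
#' which are flagged untrusted on movies so that downstream phase analysis
#' can skip them.
#'
#' @param x a [fluor_movie()] or a numeric trace.
#' @param spec a [filter_spec()].
#' @param fs sampling rate in Hz; required for a bare trace, derived from
#'   the frame interval for movies.
#' @return object of the same shape, filtered.
#' @export
bandpass <- function(x, spec = filter_spec(), fs = NULL) {
  if (inherits(x, "fluor_movie")) {
    fs <- 1000 / x$frame_interval_ms
    flt <- butter_bandpass(spec, fs)
    d <- dim(x$frames)
    m <- flatten_frames(x$frames)
    for (p in seq_len(ncol(m)))
      m[, p] <- filtfilt_trace(m[, p], flt, spec$taper)
    x$frames <- unflatten_frames(m, d)
    edge <- ceiling(2 * fs / spec$band_low_hz)
    edge <- min(edge, floor(d[1L] / 2))
    x$untrusted_frames <- sort(unique(c(x$untrusted_frames,
                                        seq_len(edge),
                                        (d[1L] - edge + 1L):d[1L])))
    x$provenance <- c(x$provenance,
                      sprintf("bandpass(%g-%g Hz, order %d)",
                              spec$band_low_hz, spec$band_high_hz,
                              spec$order))
    x
  } else {
    if (is.null(fs)) stop("fs required for a bare trace", call. = FALSE)
    flt <- butter_bandpass(spec, fs)
    filtfilt_trace(x, flt, spec$taper)
  }
}

#' Smooth a trace by truncated Fourier re-synthesis
#'
#' Re-synthesizes a band-passed trace from its `k` largest-magnitude
#' in-band Fourier components (a sinusoidal re-composition). Reported
#' alongside is the residual power fraction left out of the reconstruction.
#'
#' @param trace numeric vector (already band-passed, mean-free).
#' @param fs sampling rate, Hz.
#' @param k number of retained components (positive-frequency count).
#' @param band_hz frequency band eligible for retention, Hz.
#' @return numeric vector with attribute `residual_power` (fraction of
#'   total power discarded).
#' @export
smooth_recompose <- function(trace, fs, k = 25L,
                             band_hz = c(0, Inf)) {
  if (k <= 0) stop("k must be positive", call. = FALSE)
  n <- length(trace)
  sp <- stats::fft(trace)
  freq <- (seq_len(n) - 1L) / n * fs
  freq <- pmin(freq, fs - freq)               # two-sided -> folded Hz
  half <- seq_len(floor(n / 2) + 1L)          # DC .. Nyquist
  mag <- Mod(sp[half])
  eligible <- which(freq[half] >= band_hz[1L] & freq[half] <= band_hz[2L])
  keep_half <- eligible[order(mag[eligible], decreasing = TRUE)]
  keep_half <- head(keep_half, k)
  keep <- rep(FALSE, n)
  keep[keep_half] <- TRUE
  conj_idx <- ifelse(keep_half == 1L, 1L, n - keep_half + 2L)
  keep[conj_idx] <- TRUE
  sp[!keep] <- 0
  out <- Re(stats::fft(sp, inverse = TRUE)) / n
  tot <- sum(Mod(trace)^2)
  attr(out, "residual_power") <- if (tot > 0)
    sum((trace - out)^2) / tot else 0
  out
}

#' Mean trace over a region of interest
#'
#' Per-frame mean over the ROI intersected with the tissue mask.
#'
#' @param movie a [fluor_movie()].
#' @param roi either a logical H x W matrix or `list(row, col, height,
#'   width)` rectangle (1-based).
#' @return data.frame: time_ms, value.
#' @export
extract_trace <- function(movie, roi) {
  stopifnot(inherits(movie, "fluor_movie"))
  d <- dim(movie$frames)
  sel <- if (is.matrix(roi)) roi else {
    m <- matrix(FALSE, d[2L], d[3L])
    m[roi$row:(roi$row + roi$height - 1L),
      roi$col:(roi$col + roi$width - 1L)] <- TRUE
    m
  }
  sel <- sel & movie$mask
  if (!any(sel)) stop("ROI does not intersect the tissue mask",
                      call. = FALSE)
  m <- flatten_frames(movie$frames)
  vals <- rowMeans(m[, as.vector(sel), drop = FALSE])
  data.frame(time_ms = (seq_len(d[1L]) - 1L) * movie$frame_interval_ms,
             value = vals)
}

#' Standard optical conditioning chain
#'
#' Convenience wrapper running sliding-window normalization, masked
#' Gaussian smoothing and the zero-phase band-pass in the conventional
#' order.
#'
#' @param movie a [fluor_movie()].
#' @param spec a [filter_spec()].
#' @return conditioned [fluor_movie()].
#' @export
preprocess_movie <- function(movie, spec = filter_spec()) {
  movie <- sliding_window_normalize(movie, spec$norm_window_frames)
  movie <- spatial_gaussian(movie, spec$gaussian_sigma_px)
  bandpass(movie, spec)
}
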