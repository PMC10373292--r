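#' Fluorescence movie container
#'
#' A masked T x H x W intensity stack with its frame interval and a
#' provenance trail. All analysis operations accept and return this class;
#' masked-out pixels are excluded from every statistic and each operation
#' appends its name to `provenance`.
#'
#' @param frames T x H x W numeric array (arbitrary units).
#' @param frame_interval_ms frame interval, ms (> 0).
#' @param mask H x W logical tissue mask; default all TRUE.
#' @param modality `"voltage"` or `"calcium"`.
#' @param provenance character vector of applied operations.
#' @param untrusted_frames integer frame indices whose values carry filter
#'   edge artifacts; empty until [bandpass()] flags them.
#' @return object of class `fluor_movie`.
#' @export
fluor_movie <- function(frames, frame_interval_ms, mask = NULL,
                        modality = c("voltage", "calcium"),
                        provenance = character(),
                        untrusted_frames = integer()) {
  modality <- match.arg(modality)
  d <- dim(frames)
  if (length(d) != 3L || d[1L] < 2L)
    stop("frames must be a T x H x W array with T >= 2", call. = FALSE)
  if (frame_interval_ms <= 0)
    stop("frame_interval_ms must be positive", call. = FALSE)
  if (is.null(mask)) mask <- matrix(TRUE, d[2L], d[3L])
  stopifnot(identical(dim(mask), d[2:3]))
  structure(list(frames = frames, frame_interval_ms = frame_interval_ms,
                 mask = mask, modality = modality, provenance = provenance,
                 untrusted_frames = as.integer(untrusted_frames)),
            class = "fluor_movie")
}

#' @export
print.fluor_movie <- function(x, ...) {
  d <- dim(x$frames)
  cat(sprintf("<fluor_movie> %d frames of %dx%d @ %g ms (%s)\n",
              d[1L], d[2L], d[3L], x$frame_interval_ms, x$modality))
  if (length(x$provenance))
    cat("  provenance:", paste(x$provenance, collapse = " -> "), "\n")
  invisible(x)
}

#' Optical forward model
#'
#' Parameters converting the simulated transmembrane variable into a
#' fluorescence recording: affine gain, mono-exponential photobleaching,
#' additive per-pixel Gaussian noise, and temporal decimation to the camera
#' frame interval.
#'
#' @param frame_interval_ms camera frame interval, ms (default 5).
#' @param gain fluorescence change per unit of the transmembrane variable
#'   (a.u.; non-zero).
#' @param baseline resting fluorescence, a.u.
#' @param bleach_tau_ms time constant of mono-exponential bleaching, ms;
#'   `Inf` disables bleaching.
#' @param noise_sd SD of additive Gaussian noise per pixel per frame, a.u.
#' @param polarity +1 for dyes that brighten on depolarization, -1 for
#'   dimming dyes.
#' @return object of class `optics_model`.
#' @export
optics_model <- function(frame_interval_ms = 5, gain = 1, baseline = 0,
                         bleach_tau_ms = Inf, noise_sd = 0, polarity = 1) {
  if (frame_interval_ms <= 0) stop("frame_interval_ms must be positive",
                                   call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be non-negative", call. = FALSE)
  if (gain == 0) stop("gain must be non-zero", call. = FALSE)
  if (!polarity %in% c(-1, 1)) stop("polarity must be +1 or -1",
                                    call. = FALSE)
  structure(list(frame_interval_ms = frame_interval_ms, gain = gain,
                 baseline = baseline, bleach_tau_ms = bleach_tau_ms,
                 noise_sd = noise_sd, polarity = polarity),
            class = "optics_model")
}

#' Render a fluorescence movie from a simulated voltage stack
#'
#' Applies the optical forward model
#' `F = (baseline + polarity * gain * u) * exp(-t / bleach_tau_ms) + noise`
#' and decimates from the simulation save cadence to the camera frame
#' interval by nearest-frame selection.
#'
#' @param sim a `medium_sim` object from [simulate_medium()], or a plain
#'   T x H x W array (then `times_ms` must be given).
#' @param optics an [optics_model()].
#' @param seed integer seed for the noise stream.
#' @param times_ms frame times when `sim` is a bare array.
#' @param mask optional tissue mask.
#' @param modality recorded dye modality.
#' @return a [fluor_movie()].
#' @export
render_movie <- function(sim, optics = optics_model(), seed = 1L,
                         times_ms = NULL, mask = NULL,
                         modality = "voltage") {
  if (inherits(sim, "medium_sim")) {
    u <- sim$u; times_ms <- sim$times_ms
  } else {
    u <- sim
    if (is.null(times_ms)) stop("times_ms required for a bare array",
                                call. = FALSE)
  }
  if (!all(is.finite(u))) stop("voltage stack contains non-finite values",
                               call. = FALSE)
  dt_in <- if (length(times_ms) > 1L) diff(times_ms[1:2]) else
    optics$frame_interval_ms
  if (optics$frame_interval_ms < dt_in - 1e-9)
    stop(sprintf(
      "frame_interval_ms (%g) below the stack save interval (%g)",
      optics$frame_interval_ms, dt_in), call. = FALSE)
  t_out <- seq(times_ms[1L], times_ms[length(times_ms)],
               by = optics$frame_interval_ms)
  pick <- vapply(t_out, function(t) which.min(abs(times_ms - t)), 0L)
  f <- u[pick, , , drop = FALSE]
  f <- optics$baseline + optics$polarity * optics$gain * f
  if (is.finite(optics$bleach_tau_ms)) {
    fac <- exp(-t_out / optics$bleach_tau_ms)
    f <- f * fac            # recycles over (frame, row, col) first index
  }
  if (optics$noise_sd > 0) {
    set.seed(seed)
    f <- f + array(stats::rnorm(length(f), sd = optics$noise_sd), dim(f))
  }
  fluor_movie(f, optics$frame_interval_ms, mask = mask,
              modality = modality,
              provenance = sprintf("render_movie(gain=%g, noise_sd=%g)",
                                   optics$gain, optics$noise_sd))
}
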