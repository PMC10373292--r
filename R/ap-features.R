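#' Detect beat activations in an optical trace
#'
#' Activation is the time of maximal first derivative (dF/dt) on each
#' upstroke. Candidate upstrokes are contiguous runs where the derivative
#' exceeds `prominence` times its maximum; events closer than
#' `min_period_ms` are merged keeping the larger-amplitude one. With equal
#' derivative samples the earliest wins. Traces recorded with a
#' depolarization-dimming dye should be passed with `polarity = -1`.
#'
#' @param trace numeric vector.
#' @param time_ms sample times, ms.
#' @param min_period_ms minimum beat spacing, ms (> 0).
#' @param prominence fraction of the maximum derivative a candidate
#'   upstroke must reach (also bounded below by `min_dvdt_sd` noise SDs).
#' @param polarity +1 or -1; the trace is multiplied by it first.
#' @param min_dvdt_sd derivative threshold floor in robust noise SDs.
#' @return numeric vector of activation times (ms), possibly empty with
#'   attribute `flag = "no_beats"`.
#' @export
detect_beats <- function(trace, time_ms, min_period_ms = 250,
                         prominence = 0.3, polarity = 1,
                         min_dvdt_sd = 5) {
  stopifnot(min_period_ms > 0)
  x <- trace * polarity
  dt <- time_ms[2L] - time_ms[1L]
  dv <- diff(x) / dt
  # noise floor from second differences, which a smooth upstroke barely
  # excites; var(diff2 of white noise) = 6 sigma^2 and the noise part of
  # dv has variance 2 sigma^2 / dt^2
  noise_dv <- stats::mad(diff(x, differences = 2L)) / (sqrt(3) * dt)
  thr <- max(prominence * max(dv), min_dvdt_sd * noise_dv)
  out <- numeric(0)
  if (!is.finite(thr) || thr <= 0 || !any(dv > thr)) {
    attr(out, "flag") <- "no_beats"
    return(out)
  }
  cand <- which(dv > thr)
  gaps <- which(diff(cand) > 1L)
  starts <- c(1L, gaps + 1L); ends <- c(gaps, length(cand))
  ev <- vapply(seq_along(starts), function(i) {
    run <- cand[starts[i]:ends[i]]
    run[which.max(dv[run])]          # which.max: earliest of ties
  }, 0L)
  amp <- vapply(ev, function(i) {
    w <- which(time_ms >= time_ms[i] & time_ms <= time_ms[i] + min_period_ms / 2)
    max(x[w]) - x[i]
  }, 0)
  # merge events closer than min_period_ms keeping the larger amplitude
  keep <- rep(TRUE, length(ev))
  repeat {
    t_ev <- time_ms[ev[keep]]
    close <- which(diff(t_ev) < min_period_ms)
    if (length(close) == 0L) break
    i <- which(keep)[close[1L]]
    j <- which(keep)[close[1L] + 1L]
    if (amp[i] >= amp[j]) keep[j] <- FALSE else keep[i] <- FALSE
  }
  # dv[i] estimates the derivative at the interval midpoint t_i + dt/2;
  # a parabola through the three derivative samples around the maximum
  # refines the max-dF/dt time below the frame interval
  vapply(ev[keep], function(i) {
    t0 <- time_ms[i] + dt / 2
    if (i > 1L && i < length(dv)) {
      y1 <- dv[i - 1L]; y2 <- dv[i]; y3 <- dv[i + 1L]
      den <- y1 - 2 * y2 + y3
      if (is.finite(den) && den < 0) {
        delta <- 0.5 * (y1 - y3) / den
        if (abs(delta) <= 1) t0 <- t0 + delta * dt
      }
    }
    t0
  }, 0)
}

#' Action-potential duration at a repolarization fraction
#'
#' `APDx` is the time from activation to the first moment after the peak
#' at which the trace falls below `peak - fraction * (peak - baseline)`.
#' The baseline is the median of the diastolic samples in the 30% of the
#' preceding inter-beat interval closest to activation. Because the
#' repolarization of a normal beat is monotone, the crossing is located on
#' an antitonic (decreasing isotonic) regression fit of the post-peak
#' segment — this pools noisy samples on shallow slopes without biasing
#' noiseless traces, for which the fit reproduces the data exactly — and
#' is refined to sub-frame precision by linear interpolation between the
#' bracketing fitted samples.
#'
#' @param trace,time_ms trace and sample times (ms).
#' @param activation_ms activation time from [detect_beats()].
#' @param fraction repolarization fraction in (0, 1), e.g. 0.3 or 0.9.
#' @param next_activation_ms following activation (or `Inf`); the crossing
#'   must occur before it, otherwise the value is flagged missing.
#' @param prev_activation_ms preceding activation (or `-Inf`) used for the
#'   diastolic baseline window.
#' @param polarity +1 or -1.
#' @param refine refine the isotonic crossing by a linear fit of the
#'   rapid-repolarization (phase-3) segment, identified as the 5--68%
#'   amplitude band of the monotone fit. This pools noise on shallow
#'   near-linear ramps; disable to obtain crossing times that are provably
#'   monotone in `fraction` for a given beat.
#' @param refine_window_ms maximum distance from the isotonic crossing at
#'   which samples may still enter the phase-3 fit; the refined crossing
#'   may move at most half this far from the isotonic one.
#' @param peak_value,baseline_value externally supplied peak and baseline
#'   (e.g. trace-level estimates pooled across beats, as
#'   [trace_features()] does); `NULL` estimates them from this beat.
#' @return one-row data.frame: apd_ms, peak_ms, amplitude, quality.
#' @export
compute_apd <- function(trace, time_ms, activation_ms, fraction,
                        next_activation_ms = Inf,
                        prev_activation_ms = -Inf, polarity = 1,
                        refine = TRUE, refine_window_ms = 400,
                        peak_value = NULL, baseline_value = NULL) {
  stopifnot(fraction > 0, fraction < 1)
  x <- trace * polarity
  dt <- time_ms[2L] - time_ms[1L]
  # diastolic baseline: 30% of the preceding interval nearest activation
  if (is.finite(prev_activation_ms)) {
    lo <- activation_ms - 0.3 * (activation_ms - prev_activation_ms)
  } else {
    lo <- max(time_ms[1L], activation_ms - 100)
  }
  bw <- which(time_ms >= lo & time_ms < activation_ms)
  if (length(bw) < 1L) bw <- which(time_ms < activation_ms)
  baseline <- baseline_value %||%
    (if (length(bw)) stats::median(x[bw]) else x[1L])

  hi <- min(next_activation_ms, max(time_ms))
  w <- which(time_ms >= activation_ms & time_ms < hi)
  miss <- data.frame(apd_ms = NA_real_, peak_ms = NA_real_,
                     amplitude = NA_real_, baseline = NA_real_,
                     quality = "no_crossing")
  if (length(w) < 3L) return(miss)
  seg <- x[w]; tseg <- time_ms[w]
  if (length(seg) >= 3L)
    seg <- stats::runmed(seg, 3L, endrule = "keep")  # kill 1-sample spikes
  ipk <- which.max(seg)
  dec <- seg[ipk:length(seg)]
  tdec <- tseg[ipk:length(seg)]
  if (length(dec) < 2L) return(miss)
  iso <- -stats::isoreg(-dec)$yf          # non-increasing repolarization fit
  peak <- peak_value %||% iso[1L]
  level <- peak - fraction * (peak - baseline)
  below <- which(iso < level)
  below <- below[below > 1L]
  if (length(below) == 0L) return(miss)
  i2 <- below[1L]; i1 <- i2 - 1L
  t_cross <- tdec[i1] + (iso[i1] - level) / (iso[i1] - iso[i2]) *
    (tdec[i2] - tdec[i1])
  if (refine) {
    # refine by a continuous three-segment piecewise-linear beat fit
    # (plateau / rapid repolarization / diastolic tail) on the raw decay
    # samples; the crossing is read off the fitted curve
    raw <- x[w][ipk:length(seg)]
    # anchor the fitted peak midway between activation and the first
    # decay sample: the plateau line extrapolated there approximates the
    # true AP peak for both sharp-peaked and plateaued morphologies, and
    # is insensitive to argmax jitter on noisy plateaus
    fitm <- fit_beat_segments(tdec, raw, iso, baseline,
                              t_peak = (activation_ms + tdec[1L]) / 2)
    if (!is.null(fitm)) {
      pk_fit <- if (is.null(peak_value)) fitm$peak else peak_value
      lvl <- pk_fit - fraction * (pk_fit - baseline)
      t_ref <- pwl3_crossing(fitm, lvl)
      if (is.finite(t_ref) &&
          abs(t_ref - t_cross) <= refine_window_ms / 2) {
        t_cross <- t_ref
        peak <- pk_fit
        level <- lvl
      }
    }
  }
  data.frame(apd_ms = t_cross - activation_ms, peak_ms = tseg[ipk],
             amplitude = peak - baseline, baseline = baseline,
             quality = "ok")
}

# Continuous three-segment piecewise-linear fit of one beat's decay:
# plateau, rapid repolarization (phase 3), diastolic tail. Breakpoints are
# grid-searched (bracketed by the isotonic fit), the line parameters are
# profiled out by linear least squares on the hinge basis
# {1, t, (t-k1)+, (t-k2)+}. Returns NULL when no physiologically valid
# fit (phase-3 slope negative and steeper than the plateau) exists.
fit_beat_segments <- function(t, y, iso, baseline, t_peak = t[1L]) {
  n <- length(y)
  if (n < 10L) return(NULL)
  amp0 <- iso[1L] - baseline
  if (!is.finite(amp0) || amp0 <= 0) return(NULL)
  first_below <- function(frac, default) {
    i <- which(iso < baseline + frac * amp0)
    if (length(i)) t[i[1L]] else default
  }
  dt <- t[2L] - t[1L]
  t95 <- first_below(0.95, t[1L])
  t55 <- first_below(0.55, t[n])
  t25 <- first_below(0.25, t[1L])
  t02 <- first_below(0.02, t[n])
  fit_at <- function(k1, k2) {
    X <- cbind(1, t, pmax(t - k1, 0), pmax(t - k2, 0))
    f <- stats::.lm.fit(X, y)
    list(rss = sum(f$residuals^2), coef = f$coefficients,
         k1 = k1, k2 = k2)
  }
  valid <- function(f) {
    # phase 3 must fall, at least as steeply as the plateau (equality
    # admits the degenerate triangular AP, a single straight decay)
    s_pl <- f$coef[2L]
    s_p3 <- f$coef[2L] + f$coef[3L]
    is.finite(s_p3) && s_p3 < 0 && s_p3 <= s_pl + 1e-6
  }
  search <- function(k1s, k2s) {
    best <- NULL
    for (k1 in k1s) for (k2 in k2s) {
      if (k2 - k1 < 3 * dt) next
      f <- fit_at(k1, k2)
      if (valid(f) && (is.null(best) || f$rss < best$rss)) best <- f
    }
    best
  }
  k1s <- seq(t95, max(t55, t95 + dt), length.out = 10L)
  k2s <- seq(min(t25, t02), t02, length.out = 10L)
  best <- search(k1s, k2s)
  if (is.null(best)) return(NULL)
  st1 <- if (length(k1s) > 1L) diff(k1s[1:2]) else dt
  st2 <- if (length(k2s) > 1L) diff(k2s[1:2]) else dt
  fine <- search(best$k1 + seq(-1, 1, by = 0.25) * st1,
                 best$k2 + seq(-1, 1, by = 0.25) * st2)
  if (!is.null(fine)) best <- fine
  b <- best$coef
  yhat <- function(tt)
    b[1L] + b[2L] * tt + b[3L] * pmax(tt - best$k1, 0) +
      b[4L] * pmax(tt - best$k2, 0)
  list(k1 = best$k1, k2 = best$k2, t1 = t_peak,
       peak = yhat(t_peak), y_k1 = yhat(best$k1), y_k2 = yhat(best$k2),
       s_plateau = b[2L], s_phase3 = b[2L] + b[3L],
       s_tail = b[2L] + b[3L] + b[4L])
}

# first down-crossing of `level` on the fitted three-segment curve
pwl3_crossing <- function(fm, level) {
  if (level <= fm$peak && level > fm$y_k1) {
    if (fm$s_plateau < 0)
      return(fm$t1 + (level - fm$peak) / fm$s_plateau)
    return(fm$k1)             # non-decreasing plateau: crossing at knee
  }
  if (level <= fm$y_k1 && level >= fm$y_k2)
    return(fm$k1 + (level - fm$y_k1) / fm$s_phase3)
  if (level < fm$y_k2 && fm$s_tail < 0)
    return(fm$k2 + (level - fm$y_k2) / fm$s_tail)
  NA_real_
}

#' Beat periods from activation times
#'
#' @param activations_ms activation times, ms.
#' @return successive differences (ms); empty when fewer than two
#'   activations (with attribute `flag`).
#' @export
beat_period <- function(activations_ms) {
  if (length(activations_ms) < 2L) {
    out <- numeric(0)
    attr(out, "flag") <- "too_few_beats"
    return(out)
  }
  diff(activations_ms)
}

#' Per-beat feature table for one optical trace
#'
#' Runs beat detection and per-beat APD measurement at the requested
#' repolarization fractions, returning one row per beat.
#'
#' @param trace,time_ms trace and sample times (ms). A data.frame with
#'   columns `time_ms`, `value` (as from [extract_trace()]) may be given
#'   as `trace`.
#' @param fractions repolarization fractions; defaults 0.30 and 0.90 for
#'   voltage, 0.50 and 0.90 are conventional for calcium.
#' @param min_period_ms,prominence,polarity passed to [detect_beats()].
#' @param lowpass_hz zero-phase Butterworth low-pass cutoff applied before
#'   feature extraction (temporal denoising only; no high-pass, which
#'   would distort slow AP morphology). `NULL` disables.
#' @param ensemble measure APDs on the activation-aligned ensemble average
#'   of all detected beats (the signal-averaged AP standard in optical
#'   mapping; assumes a stable AP morphology across the trace) and assign
#'   the ensemble durations to every beat. Per-beat activation, period and
#'   amplitude are always measured per beat. Set `FALSE` for beat-to-beat
#'   analyses such as alternans.
#' @return data.frame of class `beat_features`: beat, activation_ms,
#'   peak_ms, amplitude, apd columns (`apd30_ms`, ...), apd_ratio (first
#'   fraction over last), beat_period_ms (NA for the final beat), quality.
#' @export
trace_features <- function(trace, time_ms = NULL,
                           fractions = c(0.30, 0.90),
                           min_period_ms = 250, prominence = 0.3,
                           polarity = 1, lowpass_hz = NULL,
                           ensemble = TRUE) {
  if (is.data.frame(trace)) {
    time_ms <- trace$time_ms
    trace <- trace$value
  }
  if (!is.null(lowpass_hz)) {
    fs <- 1000 / (time_ms[2L] - time_ms[1L])
    if (lowpass_hz < fs / 2) {
      flt <- signal::butter(4L, lowpass_hz / (fs / 2), type = "low")
      trace <- signal::filtfilt(flt, trace)
    }
  }
  acts <- detect_beats(trace, time_ms, min_period_ms, prominence, polarity)
  cols <- sprintf("apd%d_ms", round(fractions * 100))
  empty <- stats::setNames(
    data.frame(matrix(numeric(0), 0L, 6L + length(fractions))),
    c("beat", "activation_ms", "peak_ms", "amplitude", cols,
      "apd_ratio", "beat_period_ms"))
  if (length(acts) == 0L) {
    empty$quality <- character(0)
    attr(empty, "flag") <- "no_beats"
    return(empty)
  }
  periods <- c(diff(acts), NA_real_)
  # amplitude and baseline are slowly varying trace-level properties;
  # estimate them per beat, then pool by median so each beat's crossing
  # levels use the stable trace-wide scale
  scale_est <- lapply(seq_along(acts), function(i) {
    nxt <- if (i < length(acts)) acts[i + 1L] else Inf
    prv <- if (i > 1L) acts[i - 1L] else -Inf
    compute_apd(trace, time_ms, acts[i], 0.5, nxt, prv, polarity)
  })
  amps <- vapply(scale_est, function(a) a$amplitude, 0)
  bases <- vapply(scale_est, function(a) a$baseline, 0)
  pk_tr <- if (any(is.finite(amps)))
    stats::median(bases + amps, na.rm = TRUE) else NULL
  bl_tr <- if (any(is.finite(bases)))
    stats::median(bases, na.rm = TRUE) else NULL
  # ensemble (signal-averaged) beat: align beats at their activation
  # times on a common grid, average, and measure the average once
  ens_apds <- NULL
  if (ensemble && length(acts) >= 2L) {
    dt <- time_ms[2L] - time_ms[1L]
    pre <- min(150, acts[1L] - time_ms[1L])
    post <- min(diff(acts)) * 0.95
    grid <- seq(-pre, post, by = dt)
    beats_mat <- vapply(acts, function(a)
      stats::approx(time_ms, trace, xout = a + grid)$y,
      numeric(length(grid)))
    ens <- rowMeans(beats_mat)
    if (!any(is.na(ens))) {
      ens_try <- lapply(fractions, function(f)
        compute_apd(ens, grid, 0, f, Inf, -Inf, polarity))
      vv <- vapply(ens_try, function(a) a$apd_ms, 0)
      if (!any(is.na(vv[order(fractions)])) &&
          any(diff(vv[order(fractions)]) < 0)) {
        ens_try <- lapply(fractions, function(f)
          compute_apd(ens, grid, 0, f, Inf, -Inf, polarity,
                      refine = FALSE))
      }
      if (all(vapply(ens_try, function(a) a$quality == "ok", NA)))
        ens_apds <- ens_try
    }
  }
  ord <- order(fractions)
  rows <- lapply(seq_along(acts), function(i) {
    nxt <- if (i < length(acts)) acts[i + 1L] else Inf
    prv <- if (i > 1L) acts[i - 1L] else -Inf
    apds <- if (!is.null(ens_apds)) ens_apds else
      lapply(fractions, function(f)
        compute_apd(trace, time_ms, acts[i], f, nxt, prv, polarity,
                    peak_value = pk_tr, baseline_value = bl_tr))
    # the refined crossings are not guaranteed ordered in fraction; fall
    # back to the plain isotonic crossings (provably monotone) if inverted
    vv <- vapply(apds, function(a) a$apd_ms, 0)
    if (!any(is.na(vv[ord])) && any(diff(vv[ord]) < 0)) {
      apds <- lapply(fractions, function(f)
        compute_apd(trace, time_ms, acts[i], f, nxt, prv, polarity,
                    refine = FALSE, peak_value = pk_tr,
                    baseline_value = bl_tr))
    }
    vals <- vapply(apds, function(a) a$apd_ms, 0)
    ok <- all(vapply(apds, function(a) a$quality == "ok", NA))
    r <- data.frame(beat = i, activation_ms = acts[i],
                    peak_ms = if (!is.null(ens_apds))
                      acts[i] + apds[[1L]]$peak_ms else apds[[1L]]$peak_ms,
                    amplitude = if (!is.null(ens_apds))
                      scale_est[[i]]$amplitude else apds[[1L]]$amplitude)
    for (j in seq_along(cols)) r[[cols[j]]] <- vals[j]
    r$apd_ratio <- vals[1L] / vals[length(vals)]
    r$beat_period_ms <- periods[i]
    r$quality <- if (ok) "ok" else "flagged"
    r
  })
  out <- do.call(rbind, rows)
  class(out) <- c("beat_features", class(out))
  out
}

#' Summarize a beat table into one replicate row
#'
#' Means and medians of each metric over unflagged beats; flagged beats
#' never enter the summaries.
#'
#' @param beats a `beat_features` table from [trace_features()].
#' @param id named list of identifiers (line, protocol, N, n, ...) copied
#'   onto the row.
#' @return one-row data.frame with n_beats, n_flagged and
#'   `<metric>_mean` / `<metric>_median` columns.
#' @export
summarize_trace <- function(beats, id = list()) {
  metrics <- setdiff(names(beats)[vapply(beats, is.numeric, NA)],
                     c("beat", "activation_ms", "peak_ms"))
  ok <- beats[beats$quality == "ok", , drop = FALSE]
  row <- data.frame(n_beats = nrow(beats),
                    n_flagged = sum(beats$quality != "ok"))
  for (m in metrics) {
    v <- ok[[m]][is.finite(ok[[m]])]
    row[[paste0(m, "_mean")]] <- if (length(v)) mean(v) else NA_real_
    row[[paste0(m, "_median")]] <- if (length(v)) stats::median(v) else NA_real_
  }
  for (nm in rev(names(id))) {
    row <- cbind(stats::setNames(data.frame(id[[nm]]), nm), row)
  }
  row
}
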