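#' Electrode-grid electrogram container
#'
#' Per-electrode extracellular traces sampled on a common clock, with grid
#' geometry. Electrodes are named `r{row}c{col}`.
#'
#' @param time_ms sample times, ms (uniform).
#' @param traces numeric matrix, one column per electrode.
#' @param geometry data.frame with `electrode`, `row`, `col` and physical
#'   `x_mm`, `y_mm` positions.
#' @param pitch_mm electrode pitch, mm (> 0).
#' @param quality per-electrode quality flag ("ok" or "flat").
#' @param metadata free-form list (well, protocol label, condition, ...).
#' @return object of class `electrogram_set`.
#' @export
electrogram_set <- function(time_ms, traces, geometry, pitch_mm,
                            quality = NULL, metadata = list()) {
  traces <- as.matrix(traces)
  if (length(time_ms) != nrow(traces))
    stop("time_ms length must match trace length", call. = FALSE)
  if (pitch_mm <= 0) stop("pitch_mm must be positive", call. = FALSE)
  dtv <- diff(time_ms)
  if (any(abs(dtv - dtv[1L]) > 1e-6))
    stop("sampling must be uniform", call. = FALSE)
  if (is.null(colnames(traces))) colnames(traces) <- geometry$electrode
  if (is.null(quality)) quality <- rep("ok", ncol(traces))
  structure(list(time_ms = time_ms, traces = traces, geometry = geometry,
                 pitch_mm = pitch_mm, sample_interval_ms = dtv[1L],
                 quality = quality, metadata = metadata),
            class = "electrogram_set")
}

#' @export
print.electrogram_set <- function(x, ...) {
  cat(sprintf("<electrogram_set> %d electrodes, %.0f ms @ %g ms/sample\n",
              ncol(x$traces), max(x$time_ms), x$sample_interval_ms))
  invisible(x)
}

#' Detect depolarization spikes in one electrogram trace
#'
#' Finds the biphasic depolarization complexes: candidate samples where the
#' absolute derivative exceeds `k_mad` times its median absolute deviation,
#' grouped into events separated by at least `min_period_ms`. The spike
#' time is the extremum of the absolute derivative within the event;
#' amplitude is local max minus local min within a +/- `window_ms` window.
#'
#' @param trace numeric vector, microvolts.
#' @param time_ms sample times, ms.
#' @param min_period_ms minimum spacing between spikes, ms.
#' @param k_mad adaptive threshold multiplier on the derivative MAD.
#' @param window_ms half-width of the amplitude window, ms.
#' @return data.frame: spike_time_ms, amplitude_uv, quality. Zero rows
#'   (with a "no_spikes" attribute flag) when nothing crosses threshold.
#' @export
detect_spikes <- function(trace, time_ms, min_period_ms = 250,
                          k_mad = 8, window_ms = 10) {
  dt <- time_ms[2L] - time_ms[1L]
  dv <- abs(diff(trace)) / dt
  # MAD-based adaptive threshold, floored at a fraction of the largest
  # deflection so that near-noiseless traces do not admit every sample
  thr <- max(k_mad * stats::mad(dv), 0.25 * max(dv))
  empty <- data.frame(spike_time_ms = numeric(), amplitude_uv = numeric(),
                      quality = character())
  if (!is.finite(thr) || thr <= 0 || !any(dv > thr)) {
    attr(empty, "flag") <- "no_spikes"
    return(empty)
  }
  cand <- which(dv > thr)
  splits <- c(0L, which(diff(time_ms[cand]) > min_period_ms), length(cand))
  rows <- lapply(seq_len(length(splits) - 1L), function(i) {
    ix <- cand[(splits[i] + 1L):splits[i + 1L]]
    peak <- ix[which.max(dv[ix])]
    # dv[i] sits at the interval midpoint; a parabola through the three
    # derivative magnitudes refines the spike time below one sample
    t0 <- time_ms[peak] + dt / 2
    if (peak > 1L && peak < length(dv)) {
      den <- dv[peak - 1L] - 2 * dv[peak] + dv[peak + 1L]
      if (is.finite(den) && den < 0) {
        delta <- 0.5 * (dv[peak - 1L] - dv[peak + 1L]) / den
        if (abs(delta) <= 1) t0 <- t0 + delta * dt
      }
    }
    w <- which(time_ms >= t0 - window_ms & time_ms <= t0 + window_ms)
    data.frame(spike_time_ms = t0,
               amplitude_uv = max(trace[w]) - min(trace[w]),
               quality = "ok")
  })
  out <- do.call(rbind, rows)
  # merge residual near-duplicates, keeping the larger amplitude
  if (nrow(out) > 1L) {
    keep <- rep(TRUE, nrow(out))
    for (i in 2:nrow(out)) {
      if (out$spike_time_ms[i] - out$spike_time_ms[max(which(keep[1:(i - 1)]))] <
          min_period_ms) {
        j <- max(which(keep[1:(i - 1)]))
        if (out$amplitude_uv[i] > out$amplitude_uv[j]) keep[j] <- FALSE
        else keep[i] <- FALSE
      }
    }
    out <- out[keep, , drop = FALSE]
  }
  rownames(out) <- NULL
  out
}

#' Field-potential duration of one beat
#'
#' FPD is the interval from the depolarization spike to the repolarization
#' deflection, located as the largest absolute excursion from the local
#' baseline inside the search window `(spike + blanking, next spike -
#' margin)`; the extremum is refined to sub-sample precision by parabolic
#' interpolation. The measurement is polarity-agnostic: positive and
#' inverted T-waves give the same duration.
#'
#' @param trace,time_ms electrogram trace and sample times (ms).
#' @param spike_time_ms this beat's spike time.
#' @param next_spike_time_ms following spike time (or `Inf` for the last
#'   beat; then the window ends at the trace end).
#' @param blanking_ms dead time after the spike excluded from the search.
#' @param margin_ms guard interval before the next spike.
#' @param noise_floor_uv minimum T-wave excursion; below it the beat is
#'   flagged missing.
#' @return one-row data.frame: fpd_ms, t_wave_amp_uv, quality.
#' @export
measure_fpd <- function(trace, time_ms, spike_time_ms,
                        next_spike_time_ms = Inf, blanking_ms = 50,
                        margin_ms = 50, noise_floor_uv = 10) {
  lo <- spike_time_ms + blanking_ms
  hi <- min(next_spike_time_ms - margin_ms, max(time_ms))
  w <- which(time_ms >= lo & time_ms <= hi)
  miss <- data.frame(fpd_ms = NA_real_, t_wave_amp_uv = NA_real_,
                     quality = "no_t_wave")
  if (length(w) < 3L) return(miss)
  seg <- trace[w]
  base <- stats::median(seg)
  exc <- abs(seg - base)
  i <- which.max(exc)
  if (exc[i] < noise_floor_uv) return(miss)
  t_peak <- time_ms[w[i]]
  if (i > 1L && i < length(seg)) {           # parabolic refinement
    y1 <- exc[i - 1L]; y2 <- exc[i]; y3 <- exc[i + 1L]
    den <- y1 - 2 * y2 + y3
    if (abs(den) > 1e-12) {
      delta <- 0.5 * (y1 - y3) / den
      t_peak <- t_peak + delta * (time_ms[2L] - time_ms[1L])
    }
  }
  data.frame(fpd_ms = t_peak - spike_time_ms, t_wave_amp_uv = exc[i],
             quality = "ok")
}

#' Fridericia rate correction of field-potential duration
#'
#' `FPDc = FPD / (RR / 1000)^(1/3)` with the beat period RR expressed in
#' seconds, the standard cube-root rate correction.
#'
#' @param fpd_ms field-potential duration, ms (> 0).
#' @param beat_period_ms beat period, ms (> 0).
#' @return corrected duration, ms.
#' @examples
#' fridericia(270, 729)  # 300: 0.729^(1/3) = 0.9 exactly
#' fridericia(300, 8000) # 150: 8^(1/3) = 2
#' @export
fridericia <- function(fpd_ms, beat_period_ms) {
  if (any(fpd_ms <= 0, na.rm = TRUE) ||
      any(beat_period_ms <= 0, na.rm = TRUE))
    stop("fpd_ms and beat_period_ms must be positive", call. = FALSE)
  fpd_ms / (beat_period_ms / 1000)^(1 / 3)
}

#' Conduction velocity by plane fit of activation times
#'
#' Fits `t(x, y) = t0 + p x + q y` by least squares over electrode
#' positions (mm); the wave speed is `1 / sqrt(p^2 + q^2)` in mm/ms,
#' reported in cm/s, and the direction is the unit gradient. With several
#' beats, each beat is fitted separately and the estimates averaged.
#'
#' @param activations data.frame with columns `x_mm`, `y_mm`, `t_ms` and
#'   optionally `beat` (integer beat index).
#' @param v_max_cm_s gradients shallower than this ceiling (near-
#'   simultaneous activation) are flagged unresolvable.
#' @return object of class `conduction_estimate`: velocity_cm_s, direction
#'   (unit vector), residual_rms_ms, n_electrodes, quality.
#' @export
conduction_velocity <- function(activations, v_max_cm_s = 1000) {
  stopifnot(all(c("x_mm", "y_mm", "t_ms") %in% names(activations)))
  acts <- activations[is.finite(activations$t_ms), , drop = FALSE]
  if (is.null(acts$beat)) acts$beat <- 1L
  fits <- lapply(split(acts, acts$beat), function(b) {
    if (nrow(b) < 3L) return(NULL)
    if (qr(cbind(1, b$x_mm, b$y_mm))$rank < 3L)
      stop("electrode positions are collinear; plane fit is degenerate",
           call. = FALSE)
    fit <- stats::lm(t_ms ~ x_mm + y_mm, data = b)
    p <- coef(fit)[["x_mm"]]; q <- coef(fit)[["y_mm"]]
    g <- sqrt(p^2 + q^2)                       # ms/mm
    list(g = g, p = p, q = q,
         rms = sqrt(mean(stats::residuals(fit)^2)), n = nrow(b))
  })
  fits <- Filter(Negate(is.null), fits)
  if (length(fits) == 0L)
    stop("need at least 3 electrodes with activation times", call. = FALSE)
  g <- mean(vapply(fits, `[[`, 0, "g"))
  if (g < 100 / v_max_cm_s) {  # gradient implies v > v_max: unresolvable
    return(structure(list(velocity_cm_s = NA_real_, direction = c(NA, NA),
                          residual_rms_ms = NA_real_,
                          n_electrodes = fits[[1L]]$n,
                          quality = "unresolvable"),
                     class = "conduction_estimate"))
  }
  v <- 100 / g                                  # mm/ms -> cm/s
  p <- mean(vapply(fits, `[[`, 0, "p"))
  q <- mean(vapply(fits, `[[`, 0, "q"))
  structure(list(velocity_cm_s = v,
                 direction = c(p, q) / sqrt(p^2 + q^2),
                 residual_rms_ms = mean(vapply(fits, `[[`, 0, "rms")),
                 n_electrodes = fits[[1L]]$n, quality = "ok"),
            class = "conduction_estimate")
}

#' @export
print.conduction_estimate <- function(x, ...) {
  cat(sprintf("<conduction_estimate> %.1f cm/s (residual %.2f ms RMS, %d electrodes)\n",
              x$velocity_cm_s, x$residual_rms_ms, x$n_electrodes))
  invisible(x)
}

#' Field-potential feature table for an electrogram set
#'
#' Runs spike detection, FPD measurement and Fridericia correction on every
#' electrode and returns a tidy beat x electrode table.
#'
#' @param eset an [electrogram_set()].
#' @param min_period_ms minimum beat spacing for spike detection, ms.
#' @param ... passed to [measure_fpd()].
#' @return data.frame: electrode, beat, spike_time_ms, amplitude_uv,
#'   beat_period_ms, fpd_ms, fpdc_ms, quality.
#' @export
fp_features <- function(eset, min_period_ms = 250, ...) {
  stopifnot(inherits(eset, "electrogram_set"))
  rows <- lapply(colnames(eset$traces), function(el) {
    tr <- eset$traces[, el]
    sp <- detect_spikes(tr, eset$time_ms, min_period_ms = min_period_ms)
    if (nrow(sp) == 0L) return(NULL)
    nb <- nrow(sp)
    per <- c(diff(sp$spike_time_ms), NA_real_)
    fpd <- do.call(rbind, lapply(seq_len(nb), function(i) {
      nxt <- if (i < nb) sp$spike_time_ms[i + 1L] else Inf
      measure_fpd(tr, eset$time_ms, sp$spike_time_ms[i], nxt, ...)
    }))
    data.frame(electrode = el, beat = seq_len(nb),
               spike_time_ms = sp$spike_time_ms,
               amplitude_uv = sp$amplitude_uv,
               beat_period_ms = per, fpd_ms = fpd$fpd_ms,
               fpdc_ms = ifelse(is.finite(fpd$fpd_ms) & is.finite(per),
                                fridericia(pmax(fpd$fpd_ms, 1e-9),
                                           pmax(per, 1e-9)), NA_real_),
               quality = ifelse(fpd$quality == "ok" & sp$quality == "ok",
                                "ok", "flagged"))
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(electrode = character(), beat = integer(),
                      spike_time_ms = numeric(), amplitude_uv = numeric(),
                      beat_period_ms = numeric(), fpd_ms = numeric(),
                      fpdc_ms = numeric(), quality = character())
  rownames(out) <- NULL
  out
}

#' Vehicle-adjusted paired drug deltas
#'
#' For each metric m the drug effect is reported as the ratio-of-ratios
#' `delta = (m_post / m_pre) / (vehicle_post / vehicle_pre)`, so that any
#' time drift shared with the vehicle wells cancels; absolute differences
#' `m_post - m_pre` are reported alongside. Electrodes must match across
#' the four recordings.
#'
#' @param pre,post,vehicle_pre,vehicle_post per-electrode summary
#'   data.frames with an `electrode` column and numeric metric columns.
#' @param metrics metric columns to compare; default the numeric
#'   intersection of all four tables.
#' @return list with `by_electrode` (electrode x metric rows: ratio delta
#'   and absolute difference) and `summary` (per-metric median delta).
#' @export
paired_drug_delta <- function(pre, post, vehicle_pre, vehicle_post,
                              metrics = NULL) {
  tabs <- list(pre = pre, post = post, vpre = vehicle_pre,
               vpost = vehicle_post)
  for (nm in names(tabs))
    if (!"electrode" %in% names(tabs[[nm]]))
      stop("each table needs an electrode column", call. = FALSE)
  ids <- lapply(tabs, function(t) sort(t$electrode))
  if (!all(vapply(ids[c("pre", "post")], identical, NA, ids$pre)))
    stop(sprintf("unmatched electrodes between pre and post: %s",
                 paste(symdiff_chr(ids$pre, ids$post), collapse = ", ")),
         call. = FALSE)
  if (is.null(metrics)) {
    num <- function(t) names(t)[vapply(t, is.numeric, NA)]
    metrics <- Reduce(intersect, lapply(tabs, num))
  }
  veh_ratio <- vapply(metrics, function(m) {
    stats::median(tabs$vpost[[m]], na.rm = TRUE) /
      stats::median(tabs$vpre[[m]], na.rm = TRUE)
  }, 0)
  ord <- order(tabs$pre$electrode)
  pre_o <- tabs$pre[ord, ]; post_o <- tabs$post[order(tabs$post$electrode), ]
  by_el <- do.call(rbind, lapply(metrics, function(m) {
    data.frame(electrode = pre_o$electrode, metric = m,
               pre = pre_o[[m]], post = post_o[[m]],
               ratio_delta = (post_o[[m]] / pre_o[[m]]) / veh_ratio[[m]],
               abs_diff = post_o[[m]] - pre_o[[m]])
  }))
  summ <- do.call(rbind, lapply(metrics, function(m) {
    d <- by_el[by_el$metric == m, ]
    data.frame(metric = m,
               median_ratio_delta = stats::median(d$ratio_delta, na.rm = TRUE),
               median_abs_diff = stats::median(d$abs_diff, na.rm = TRUE))
  }))
  list(by_electrode = by_el, summary = summ)
}

symdiff_chr <- function(a, b) union(setdiff(a, b), setdiff(b, a))
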