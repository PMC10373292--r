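#' Link per-frame phase-singularity detections into tracks
#'
#' Greedy nearest-neighbor linking: detections in consecutive frames are
#' joined when they share chirality and lie within `max_link_px`; closest
#' pairs are linked first. A track missing from up to `max_gap_frames`
#' consecutive frames may be resumed. Lifetime is
#' `(last frame - first frame) * frame_interval_ms`.
#'
#' @param detections data.frame from [detect_singularities_movie()]
#'   (columns frame, row, col, chirality).
#' @param max_link_px maximum frame-to-frame displacement, pixels.
#' @param max_gap_frames frames a track may vanish and still be resumed.
#' @param frame_interval_ms frame interval used for lifetimes, ms.
#' @return data.frame of detections with a `track_id` column; summary per
#'   track available via [track_summary()].
#' @export
track_singularities <- function(detections, max_link_px = 10,
                                max_gap_frames = 2L,
                                frame_interval_ms = 5) {
  det <- detections[order(detections$frame), , drop = FALSE]
  if (nrow(det) == 0L) {
    det$track_id <- integer(0)
    attr(det, "frame_interval_ms") <- frame_interval_ms
    return(det)
  }
  det$track_id <- NA_integer_
  # active tracks: id, last frame, last row/col, chirality
  active <- data.frame(id = integer(), frame = integer(), row = numeric(),
                       col = numeric(), chirality = integer())
  next_id <- 1L
  for (f in sort(unique(det$frame))) {
    active <- active[f - active$frame <= max_gap_frames + 1L, , drop = FALSE]
    idx <- which(det$frame == f)
    if (nrow(active) > 0L && length(idx) > 0L) {
      # candidate links sorted by distance, same chirality only
      cand <- expand.grid(a = seq_len(nrow(active)), d = seq_along(idx))
      cand$dist <- sqrt((active$row[cand$a] - det$row[idx[cand$d]])^2 +
                        (active$col[cand$a] - det$col[idx[cand$d]])^2)
      cand <- cand[cand$dist <= max_link_px &
                     active$chirality[cand$a] ==
                       det$chirality[idx[cand$d]], , drop = FALSE]
      cand <- cand[order(cand$dist), , drop = FALSE]
      used_a <- logical(nrow(active)); used_d <- logical(length(idx))
      for (i in seq_len(nrow(cand))) {
        a <- cand$a[i]; dd <- cand$d[i]
        if (used_a[a] || used_d[dd]) next
        used_a[a] <- TRUE; used_d[dd] <- TRUE
        det$track_id[idx[dd]] <- active$id[a]
        active$frame[a] <- f
        active$row[a] <- det$row[idx[dd]]
        active$col[a] <- det$col[idx[dd]]
      }
    }
    new <- idx[is.na(det$track_id[idx])]
    for (dd in new) {
      det$track_id[dd] <- next_id
      active <- rbind(active,
                      data.frame(id = next_id, frame = f,
                                 row = det$row[dd], col = det$col[dd],
                                 chirality = det$chirality[dd]))
      next_id <- next_id + 1L
    }
  }
  attr(det, "frame_interval_ms") <- frame_interval_ms
  det
}

#' Per-track summary of singularity tracks
#'
#' @param tracked output of [track_singularities()].
#' @return data.frame: track_id, chirality, first_frame, last_frame,
#'   n_detections, lifetime_ms, mean_step_px.
#' @export
track_summary <- function(tracked) {
  dt <- attr(tracked, "frame_interval_ms") %||% 5
  if (nrow(tracked) == 0L)
    return(data.frame(track_id = integer(), chirality = integer(),
                      first_frame = integer(), last_frame = integer(),
                      n_detections = integer(), lifetime_ms = numeric(),
                      mean_step_px = numeric()))
  out <- do.call(rbind, lapply(split(tracked, tracked$track_id), function(d) {
    d <- d[order(d$frame), ]
    step <- if (nrow(d) > 1L)
      mean(sqrt(diff(d$row)^2 + diff(d$col)^2) / diff(d$frame)) else NA_real_
    data.frame(track_id = d$track_id[1L], chirality = d$chirality[1L],
               first_frame = min(d$frame), last_frame = max(d$frame),
               n_detections = nrow(d),
               lifetime_ms = (max(d$frame) - min(d$frame)) * dt,
               mean_step_px = step)
  }))
  rownames(out) <- NULL
  out[order(-out$lifetime_ms), ]
}

#' Extract activation wavefronts from a phase movie
#'
#' Per frame, marks pixels where the wrapped difference `phase - phi_act`
#' changes sign between 4-neighbors (the activation isophase passes
#' between them), keeps 8-connected components of at least `min_size`
#' pixels, and links components across frames by pixel overlap. Death
#' causes are classified as `"boundary"` (last component touches the mask
#' edge), `"singularity"` (endpoint within `ps_radius_px` of a supplied PS
#' detection) or `"collision"` otherwise.
#'
#' @param pmovie a `phase_movie`.
#' @param phi_act activation isophase, radians.
#' @param min_size minimum component size, pixels.
#' @param ps_detections optional PS table used for death-cause labelling.
#' @param ps_radius_px distance defining "terminates on a singularity".
#' @param include_untrusted analyze flagged edge frames too.
#' @return list with `fronts` (data.frame: frame, front_id, n_pixels) and
#'   `tracks` (data.frame: front_track_id, first_frame, last_frame,
#'   lifetime_ms, death_cause).
#' @export
extract_wavefronts <- function(pmovie, phi_act = pi / 2, min_size = 5L,
                               ps_detections = NULL, ps_radius_px = 4,
                               include_untrusted = FALSE) {
  stopifnot(inherits(pmovie, "phase_movie"))
  Tn <- dim(pmovie$phase)[1L]
  H <- dim(pmovie$phase)[2L]; W <- dim(pmovie$phase)[3L]
  frames <- seq_len(Tn)
  if (!include_untrusted)
    frames <- setdiff(frames, pmovie$untrusted_frames)
  comp_stack <- vector("list", Tn)
  front_rows <- list()
  for (t in frames) {
    d <- wrap_phase(pmovie$phase[t, , ] - phi_act)
    d[!pmovie$mask] <- NA
    # activation crossing between 4-neighbors: sign change with small |d|
    # on at least one side (excludes the pi anti-isophase)
    cross <- matrix(FALSE, H, W)
    sgn <- sign(d)
    near <- abs(d) < pi / 2
    right <- sgn[, -W] * sgn[, -1L] < 0 & (near[, -W] | near[, -1L])
    down <- sgn[-H, ] * sgn[-1L, ] < 0 & (near[-H, ] | near[-1L, ])
    cross[, -W] <- cross[, -W] | (right & !is.na(right))
    cross[-H, ] <- cross[-H, ] | (down & !is.na(down))
    cross[is.na(d)] <- FALSE
    lab <- label_components(cross)
    if (max(lab) > 0L) {
      sizes <- tabulate(lab[lab > 0L])
      keep <- which(sizes >= min_size)
      lab[!(lab %in% keep)] <- 0L
      relab <- match(lab, sort(unique(lab[lab > 0L])))
      lab <- matrix(ifelse(is.na(relab), 0L, relab), H, W)
    }
    comp_stack[[t]] <- lab
    if (max(lab) > 0L)
      front_rows[[length(front_rows) + 1L]] <-
        data.frame(frame = t, front_id = seq_len(max(lab)),
                   n_pixels = tabulate(lab[lab > 0L]))
  }
  fronts <- do.call(rbind, front_rows)
  if (is.null(fronts))
    fronts <- data.frame(frame = integer(), front_id = integer(),
                         n_pixels = integer())

  # link components across consecutive analyzed frames by overlap
  track_of <- list()      # per frame: component id -> track id
  next_tr <- 1L
  tr_first <- integer(); tr_last <- integer(); tr_lastlab <- list()
  fr_sorted <- frames[frames %in% which(!vapply(comp_stack, is.null, NA))]
  prev_t <- NA_integer_
  for (t in fr_sorted) {
    lab <- comp_stack[[t]]
    ncomp <- max(lab)
    ids <- integer(ncomp)
    if (!is.na(prev_t) && t - prev_t == 1L) {
      # dilate the previous frame's labels so fronts moving a few pixels
      # per frame still overlap their successors
      plab <- dilate_labels(comp_stack[[prev_t]], 2L)
      ptr <- track_of[[prev_t]]
      for (g in seq_len(ncomp)) {
        ov <- plab[lab == g]
        ov <- ov[ov > 0L]
        if (length(ov) > 0L) {
          ids[g] <- ptr[as.integer(names(which.max(table(ov))))]
        }
      }
    }
    for (g in seq_len(ncomp)) {
      if (ids[g] == 0L) {
        ids[g] <- next_tr
        tr_first[next_tr] <- t
        next_tr <- next_tr + 1L
      }
      tr_last[ids[g]] <- t
      # endpoint pixels per track, for death-cause classification
      tr_lastlab[[ids[g]]] <- which(lab == g, arr.ind = TRUE)
    }
    track_of[[t]] <- ids
    prev_t <- t
  }
  n_tr <- next_tr - 1L
  death <- character(n_tr)
  for (i in seq_len(n_tr)) {
    px <- tr_lastlab[[i]]
    if (is.null(px) || nrow(px) == 0L) { death[i] <- "collision"; next }
    on_edge <- any(px[, 1L] <= 1L | px[, 1L] >= H |
                   px[, 2L] <= 1L | px[, 2L] >= W)
    near_ps <- FALSE
    if (!is.null(ps_detections) && nrow(ps_detections) > 0L) {
      ps_f <- ps_detections[abs(ps_detections$frame - tr_last[i]) <= 1L, ,
                            drop = FALSE]
      if (nrow(ps_f) > 0L) {
        dmin <- min(outer(px[, 1L], ps_f$row, "-")^2 +
                      outer(px[, 2L], ps_f$col, "-")^2)
        near_ps <- sqrt(dmin) <= ps_radius_px
      }
    }
    death[i] <- if (near_ps) "singularity" else if (on_edge) "boundary"
      else "collision"
  }
  tracks <- data.frame(front_track_id = seq_len(n_tr),
                       first_frame = tr_first[seq_len(n_tr)],
                       last_frame = tr_last[seq_len(n_tr)],
                       lifetime_ms = (tr_last[seq_len(n_tr)] -
                                        tr_first[seq_len(n_tr)] + 1L) *
                         pmovie$frame_interval_ms,
                       death_cause = death)
  list(fronts = fronts, tracks = tracks)
}

# grow nonzero labels by `r` pixels (8-neighborhood); overlapping growth
# keeps the larger label id, which is immaterial for majority-overlap votes
dilate_labels <- function(lab, r = 1L) {
  H <- nrow(lab); W <- ncol(lab)
  for (i in seq_len(r)) {
    out <- lab
    for (dr in -1:1) for (dc in -1:1) {
      if (dr == 0L && dc == 0L) next
      rs <- pmin(pmax(seq_len(H) + dr, 1L), H)
      cs <- pmin(pmax(seq_len(W) + dc, 1L), W)
      out <- pmax(out, lab[rs, cs])
    }
    lab <- out
  }
  lab
}

#' Recording-level rotor summary
#'
#' Aggregates singularity tracks and wavefront tracks into the summary
#' statistics reported for reentry recordings: total detections, track
#' count, mean and SD singularity lifetime, mean and SD wavefront
#' lifetime, the fraction of analyzed frames covered by the dominant
#' track, and the per-frame singularity count series.
#'
#' @param tracked output of [track_singularities()].
#' @param wavefronts optional output of [extract_wavefronts()].
#' @param n_frames_analyzed number of trusted frames analyzed.
#' @return list of class `rotor_report`.
#' @export
rotor_report <- function(tracked, wavefronts = NULL,
                         n_frames_analyzed = NA_integer_) {
  ts <- track_summary(tracked)
  per_frame <- if (nrow(tracked) > 0L) table(tracked$frame) else table(integer())
  dom <- if (nrow(ts) > 0L)
    (ts$last_frame[1L] - ts$first_frame[1L] + 1L) / n_frames_analyzed
    else NA_real_
  wf <- if (!is.null(wavefronts)) wavefronts$tracks else NULL
  structure(list(
    total_detections = nrow(tracked),
    track_count = nrow(ts),
    singularity_lifetime_mean_ms = if (nrow(ts)) mean(ts$lifetime_ms) else NA_real_,
    singularity_lifetime_sd_ms = if (nrow(ts) > 1L) stats::sd(ts$lifetime_ms) else
      if (nrow(ts) == 1L) 0 else NA_real_,
    wavefront_lifetime_mean_ms = if (!is.null(wf) && nrow(wf))
      mean(wf$lifetime_ms) else NA_real_,
    wavefront_lifetime_sd_ms = if (!is.null(wf) && nrow(wf) > 1L)
      stats::sd(wf$lifetime_ms) else if (!is.null(wf) && nrow(wf) == 1L) 0
      else NA_real_,
    dominant_track_fraction = dom,
    per_frame_counts = as.integer(per_frame),
    per_frame_index = as.integer(names(per_frame)),
    tracks = ts), class = "rotor_report")
}

#' @export
print.rotor_report <- function(x, ...) {
  cat(sprintf(paste0("<rotor_report> %d detections in %d tracks; ",
                     "PS lifetime %.0f +/- %.0f ms; ",
                     "wavefront lifetime %.1f +/- %.1f ms\n"),
              x$total_detections, x$track_count,
              x$singularity_lifetime_mean_ms,
              x$singularity_lifetime_sd_ms,
              x$wavefront_lifetime_mean_ms, x$wavefront_lifetime_sd_ms))
  invisible(x)
}
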