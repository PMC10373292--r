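#' Validate a pipeline run configuration
#'
#' A run configuration is a named list (typically parsed from YAML) with:
#' either a `simulation` block (`protocol`, `duration_ms`, optional
#' `grid`, `optics`) or an `inputs` block (paths to movie / electrogram
#' files); optional module parameter blocks `preprocess`, `ap`, `phase`,
#' `mea`; `stages` (subset of simulate/preprocess/ap/phase/mea/report);
#' `seed`; an `id` block (line, protocol label, N, n). Validation happens
#' before any computation.
#'
#' @param config named list.
#' @return the normalized config (class `run_config`).
#' @export
run_config <- function(config) {
  has_sim <- !is.null(config$simulation)
  has_in <- !is.null(config$inputs)
  if (has_sim == has_in)
    stop("config must have exactly one of: simulation, inputs",
         call. = FALSE)
  if (has_in) {
    paths <- unlist(config$inputs)
    missing <- paths[!file.exists(paths)]
    if (length(missing))
      stop("missing input file(s): ", paste(missing, collapse = ", "),
           call. = FALSE)
  }
  all_stages <- c("simulate", "preprocess", "ap", "phase", "mea", "report")
  stages <- config$stages %||% all_stages
  bad <- setdiff(stages, all_stages)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "), call. = FALSE)
  config$stages <- intersect(all_stages, stages)  # fixed execution order
  config$seed <- as.integer(config$seed %||% 1L)
  if (!is.null(config$preprocess))
    do.call(filter_spec, config$preprocess)       # bounds check only
  config$id <- config$id %||% list(line = "synthetic", protocol = "sim",
                                   N = 1L, n = 1L)
  structure(config, class = "run_config")
}

config_hash <- function(config) {
  tmp <- tempfile(fileext = ".yaml")
  on.exit(unlink(tmp))
  plain <- unclass(config)
  yaml::write_yaml(plain[order(names(plain))], tmp)
  unname(tools::md5sum(tmp))
}

#' Run the analysis pipeline
#'
#' Executes the requested stages in fixed order (simulate, preprocess, ap,
#' phase, mea, report), writing each stage's artifacts under `out_dir` and
#' a log (`run.log`) naming every stage, its parameters and the config
#' hash. Identical configurations and seeds produce byte-identical
#' outputs.
#'
#' @param config a [run_config()] or plain list (then validated here).
#' @param out_dir output directory, created if needed.
#' @return invisibly, a list with the stage artifacts and `config_hash`.
#' @export
run_pipeline <- function(config, out_dir) {
  cfg <- if (inherits(config, "run_config")) config else run_config(config)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  hash <- config_hash(cfg)
  logf <- file.path(out_dir, "run.log")
  logln <- function(...) cat(sprintf(...), "\n", sep = "",
                             file = logf, append = TRUE)
  cat(sprintf("config_hash: %s\n", hash), file = logf)
  res <- list(config_hash = hash)
  spec <- do.call(filter_spec, cfg$preprocess %||% list())

  movie <- NULL; eset <- NULL
  if ("simulate" %in% cfg$stages) {
    logln("stage simulate: seed=%d", cfg$seed)
    simc <- cfg$simulation
    par <- do.call(medium_params,
                   c(simc$grid %||% list(), list(seed = cfg$seed)))
    prot <- do.call(stimulus_protocol, simc$protocol)
    sim <- simulate_medium(par, prot, simc$duration_ms,
                           dt_save_ms = simc$dt_save_ms %||% 5)
    opt <- do.call(optics_model, simc$optics %||% list())
    movie <- render_movie(sim, opt, seed = cfg$seed)
    eset <- synth_electrograms(sim, noise_sd_uv = simc$egm_noise_uv %||% 0,
                               seed = cfg$seed + 1L)
    write_movie_tiff(movie, file.path(out_dir, "movie.tif"),
                     seed = cfg$seed)
    write_tip_csv(sim$ground_truth$tip_trajectory,
                  file.path(out_dir, "true_tips.csv"))
    write_electrograms_csv(eset, file.path(out_dir, "electrograms.csv"))
    res$sim <- sim
  } else if (!is.null(cfg$inputs)) {
    if (!is.null(cfg$inputs$movie)) movie <- read_movie_tiff(cfg$inputs$movie)
    if (!is.null(cfg$inputs$electrograms))
      eset <- read_electrograms_csv(cfg$inputs$electrograms)
  }

  if ("preprocess" %in% cfg$stages && !is.null(movie)) {
    logln("stage preprocess: band %g-%g Hz, sigma %g px, window %d",
          spec$band_low_hz, spec$band_high_hz, spec$gaussian_sigma_px,
          spec$norm_window_frames)
    movie <- preprocess_movie(movie, spec)
    res$movie <- movie
  }

  if ("ap" %in% cfg$stages && !is.null(movie)) {
    logln("stage ap")
    apc <- cfg$ap %||% list()
    d <- dim(movie$frames)
    roi <- apc$roi %||% list(row = max(1L, d[2L] %/% 4L),
                             col = max(1L, d[3L] %/% 4L),
                             height = d[2L] %/% 2L, width = d[3L] %/% 2L)
    tr <- extract_trace(movie, roi)
    beats <- trace_features(tr,
                            fractions = apc$fractions %||% c(0.30, 0.90),
                            min_period_ms = apc$min_period_ms %||% 250)
    utils::write.csv(cbind(beats, config_hash = hash),
                     file.path(out_dir, "ap_features.csv"),
                     row.names = FALSE)
    summ <- summarize_trace(beats, id = cfg$id)
    utils::write.csv(cbind(summ, config_hash = hash),
                     file.path(out_dir, "ap_summary.csv"),
                     row.names = FALSE)
    res$ap <- beats
  }

  if ("phase" %in% cfg$stages && !is.null(movie)) {
    logln("stage phase")
    phc <- cfg$phase %||% list()
    pm <- instantaneous_phase(movie)
    det <- detect_singularities_movie(pm,
      r_inner = phc$r_inner %||% 2L, r_outer = phc$r_outer %||% 4L)
    tracked <- track_singularities(det,
      max_link_px = phc$max_link_px %||% 10,
      max_gap_frames = phc$max_gap_frames %||% 2L,
      frame_interval_ms = pm$frame_interval_ms)
    wf <- extract_wavefronts(pm, ps_detections = det)
    n_tr <- dim(pm$phase)[1L] - length(pm$untrusted_frames)
    rep <- rotor_report(tracked, wf, n_frames_analyzed = n_tr)
    write_tip_csv(tracked, file.path(out_dir, "ps_tracks.csv"))
    jsonlite::write_json(c(unclass(rep)[c(
      "total_detections", "track_count",
      "singularity_lifetime_mean_ms", "singularity_lifetime_sd_ms",
      "wavefront_lifetime_mean_ms", "wavefront_lifetime_sd_ms",
      "dominant_track_fraction")], list(config_hash = hash)),
      file.path(out_dir, "rotor_report.json"), auto_unbox = TRUE,
      digits = NA)
    res$phase <- rep
  }

  if ("mea" %in% cfg$stages && !is.null(eset)) {
    logln("stage mea")
    fp <- fp_features(eset, min_period_ms = cfg$mea$min_period_ms %||% 250)
    utils::write.csv(cbind(fp, config_hash = hash),
                     file.path(out_dir, "fp_features.csv"),
                     row.names = FALSE)
    cvtab <- tryCatch({
      first <- fp[fp$beat == 1L & is.finite(fp$spike_time_ms), ]
      geo <- eset$geometry
      acts <- merge(first, geo, by = "electrode")
      cv <- conduction_velocity(data.frame(x_mm = acts$x_mm,
                                           y_mm = acts$y_mm,
                                           t_ms = acts$spike_time_ms))
      data.frame(velocity_cm_s = cv$velocity_cm_s,
                 residual_rms_ms = cv$residual_rms_ms,
                 n_electrodes = cv$n_electrodes, quality = cv$quality)
    }, error = function(e) data.frame(velocity_cm_s = NA_real_,
                                      residual_rms_ms = NA_real_,
                                      n_electrodes = 0L,
                                      quality = conditionMessage(e)))
    utils::write.csv(cbind(cvtab, config_hash = hash),
                     file.path(out_dir, "cv_estimates.csv"),
                     row.names = FALSE)
    res$mea <- fp
  }

  if ("report" %in% cfg$stages && !is.null(res$ap) && nrow(res$ap) > 0) {
    logln("stage report")
    summ <- summarize_trace(res$ap, id = cfg$id)
    agg <- aggregate_replicates(list(summ))
    utils::write.csv(cbind(agg$replicates, config_hash = hash),
                     file.path(out_dir, "replicate_table.csv"),
                     row.names = FALSE)
    utils::write.csv(agg$summary,
                     file.path(out_dir, "group_summary.csv"),
                     row.names = FALSE)
    res$report <- agg
  }
  logln("done")
  invisible(res)
}

#' Aggregate replicate-level summary tables
#'
#' Concatenates replicate tables into one long table keyed by protocol,
#' line, differentiation (N) and technical replicate (n), and computes
#' per-protocol descriptive summaries (mean of per-replicate means, SD,
#' replicate counts). The summaries are descriptive only — they are the
#' tidy input a mixed-effects fit would consume, not model estimates.
#'
#' @param tables list of data.frames as produced by [summarize_trace()]
#'   (wide, one row per replicate, with `protocol`, `N`, `n` columns).
#' @return list with `replicates` (long table: protocol, line, N, n,
#'   metric, value) and `summary` (per-protocol, per-metric descriptive
#'   stats, labelled as such).
#' @export
aggregate_replicates <- function(tables) {
  stopifnot(length(tables) >= 1L)
  keys <- c("protocol", "line", "N", "n")
  wide <- do.call(rbind, lapply(tables, function(t) {
    if (!all(c("protocol", "N", "n") %in% names(t)))
      stop("replicate tables must carry protocol, N and n identifiers",
           call. = FALSE)
    if (is.null(t$line)) t$line <- NA_character_
    t
  }))
  dup <- duplicated(wide[, c("protocol", "N", "n")])
  if (any(dup))
    stop("duplicated (protocol, N, n) replicate keys", call. = FALSE)
  metrics <- setdiff(names(wide)[vapply(wide, is.numeric, NA)],
                     c("N", "n", "n_beats", "n_flagged"))
  long <- do.call(rbind, lapply(metrics, function(m)
    data.frame(protocol = wide$protocol, line = wide$line,
               N = wide$N, n = wide$n, metric = m, value = wide[[m]])))
  summ <- do.call(rbind, lapply(split(long, list(long$protocol,
                                                 long$metric),
                                      drop = TRUE), function(d) {
    v <- d$value[is.finite(d$value)]
    data.frame(protocol = d$protocol[1L], metric = d$metric[1L],
               mean = if (length(v)) mean(v) else NA_real_,
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
               N = length(unique(d$N)), n = nrow(d),
               note = "descriptive summary (not a mixed-model estimate)")
  }))
  rownames(summ) <- NULL
  list(replicates = long, summary = summ)
}
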