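#' Write a fluorescence or phase movie as 16-bit TIFF plus JSON sidecar
#'
#' Values are mapped to \[0, 1\] by the affine map `(x - lo) / (hi - lo)`
#' over the finite data range and stored as one 16-bit page per frame; the
#' sidecar records the affine map, frame interval, mask, provenance and
#' seed, so the movie round-trips through [read_movie_tiff()].
#'
#' @param movie a [fluor_movie()] (phase movies can be exported by wrapping
#'   their phase array in a `fluor_movie` first).
#' @param path output TIFF path; the sidecar goes to `<path>.json`.
#' @param seed optional integer recorded for provenance.
#' @return `path`, invisibly.
#' @export
write_movie_tiff <- function(movie, path, seed = NULL) {
  stopifnot(inherits(movie, "fluor_movie"))
  d <- dim(movie$frames)
  lo <- min(movie$frames[is.finite(movie$frames)])
  hi <- max(movie$frames[is.finite(movie$frames)])
  scale <- if (hi > lo) hi - lo else 1
  pages <- lapply(seq_len(d[1L]), function(t)
    (movie$frames[t, , ] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  side <- list(frame_interval_ms = movie$frame_interval_ms,
               modality = movie$modality,
               affine = list(lo = lo, scale = scale),
               mask = movie$mask,
               provenance = movie$provenance,
               untrusted_frames = movie$untrusted_frames,
               seed = seed)
  jsonlite::write_json(side, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a movie written by [write_movie_tiff()]
#'
#' @param path TIFF path with its `<path>.json` sidecar alongside.
#' @return a [fluor_movie()] with original values restored via the stored
#'   affine map.
#' @export
read_movie_tiff <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  pages <- tiff::readTIFF(path, all = TRUE)
  H <- nrow(pages[[1L]]); W <- ncol(pages[[1L]])
  frames <- array(0, c(length(pages), H, W))
  for (t in seq_along(pages))
    frames[t, , ] <- pages[[t]] * side$affine$scale + side$affine$lo
  mask <- matrix(as.logical(side$mask), H, W)
  fluor_movie(frames, side$frame_interval_ms, mask = mask,
              modality = side$modality,
              provenance = as.character(side$provenance),
              untrusted_frames = as.integer(side$untrusted_frames))
}

#' Write an electrogram set as CSV plus geometry sidecar
#'
#' Column 0 is `time_ms`, one column per electrode named `r{row}c{col}`;
#' grid geometry, pitch and quality flags go to `<path>.json`.
#'
#' @param eset an [electrogram_set()].
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_electrograms_csv <- function(eset, path) {
  stopifnot(inherits(eset, "electrogram_set"))
  df <- data.frame(time_ms = eset$time_ms, eset$traces,
                   check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  jsonlite::write_json(list(pitch_mm = eset$pitch_mm,
                            geometry = eset$geometry,
                            quality = eset$quality,
                            metadata = eset$metadata),
                       paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read an electrogram CSV written by [write_electrograms_csv()]
#'
#' @param path CSV path with its `<path>.json` sidecar alongside.
#' @return an [electrogram_set()].
#' @export
read_electrograms_csv <- function(path) {
  side <- jsonlite::read_json(paste0(path, ".json"),
                              simplifyVector = TRUE)
  df <- utils::read.csv(path, check.names = FALSE)
  electrogram_set(time_ms = df$time_ms,
                  traces = as.matrix(df[, -1L, drop = FALSE]),
                  geometry = as.data.frame(side$geometry),
                  pitch_mm = side$pitch_mm,
                  quality = as.character(side$quality),
                  metadata = as.list(side$metadata))
}

#' Write a tip trajectory or PS detection table as CSV
#'
#' @param tab data.frame with at least frame, row, col, chirality.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_tip_csv <- function(tab, path) {
  utils::write.csv(tab, path, row.names = FALSE)
  invisible(path)
}
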