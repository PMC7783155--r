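#' Read a TrackMate-style spots CSV
#'
#' Ingests the spots export of nucleus tracking: a CSV with at least
#' `TRACK_ID`, `POSITION_X`, `POSITION_Y` (micrometres) and either
#' `POSITION_T` (seconds) or `FRAME` (converted through the acquisition
#' interval; 600 s by default, the 10-minute imaging cadence). Missing
#' columns are reported by name; per-track times must be strictly
#' increasing.
#'
#' @param path CSV file path.
#' @param intervalS acquisition interval in seconds, used when only `FRAME`
#'   is present.
#' @return trajectory data.frame (`track_id`, `time_s`, `x_um`, `y_um`)
#'   with attribute `interval_s`.
#' @export
readTracks <- function(path, intervalS = 600) {
  raw <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("TRACK_ID", "POSITION_X", "POSITION_Y")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("tracks file lacks column(s): ", paste(miss, collapse = ", "))
  if ("POSITION_T" %in% names(raw)) {
    timeS <- as.numeric(raw$POSITION_T)
  } else if ("FRAME" %in% names(raw)) {
    timeS <- as.numeric(raw$FRAME) * intervalS
  } else {
    stop("tracks file lacks column(s): FRAME or POSITION_T")
  }
  out <- data.frame(track_id = raw$TRACK_ID, time_s = timeS,
                    x_um = as.numeric(raw$POSITION_X),
                    y_um = as.numeric(raw$POSITION_Y))
  out <- out[order(out$track_id, out$time_s), ]
  rownames(out) <- NULL
  .checkTracks(out)
  attr(out, "interval_s") <- intervalS
  out
}

#' Write a trajectory table as a TrackMate-style spots CSV
#'
#' Inverse of [readTracks()]: writes `TRACK_ID`, `FRAME`, `POSITION_X`,
#' `POSITION_Y`, `POSITION_T` so that a write/read round trip reproduces
#' the numeric content exactly.
#'
#' @param tracks trajectory data.frame (`track_id`, `time_s`, `x_um`,
#'   `y_um`).
#' @param path output CSV path.
#' @param intervalS acquisition interval in seconds used to derive `FRAME`.
#' @return `path`, invisibly.
#' @export
writeTracks <- function(tracks, path, intervalS = attr(tracks, "interval_s")) {
  .checkTracks(tracks)
  if (is.null(intervalS)) intervalS <- 600
  out <- data.frame(TRACK_ID = tracks$track_id,
                    FRAME = round(tracks$time_s / intervalS),
                    POSITION_X = tracks$x_um,
                    POSITION_Y = tracks$y_um,
                    POSITION_T = tracks$time_s)
  write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Convert a simulation result to a physical trajectory table
#'
#' Maps recorded lattice positions to micrometres at site centres
#' (`x = (col - 1/2) * cellSizeUm`, `y = (row - 1/2) * cellSizeUm`) and
#' iteration indices to seconds through the physical step length
#' (`dt * totalTimeH`, i.e. 420 s for the 7-minute default), yielding the
#' same table layout the tracking pipeline produces for real spheroids.
#'
#' @param result a [SimulationResult-class].
#' @return trajectory data.frame (`track_id`, `time_s`, `x_um`, `y_um`)
#'   with attribute `interval_s`.
#' @export
resultTracks <- function(result) {
  stopifnot(is(result, "SimulationResult"))
  p <- result@params
  stepS <- p@dt * p@totalTimeH * 3600
  tr <- result@tracks
  out <- data.frame(track_id = tr$cell_id, time_s = tr$step * stepS,
                    x_um = (tr$col - 0.5) * p@cellSizeUm,
                    y_um = (tr$row - 0.5) * p@cellSizeUm)
  out <- out[order(out$track_id, out$time_s), ]
  rownames(out) <- NULL
  attr(out, "interval_s") <- stepS
  out
}

#' Centroid of a track table at its first time point
#'
#' The mean position of all tracks present at time zero, in micrometres —
#' the simulated analogue of the bright-field mask centroid; for a centred
#' spheroid it recovers the lattice centre.
#'
#' @param tracks trajectory data.frame.
#' @return numeric `(x_c, y_c)`.
#' @export
initialCentroid <- function(tracks) {
  .checkTracks(tracks)
  t0 <- min(tracks$time_s)
  at0 <- tracks[tracks$time_s == t0, ]
  c(mean(at0$x_um), mean(at0$y_um))
}
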