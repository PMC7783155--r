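# Trajectory tables are plain data.frames with columns track_id, time_s,
# x_um, y_um (micrometres / seconds), optionally carrying an "interval_s"
# attribute with the acquisition cadence.

.checkTracks <- function(tracks) {
  need <- c("track_id", "time_s", "x_um", "y_um")
  miss <- setdiff(need, names(tracks))
  if (length(miss))
    stop("track table lacks column(s): ", paste(miss, collapse = ", "))
  if (!nrow(tracks)) stop("empty track table")
  if (!all(is.finite(tracks$time_s)) || !all(is.finite(tracks$x_um)) ||
      !all(is.finite(tracks$y_um)))
    stop("non-finite values in track table")
  bad <- vapply(split(tracks$time_s, tracks$track_id),
                function(t) is.unsorted(t, strictly = TRUE), logical(1))
  if (any(bad))
    stop("per-track times must be strictly increasing (track ",
         paste(names(bad)[bad], collapse = ", "), ")")
  invisible(tracks)
}

#' Mean relative radial migration over time
#'
#' For every time point, the mean over cells present of the radial distance
#' from the fixed spheroid centroid, normalised by the time-zero mean:
#' `meanRRM(t_j) = <sqrt((x_i(t_j) - x_c)^2 + (y_i(t_j) - y_c)^2)>_i /
#' <sqrt((x_i(t_0) - x_c)^2 + (y_i(t_0) - y_c)^2)>_i`,
#' the average being over cells, never over time. A spheroid that stays
#' clustered keeps a mean RRM of 1; cells at doubled radial distances give
#' 2. The centroid is the initial bright-field centroid and stays fixed for
#' the whole series. Tracks absent from a time point (tracking loss) drop
#' out of that time point's average.
#'
#' @param tracks trajectory data.frame (`track_id`, `time_s`, `x_um`,
#'   `y_um`).
#' @param centroid numeric `(x_c, y_c)` in micrometres.
#' @return data.frame with columns `time_h` (hours since the first time
#'   point), `rrm` and `n_cells`; the first `rrm` value is exactly 1.
#' @export
meanRRM <- function(tracks, centroid) {
  .checkTracks(tracks)
  stopifnot(length(centroid) == 2L, all(is.finite(centroid)))
  rad <- sqrt((tracks$x_um - centroid[1])^2 + (tracks$y_um - centroid[2])^2)
  t0 <- min(tracks$time_s)
  denom <- mean(rad[tracks$time_s == t0])
  if (!is.finite(denom) || denom <= 0)
    stop("undefined RRM: mean initial radial distance is zero (all cells at the centroid)")
  times <- sort(unique(tracks$time_s))
  mr <- vapply(times, function(tt) mean(rad[tracks$time_s == tt]), numeric(1))
  nc <- vapply(times, function(tt) sum(tracks$time_s == tt), numeric(1))
  data.frame(time_h = (times - t0) / 3600, rrm = mr / denom, n_cells = nc)
}

#' Single-track diffusion coefficient
#'
#' Estimates a 2-D diffusion coefficient from one trajectory as the summed
#' squared frame-to-frame displacements over four times the track duration:
#' `d_cell = 1/(4 T) * sum_j [(x(t_j) - x(t_{j-1}))^2 +
#' (y(t_j) - y(t_{j-1}))^2]`.
#'
#' @param track data.frame for one track with `time_s`, `x_um`, `y_um`
#'   (rows in time order or carrying times to sort by).
#' @param totalS total trajectory duration T in seconds; defaults to the
#'   track's time span.
#' @return diffusion coefficient in um^2/s.
#' @examples
#' tr <- data.frame(time_s = c(0, 420), x_um = c(0, 10), y_um = c(0, 0))
#' estimateDcell(tr)   # 100 / (4 * 420)
#' @export
estimateDcell <- function(track, totalS = NULL) {
  stopifnot(all(c("time_s", "x_um", "y_um") %in% names(track)))
  if (nrow(track) < 2L) stop("a track needs at least two time points")
  track <- track[order(track$time_s), ]
  if (is.null(totalS)) totalS <- max(track$time_s) - min(track$time_s)
  if (!is.finite(totalS) || totalS <= 0) stop("'totalS' must be positive")
  sum(diff(track$x_um)^2 + diff(track$y_um)^2) / (4 * totalS)
}

#' Population diffusion coefficient with its standard error
#'
#' Averages [estimateDcell()] over all tracks of a table, reporting the
#' mean and `SEM = sd / sqrt(n)` ("mean +/- SEM" as for the measured
#' monolayer value of 0.21 um^2/s).
#'
#' @param tracks trajectory data.frame with at least two tracks.
#' @return list with `mean`, `sem`, `n` and the per-track estimates
#'   `dcell`.
#' @export
populationDcell <- function(tracks) {
  .checkTracks(tracks)
  per <- split(tracks, tracks$track_id)
  if (length(per) < 2L) stop("at least two tracks are needed for a SEM")
  d <- vapply(per, estimateDcell, numeric(1))
  list(mean = mean(d), sem = sd(d) / sqrt(length(d)), n = length(d), dcell = d)
}

#' Invasion velocity from the early linear regime
#'
#' Ordinary least-squares slope of the mean RRM series over time points in
#' the first `windowH` hours (7.5 h by default, the linear-increase regime
#' of the invasion assays); the intercept is free, not forced through 1.
#'
#' @param rrm RRM series data.frame (`time_h`, `rrm`) from [meanRRM()].
#' @param windowH fitting window in hours.
#' @return slope in RRM units per hour.
#' @export
invasionVelocity <- function(rrm, windowH = 7.5) {
  stopifnot(all(c("time_h", "rrm") %in% names(rrm)))
  keep <- rrm$time_h <= windowH
  if (sum(keep) < 2L) stop("need at least two RRM points inside the window")
  unname(coef(lm(rrm ~ time_h, data = rrm[keep, ]))[2])
}

#' Stratify spheroids by initial diameter
#'
#' Splits records at the 100 um threshold separating the constant (large)
#' from the divergent (small) invasion behaviour; a diameter of exactly the
#' threshold counts as large. Group-averaged RRM curves are computed
#' pointwise over the time points shared by every member of a group.
#'
#' @param records list of [SpheroidRecord-class].
#' @param thresholdUm diameter threshold in micrometres.
#' @return list with `small` and `large` (sublists of records) and
#'   `rrmSmall` / `rrmLarge` (pointwise mean RRM curves, NULL for an empty
#'   group).
#' @export
splitBySize <- function(records, thresholdUm = 100) {
  stopifnot(is.list(records))
  dia <- vapply(records, function(r) r@diameterUm, numeric(1))
  small <- records[dia < thresholdUm]
  large <- records[dia >= thresholdUm]
  avg <- function(group) {
    if (!length(group)) return(NULL)
    series <- lapply(group, function(r) r@rrm)
    common <- Reduce(intersect, lapply(series, function(s) s$time_h))
    if (!length(common)) return(NULL)
    common <- sort(common)
    vals <- vapply(series, function(s) s$rrm[match(common, s$time_h)],
                   numeric(length(common)))
    data.frame(time_h = common,
               rrm = if (length(common) == 1L) mean(vals) else rowMeans(vals))
  }
  list(small = small, large = large,
       rrmSmall = avg(small), rrmLarge = avg(large))
}

#' Two-sample Kolmogorov-Smirnov comparison
#'
#' Non-parametric comparison of two empirical cumulative distributions:
#' the KS statistic (supremum ECDF difference) with the asymptotic
#' two-sample p-value.
#'
#' @param a,b numeric samples, both non-empty.
#' @return list with `statistic` and `p`.
#' @examples
#' ksCompare(c(1, 2), c(1, 3))$statistic   # 0.5
#' @export
ksCompare <- function(a, b) {
  stopifnot(length(a) > 0, length(b) > 0)
  res <- suppressWarnings(ks.test(a, b, exact = FALSE))
  list(statistic = unname(res$statistic), p = unname(res$p.value))
}

#' Bundle a spheroid's tracks with its RRM series
#'
#' Convenience constructor for [SpheroidRecord-class]: validates the track
#' table and computes [meanRRM()] once.
#'
#' @param id character identifier.
#' @param diameterUm initial diameter in micrometres.
#' @param centroid `(x_c, y_c)` in micrometres.
#' @param tracks trajectory data.frame.
#' @return a [SpheroidRecord-class].
#' @export
spheroidRecord <- function(id, diameterUm, centroid, tracks) {
  new("SpheroidRecord", id = as.character(id), diameterUm = diameterUm,
      centroid = as.numeric(centroid), tracks = tracks,
      rrm = meanRRM(tracks, centroid))
}
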