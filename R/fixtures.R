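#' Synthetic Brownian trajectory tables
#'
#' Generates isotropic 2-D random-walk tracks at a fixed imaging cadence:
#' each step adds independent Gaussian displacements with variance
#' `2 * trueD * dtS` per axis (total mean squared displacement `4 D dt` per
#' step, the 2-D convention the `1/(4T)` estimator inverts, so recovery is
#' unbiased). Defaults mirror the monolayer reference measurement: D = 0.21
#' um^2/s sampled every 10 min for 24 h. Deterministic given `seed`.
#'
#' @param trueD diffusion coefficient in um^2/s.
#' @param nCells number of tracks.
#' @param nSteps number of displacement steps per track.
#' @param dtS sampling interval in seconds.
#' @param originRadius tracks start uniformly inside a disk of this radius
#'   (um) around the origin; 0 starts all tracks at the origin.
#' @param seed RNG seed.
#' @return trajectory data.frame (`track_id`, `time_s`, `x_um`, `y_um`)
#'   with attribute `interval_s`.
#' @examples
#' tr <- brownianTracks(trueD = 0.21, nCells = 5, nSteps = 10, seed = 1)
#' populationDcell(tr)$mean
#' @export
brownianTracks <- function(trueD = 0.21, nCells = 100, nSteps = 144,
                           dtS = 600, originRadius = 0, seed = 1) {
  stopifnot(trueD >= 0, nCells >= 1, nSteps >= 1, dtS > 0, originRadius >= 0)
  set.seed(as.integer(seed))
  sdStep <- sqrt(2 * trueD * dtS)
  times <- (0:nSteps) * dtS
  tabs <- lapply(seq_len(nCells), function(id) {
    if (originRadius > 0) {
      th <- runif(1, 0, 2 * pi)
      rad <- originRadius * sqrt(runif(1))
      x0 <- rad * cos(th); y0 <- rad * sin(th)
    } else {
      x0 <- 0; y0 <- 0
    }
    data.frame(track_id = id, time_s = times,
               x_um = x0 + cumsum(c(0, rnorm(nSteps, 0, sdStep))),
               y_um = y0 + cumsum(c(0, rnorm(nSteps, 0, sdStep))))
  })
  out <- do.call(rbind, tabs)
  rownames(out) <- NULL
  attr(out, "interval_s") <- dtS
  out
}

#' Random-movement interval for a motility-inhibition experiment
#'
#' A drug that reduces single-cell diffusivity to `fraction +/- spread` of
#' the control value is simulated by drawing the random-movement weight `r`
#' from the matching interval `[fraction - spread, fraction + spread]`,
#' relying on the engine property that the walker's effective diffusivity
#' scales linearly with `r`. The measured MK-2206 reduction of 40 +/- 15 %
#' gives the interval (0.25, 0.55).
#'
#' @param fraction residual diffusivity as a fraction of control.
#' @param spread half-width of the uncertainty band.
#' @return numeric `(r_low, r_high)`.
#' @examples
#' drugRInterval(0.40, 0.15)   # c(0.25, 0.55)
#' @export
drugRInterval <- function(fraction, spread) {
  stopifnot(is.finite(fraction), is.finite(spread), spread >= 0)
  lo <- fraction - spread
  hi <- fraction + spread
  if (lo <= 0 || hi > 1)
    stop(sprintf("interval (%g, %g) escapes (0, 1]", lo, hi))
  c(lo, hi)
}
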