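#' Construct simulation parameters with study defaults
#'
#' Returns a validated [SimulationParams-class] built from the calibrated
#' optimum of the spheroid migration model (`D = 50`, `c1 = 0.035`,
#' `c2 = c1/2`, `cf = 20`, `q = 0.3`, `r = 1`, `alpha = 0`) on a 200 x 200
#' lattice of 10 um sites with a 7-minute time step mapped onto a 24-hour
#' experiment (`dt = 7/1440`), merged with any overrides given as named
#' arguments. Unknown names and any invariant violation (in particular the
#' explicit-scheme stability bound `dt <= h^2/(2 D)`) are errors.
#'
#' @param ... named overrides of the fields of [SimulationParams-class]
#'   (e.g. `D = 25`, `r = 0.4`, `m = 100`, `seed = 7`).
#' @return a [SimulationParams-class] object.
#' @examples
#' p <- makeParams()                 # the calibrated optimum
#' makeParams(r = 0.4, seed = 3)     # reduced random motility
#' @export
makeParams <- function(...) {
  defaults <- list(
    D = 50, c1 = 0.035, c2 = 0.035 / 2, cf = 20,
    q = 0.3, r = 1, alpha = 0,
    dt = 7 / 1440, h = 1, m = 200,
    cellSizeUm = 10, totalTimeH = 24,
    sigmaG = 2, neighborOrder = 1,
    fieldUpdate = "after", seed = 1
  )
  overrides <- list(...)
  if (length(overrides)) {
    if (is.null(names(overrides)) || any(!nzchar(names(overrides))))
      stop("all overrides must be named")
    unknown <- setdiff(names(overrides), names(defaults))
    if (length(unknown))
      stop("unknown parameter(s): ", paste(unknown, collapse = ", "))
    defaults[names(overrides)] <- overrides
  }
  do.call(new, c(list("SimulationParams"), defaults))
}

#' Derive the finite-difference scheme constants
#'
#' Computes `lam = D * dt / h^2` and `delta = 1 - 4 * lam` for the explicit
#' five-point chemoattractant solver; construction fails when `lam > 1/2`
#' (the stability bound).
#'
#' @param params a [SimulationParams-class].
#' @param boundaryMode boundary handling; `"dirichlet0"` treats the
#'   concentration outside the lattice as zero.
#' @return a [ChemoScheme-class].
#' @examples
#' chemoScheme(makeParams())   # lambda ~ 0.243 for the defaults
#' @export
chemoScheme <- function(params, boundaryMode = "dirichlet0") {
  lam <- params@D * params@dt / params@h^2
  new("ChemoScheme", lam = lam, delta = 1 - 4 * lam, boundaryMode = boundaryMode)
}

#' Number of iterations covering a physical duration
#'
#' `floor(total minutes / step minutes)`; the study's 24 h at a 7 min step
#' gives 205 iterations.
#'
#' @param totalTimeH experiment duration in hours.
#' @param stepMin iteration length in minutes.
#' @return integer iteration count.
#' @examples
#' nStepsFor(24, 7)   # 205
#' @export
nStepsFor <- function(totalTimeH, stepMin) {
  stopifnot(is.numeric(totalTimeH), totalTimeH > 0,
            is.numeric(stepMin), stepMin > 0)
  as.integer(floor(totalTimeH * 60 / stepMin))
}

#' Initial spheroid occupancy and chemical field
#'
#' Places a filled `d x d` block of cells at the centre of an `m x m`
#' lattice (lower-left corner at `floor((m - d) / 2)`, so even/odd sizes are
#' handled by a fixed convention) and an all-zero chemoattractant field.
#' Cell ids are assigned row-major over the block, deterministically.
#'
#' @param m lattice side length in sites.
#' @param d spheroid side length in sites (`0 < d < m`); a 10 um site makes
#'   `d = 5..16` cover the 50-160 um diameter range of the migration assays.
#' @return a list with components `state` ([CellState-class]) and `field`
#'   ([ChemoField-class]).
#' @examples
#' init <- initSpheroid(m = 200, d = 5)
#' sum(occupancy(init$state))   # 25 cells
#' @export
initSpheroid <- function(m, d) {
  stopifnot(length(m) == 1L, length(d) == 1L, m == round(m), d == round(d))
  if (d <= 0) stop("'d' must be positive")
  if (d >= m) stop(sprintf("spheroid side d = %d must be smaller than the lattice m = %d", d, m))
  m <- as.integer(m); d <- as.integer(d)
  occ <- matrix(0L, m, m)
  lo <- as.integer(floor((m - d) / 2)) + 1L
  idx <- lo:(lo + d - 1L)
  occ[idx, idx] <- 1L
  cells <- expand.grid(col = idx, row = idx, KEEP.OUT.ATTRS = FALSE)
  cells <- data.frame(cell_id = seq_len(d * d),
                      row = as.integer(cells$row),
                      col = as.integer(cells$col))
  state <- new("CellState", occupancy = occ, cells = cells, timeIndex = 0)
  field <- new("ChemoField", values = matrix(0, m, m))
  list(state = state, field = field)
}
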