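#' @import methods
#' @importFrom stats runif sd lm coef ks.test rnorm setNames
#' @importFrom utils read.csv write.csv write.table packageVersion
NULL

#' Simulation parameters for the spheroid migration automaton
#'
#' Holds every model constant of the cellular automaton together with the
#' lattice/time discretisation. All engine mathematics is dimensionless:
#' one length unit is one lattice site (one cell diameter, `cellSizeUm`
#' micrometres) and one time unit is the full experiment duration
#' (`totalTimeH` hours), so `dt` is the fraction of the experiment covered
#' by one iteration. Validity enforces the explicit-scheme stability bound
#' `dt <= h^2 / (2 D)` for the chemoattractant diffusion solver, probability
#' bounds on `q`, `r` and `alpha`, and non-overshooting degradation
#' (`c2 * dt <= 1`).
#'
#' @slot D dimensionless chemical-to-cell diffusivity ratio D_chem/D_cell.
#' @slot c1 chemoattractant production rate per occupied site per time unit.
#' @slot c2 chemoattractant degradation rate (per time unit, proportional to
#'   local concentration at occupied sites).
#' @slot cf chemotaxis strength; positive for an attractant, negative for a
#'   repellent.
#' @slot q mechanical-interaction weight in `[0, 1]`.
#' @slot r random-movement weight (probability of taking a random step when
#'   no other mechanism contributes) in `[0, 1]`.
#' @slot alpha proliferation probability per cell per iteration in `[0, 1]`.
#' @slot dt dimensionless time step.
#' @slot h lattice spacing in dimensionless units (1).
#' @slot m lattice side length in sites.
#' @slot cellSizeUm physical edge of one site, micrometres.
#' @slot totalTimeH physical duration mapped onto one time unit, hours.
#' @slot sigmaG standard deviation of the random-movement Gaussian kernel,
#'   in sites.
#' @slot neighborOrder mechanical interaction range: 1 (3x3 ones window) or
#'   2 (5x5 window).
#' @slot fieldUpdate `"after"` (default) updates the chemical field once per
#'   iteration after all cells have acted; `"before"` updates it first.
#' @slot seed integer RNG seed used by [runSimulation()].
#'
#' @seealso [makeParams()] for construction with defaults.
#' @export
setClass("SimulationParams",
  representation(
    D = "numeric", c1 = "numeric", c2 = "numeric", cf = "numeric",
    q = "numeric", r = "numeric", alpha = "numeric",
    dt = "numeric", h = "numeric", m = "numeric",
    cellSizeUm = "numeric", totalTimeH = "numeric",
    sigmaG = "numeric", neighborOrder = "numeric",
    fieldUpdate = "character", seed = "numeric"
  )
)

setValidity("SimulationParams", function(object) {
  msgs <- character()
  num1 <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)
  for (s in c("D", "c1", "c2", "cf", "q", "r", "alpha", "dt", "h", "m",
              "cellSizeUm", "totalTimeH", "sigmaG", "neighborOrder", "seed")) {
    if (!num1(slot(object, s))) msgs <- c(msgs, sprintf("'%s' must be a single finite number", s))
  }
  if (length(msgs)) return(msgs)
  if (object@D < 0 || object@c1 < 0 || object@c2 < 0)
    msgs <- c(msgs, "'D', 'c1' and 'c2' must be nonnegative")
  for (s in c("q", "r", "alpha")) {
    v <- slot(object, s)
    if (v < 0 || v > 1) msgs <- c(msgs, sprintf("'%s' = %g must lie in [0, 1]", s, v))
  }
  if (object@dt <= 0) msgs <- c(msgs, "'dt' must be positive")
  if (object@h <= 0) msgs <- c(msgs, "'h' must be positive")
  bound <- object@h^2 / (2 * object@D)
  if (object@D > 0 && object@dt > bound)
    msgs <- c(msgs, sprintf(
      "explicit chemo scheme unstable: dt = %g exceeds h^2/(2D) = %g (lambda = %g > 1/2)",
      object@dt, bound, object@D * object@dt / object@h^2))
  if (object@c2 * object@dt > 1)
    msgs <- c(msgs, sprintf("degradation overshoots: c2*dt = %g > 1", object@c2 * object@dt))
  if (object@m < 3 || object@m != round(object@m))
    msgs <- c(msgs, "'m' must be an integer >= 3")
  if (object@cellSizeUm <= 0) msgs <- c(msgs, "'cellSizeUm' must be positive")
  if (object@totalTimeH <= 0) msgs <- c(msgs, "'totalTimeH' must be positive")
  if (object@sigmaG <= 0) msgs <- c(msgs, "'sigmaG' must be positive")
  if (!object@neighborOrder %in% c(1, 2))
    msgs <- c(msgs, "'neighborOrder' must be 1 or 2")
  if (!object@fieldUpdate %in% c("after", "before"))
    msgs <- c(msgs, "'fieldUpdate' must be \"after\" or \"before\"")
  if (length(msgs)) msgs else TRUE
})

#' Finite-difference scheme constants for the chemoattractant solver
#'
#' Derived quantities of the explicit five-point stencil:
#' `lam = D * dt / h^2` and `delta = 1 - 4 * lam`. The scheme is stable for
#' `lam <= 1/2` and preserves nonnegativity for `lam <= 1/4`.
#'
#' @slot lam diffusion number lambda.
#' @slot delta centre weight `1 - 4 lambda`.
#' @slot boundaryMode boundary handling; only `"dirichlet0"` (zero
#'   concentration outside the lattice) is implemented.
#' @seealso [chemoScheme()]
#' @export
setClass("ChemoScheme",
  representation(lam = "numeric", delta = "numeric", boundaryMode = "character")
)

setValidity("ChemoScheme", function(object) {
  msgs <- character()
  if (!is.finite(object@lam) || object@lam < 0) msgs <- c(msgs, "'lam' must be finite and >= 0")
  if (object@lam > 0.5) msgs <- c(msgs, sprintf("lambda = %g exceeds the stability bound 1/2", object@lam))
  if (abs(object@delta - (1 - 4 * object@lam)) > 1e-12) msgs <- c(msgs, "'delta' must equal 1 - 4*lam")
  if (object@delta < -1) msgs <- c(msgs, "'delta' below -1")
  if (!identical(object@boundaryMode, "dirichlet0")) msgs <- c(msgs, "unsupported boundary mode")
  if (length(msgs)) msgs else TRUE
})

#' Binary occupancy lattice with identity-preserving cell list
#'
#' The occupancy matrix holds 1 at occupied sites and 0 elsewhere; `cells`
#' carries one row per cell (`cell_id`, `row`, `col`) so that trajectories
#' keep their identity across iterations. Validity enforces strict volume
#' exclusion: occupancy entries are 0/1, each cell sits on its own site, and
#' the occupancy total equals the number of cells.
#'
#' @slot occupancy integer m-by-m matrix of 0/1.
#' @slot cells data.frame with columns `cell_id`, `row`, `col`.
#' @slot timeIndex iteration counter (0 at initialisation).
#' @export
setClass("CellState",
  representation(occupancy = "matrix", cells = "data.frame", timeIndex = "numeric")
)

setValidity("CellState", function(object) {
  occ <- object@occupancy
  cl <- object@cells
  msgs <- character()
  if (!all(occ %in% c(0L, 1L))) msgs <- c(msgs, "occupancy entries must be 0 or 1")
  if (!all(c("cell_id", "row", "col") %in% names(cl)))
    return("cells must have columns cell_id, row, col")
  if (sum(occ) != nrow(cl))
    msgs <- c(msgs, "occupancy sum does not match the number of cells")
  if (anyDuplicated(cl$cell_id)) msgs <- c(msgs, "cell_ids must be unique")
  if (nrow(cl)) {
    if (anyDuplicated(cl[c("row", "col")])) msgs <- c(msgs, "two cells share a site")
    if (any(cl$row < 1 | cl$row > nrow(occ) | cl$col < 1 | cl$col > ncol(occ)))
      msgs <- c(msgs, "cell coordinates outside the lattice")
    else if (any(occ[cbind(cl$row, cl$col)] != 1L))
      msgs <- c(msgs, "cell list and occupancy disagree")
  }
  if (length(msgs)) msgs else TRUE
})

#' Chemoattractant concentration lattice
#'
#' @slot values m-by-m matrix of finite, nonnegative concentrations
#'   (dimensionless units).
#' @export
setClass("ChemoField", representation(values = "matrix"))

setValidity("ChemoField", function(object) {
  v <- object@values
  if (!all(is.finite(v))) return("field values must be finite")
  if (any(v < 0)) return("field values must be nonnegative")
  TRUE
})

#' 3x3 movement-weight stencil
#'
#' A probability kernel over the Moore neighbourhood, indexed by offsets
#' `(di, dj)` in `{-1, 0, 1}^2` (row 1 is `di = -1`, column 1 is `dj = -1`).
#' The random (G), chemotactic (C), mechanical (I) and composed (P) kernels
#' are all instances. Entries are nonnegative; an all-zero kernel is the
#' degenerate "stay put" case.
#'
#' @slot weights 3x3 numeric matrix of nonnegative weights.
#' @export
setClass("ProbabilityKernel", representation(weights = "matrix"))

setValidity("ProbabilityKernel", function(object) {
  w <- object@weights
  if (!identical(dim(w), c(3L, 3L))) return("weights must be a 3x3 matrix")
  if (!all(is.finite(w))) return("weights must be finite")
  if (any(w < 0)) return("weights must be nonnegative")
  TRUE
})

#' Mechanism on/off switches
#'
#' One flag per biological actuator, used for ablation experiments
#' ("turn off one mechanism at a time").
#'
#' @slot randomOn,chemoOn,mechOn,proliferationOn logical switches.
#' @seealso [mechanismFlags()], [ablate()]
#' @export
setClass("MechanismFlags",
  representation(randomOn = "logical", chemoOn = "logical",
                 mechOn = "logical", proliferationOn = "logical")
)

setValidity("MechanismFlags", function(object) {
  for (s in c("randomOn", "chemoOn", "mechOn", "proliferationOn"))
    if (length(slot(object, s)) != 1L || is.na(slot(object, s)))
      return(sprintf("'%s' must be TRUE or FALSE", s))
  TRUE
})

#' Result of a simulation run
#'
#' Carries everything needed to reproduce and analyse a run: the parameters
#' and flags, the per-iteration lattice positions of every cell (long
#' format, one row per cell per recorded step, step 0 included), division
#' events, the final state and chemical field, and optional field snapshots.
#'
#' @slot params the [SimulationParams-class] used.
#' @slot flags the [MechanismFlags-class] used.
#' @slot tracks data.frame `cell_id`, `step`, `row`, `col` (lattice units).
#' @slot divisions data.frame `step`, `mother_id`, `daughter_id`.
#' @slot finalState [CellState-class] after the last iteration.
#' @slot finalField [ChemoField-class] after the last iteration.
#' @slot fieldSnapshots named list of field matrices at requested steps.
#' @slot nSteps number of iterations performed.
#' @export
setClass("SimulationResult",
  representation(
    params = "SimulationParams", flags = "MechanismFlags",
    tracks = "data.frame", divisions = "data.frame",
    finalState = "CellState", finalField = "ChemoField",
    fieldSnapshots = "list", nSteps = "numeric"
  )
)

#' A tracked spheroid with its derived RRM series
#'
#' Bundles one spheroid's identity, initial diameter, fixed centroid and
#' trajectory table with the mean relative radial migration series computed
#' from them; the unit [splitBySize()] stratifies.
#'
#' @slot id character identifier.
#' @slot diameterUm initial spheroid diameter, micrometres.
#' @slot centroid numeric length-2, centroid `(x, y)` in micrometres fixed
#'   at its time-zero value.
#' @slot tracks trajectory data.frame (`track_id`, `time_s`, `x_um`, `y_um`).
#' @slot rrm RRM series data.frame (`time_h`, `rrm`) from [meanRRM()].
#' @export
setClass("SpheroidRecord",
  representation(id = "character", diameterUm = "numeric",
                 centroid = "numeric", tracks = "data.frame", rrm = "data.frame")
)

setValidity("SpheroidRecord", function(object) {
  msgs <- character()
  if (length(object@diameterUm) != 1L || !is.finite(object@diameterUm) || object@diameterUm <= 0)
    msgs <- c(msgs, "'diameterUm' must be a single positive number")
  if (length(object@centroid) != 2L || !all(is.finite(object@centroid)))
    msgs <- c(msgs, "'centroid' must be two finite coordinates")
  if (length(msgs)) msgs else TRUE
})
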