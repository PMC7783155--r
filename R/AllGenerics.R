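#' Accessors for the automaton classes
#'
#' Small accessor generics so user code never touches slots directly:
#' `occupancy()` returns the 0/1 lattice, `cellTable()` the identity-keeping
#' cell coordinate table, `fieldValues()` the chemical concentration matrix,
#' `kernelWeights()` a kernel's 3x3 weight matrix, `simParams()` and
#' `simFlags()` a result's configuration, `latticeTracks()` the recorded
#' per-step lattice positions and `divisionEvents()` the division log.
#'
#' @param x an object of the matching class.
#' @return the component named above.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("occupancy", function(x) standardGeneric("occupancy"))
#' @rdname accessors
#' @export
setGeneric("cellTable", function(x) standardGeneric("cellTable"))
#' @rdname accessors
#' @export
setGeneric("fieldValues", function(x) standardGeneric("fieldValues"))
#' @rdname accessors
#' @export
setGeneric("kernelWeights", function(x) standardGeneric("kernelWeights"))
#' @rdname accessors
#' @export
setGeneric("simParams", function(x) standardGeneric("simParams"))
#' @rdname accessors
#' @export
setGeneric("simFlags", function(x) standardGeneric("simFlags"))
#' @rdname accessors
#' @export
setGeneric("latticeTracks", function(x) standardGeneric("latticeTracks"))
#' @rdname accessors
#' @export
setGeneric("divisionEvents", function(x) standardGeneric("divisionEvents"))

#' @rdname accessors
#' @export
setMethod("occupancy", "CellState", function(x) x@occupancy)
#' @rdname accessors
#' @export
setMethod("occupancy", "SimulationResult", function(x) x@finalState@occupancy)
#' @rdname accessors
#' @export
setMethod("cellTable", "CellState", function(x) x@cells)
#' @rdname accessors
#' @export
setMethod("cellTable", "SimulationResult", function(x) x@finalState@cells)
#' @rdname accessors
#' @export
setMethod("fieldValues", "ChemoField", function(x) x@values)
#' @rdname accessors
#' @export
setMethod("fieldValues", "SimulationResult", function(x) x@finalField@values)
#' @rdname accessors
#' @export
setMethod("kernelWeights", "ProbabilityKernel", function(x) x@weights)
#' @rdname accessors
#' @export
setMethod("simParams", "SimulationResult", function(x) x@params)
#' @rdname accessors
#' @export
setMethod("simFlags", "SimulationResult", function(x) x@flags)
#' @rdname accessors
#' @export
setMethod("latticeTracks", "SimulationResult", function(x) x@tracks)
#' @rdname accessors
#' @export
setMethod("divisionEvents", "SimulationResult", function(x) x@divisions)

setMethod("show", "SimulationParams", function(object) {
  cat("SimulationParams\n")
  cat(sprintf("  lattice: %d x %d sites (%g um/site, domain %g um)\n",
              as.integer(object@m), as.integer(object@m),
              object@cellSizeUm, object@m * object@cellSizeUm))
  cat(sprintf("  time: dt = %.6g (%g min of %g h), lambda = %.4g\n",
              object@dt, object@dt * object@totalTimeH * 60,
              object@totalTimeH, object@D * object@dt / object@h^2))
  cat(sprintf("  mechanisms: D = %g, c1 = %g, c2 = %g, cf = %g, q = %g, r = %g, alpha = %g\n",
              object@D, object@c1, object@c2, object@cf, object@q,
              object@r, object@alpha))
  cat(sprintf("  kernel sigma = %g sites, neighbor order = %d, seed = %g\n",
              object@sigmaG, as.integer(object@neighborOrder), object@seed))
  invisible(object)
})

setMethod("show", "CellState", function(object) {
  cat(sprintf("CellState: %d cells on a %d x %d lattice (iteration %d)\n",
              nrow(object@cells), nrow(object@occupancy), ncol(object@occupancy),
              as.integer(object@timeIndex)))
  invisible(object)
})

setMethod("show", "ChemoField", function(object) {
  v <- object@values
  cat(sprintf("ChemoField: %d x %d, total mass %.4g, max %.4g\n",
              nrow(v), ncol(v), sum(v), max(v)))
  invisible(object)
})

setMethod("show", "ProbabilityKernel", function(object) {
  cat("ProbabilityKernel (rows di = -1,0,1; cols dj = -1,0,1):\n")
  print(round(object@weights, 5))
  invisible(object)
})

setMethod("show", "MechanismFlags", function(object) {
  onoff <- function(x) if (x) "on" else "off"
  cat(sprintf("MechanismFlags: random %s, chemotaxis %s, mechanics %s, proliferation %s\n",
              onoff(object@randomOn), onoff(object@chemoOn),
              onoff(object@mechOn), onoff(object@proliferationOn)))
  invisible(object)
})

setMethod("show", "SimulationResult", function(object) {
  cat(sprintf("SimulationResult: %d steps, %d cells at end (%d at start), %d divisions\n",
              as.integer(object@nSteps), nrow(object@finalState@cells),
              length(unique(object@tracks$cell_id[object@tracks$step == 0])),
              nrow(object@divisions)))
  show(object@flags)
  invisible(object)
})

setMethod("show", "SpheroidRecord", function(object) {
  cat(sprintf("SpheroidRecord '%s': diameter %g um, centroid (%.1f, %.1f) um, %d tracks\n",
              object@id, object@diameterUm, object@centroid[1], object@centroid[2],
              length(unique(object@tracks$track_id))))
  invisible(object)
})
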