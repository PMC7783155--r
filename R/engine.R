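#' Mechanism switches
#'
#' Builds a [MechanismFlags-class]. All four actuators default to on;
#' proliferation is a no-op anyway whenever `alpha = 0` (the study default,
#' since few mitoses occur within 24 h).
#'
#' @param random,chemotaxis,mechanics,proliferation logical switches.
#' @return a [MechanismFlags-class].
#' @examples
#' mechanismFlags(chemotaxis = FALSE)   # the chemotaxis ablation
#' @export
mechanismFlags <- function(random = TRUE, chemotaxis = TRUE,
                           mechanics = TRUE, proliferation = TRUE) {
  new("MechanismFlags", randomOn = random, chemoOn = chemotaxis,
      mechOn = mechanics, proliferationOn = proliferation)
}

#' Switch one mechanism off
#'
#' Returns a copy of `flags` with the named mechanism disabled; applying the
#' same ablation twice is idempotent.
#'
#' @param flags a [MechanismFlags-class].
#' @param drop one of `"random"`, `"chemotaxis"`, `"mechanics"`,
#'   `"proliferation"`.
#' @return a [MechanismFlags-class].
#' @export
ablate <- function(flags, drop) {
  drop <- match.arg(drop, c("random", "chemotaxis", "mechanics", "proliferation"))
  slotName <- c(random = "randomOn", chemotaxis = "chemoOn",
                mechanics = "mechOn", proliferation = "proliferationOn")[[drop]]
  slot(flags, slotName) <- FALSE
  validObject(flags)
  flags
}

# Offset tables shared by the movement sampler (column-major order of the
# 3x3 kernel; index 5 is the centre).
.DI <- rep(-1:1, 3)
.DJ <- rep(-1:1, each = 3)
.E <- 8L; .W <- 2L; .S <- 6L; .N <- 4L  # cardinal offset indices

# One iteration over bare state vectors. Mutates nothing; returns the new
# occupancy, cell vectors and division log. Kernels C and I are computed
# from the state frozen at step entry; occupancy checks for actual moves
# and daughter placement use the live lattice.
.advanceCore <- function(occ, ids, ri, ci, U, params, flags, nextId) {
  m <- nrow(occ)
  nm <- ncol(occ)
  r <- params@r; cf <- params@cf; q <- params@q; alpha <- params@alpha
  gv <- if (flags@randomOn && r > 0) r * as.vector(.gaussWeights(params@sigmaG)) else numeric(9)
  doChemo <- flags@chemoOn && cf != 0
  doMech <- flags@mechOn && q > 0
  doProl <- flags@proliferationOn && alpha > 0
  conv <- if (doMech) .convOnes(occ, params@neighborOrder) else NULL
  Uf <- U
  n0 <- length(ids)
  divStep <- list()
  ord <- sample.int(n0)
  for (k in ord) {
    i <- ri[k]; j <- ci[k]
    if (doProl && runif(1) < alpha) {
      # division: mother stays; daughter takes a uniformly chosen free
      # 8-neighbour (live occupancy); no free site, no division
      fi <- integer(8); fj <- integer(8); nf <- 0L
      for (t in c(1L, 2L, 3L, 4L, 6L, 7L, 8L, 9L)) {
        ii <- i + .DI[t]; jj <- j + .DJ[t]
        if (ii >= 1L && ii <= m && jj >= 1L && jj <= nm && occ[ii, jj] == 0L) {
          nf <- nf + 1L; fi[nf] <- ii; fj[nf] <- jj
        }
      }
      if (nf > 0L) {
        pick <- if (nf == 1L) 1L else sample.int(nf, 1L)
        occ[fi[pick], fj[pick]] <- 1L
        ids <- c(ids, nextId); ri <- c(ri, fi[pick]); ci <- c(ci, fj[pick])
        divStep[[length(divStep) + 1L]] <- c(ids[k], nextId)
        nextId <- nextId + 1L
      }
      next
    }
    w <- gv
    if (doChemo) {
      uij <- Uf[i, j]
      sat <- (1 + 3 * uij)^2
      e <- if (j < nm) Uf[i, j + 1L] else 0
      wv <- if (j > 1L) Uf[i, j - 1L] else 0
      s <- if (i < m) Uf[i + 1L, j] else 0
      nv <- if (i > 1L) Uf[i - 1L, j] else 0
      mux <- (e - wv) / sat
      muy <- (s - nv) / sat
      ax <- abs(mux); ay <- abs(muy)
      if (ax > 0 || ay > 0) {
        useX <- if (ax > ay) TRUE else if (ay > ax) FALSE else runif(1) < 0.5
        if (useX) {
          t <- if (xor(mux > 0, cf < 0)) .E else .W
          w[t] <- w[t] + abs(cf) * ax
        } else {
          t <- if (xor(muy > 0, cf < 0)) .S else .N
          w[t] <- w[t] + abs(cf) * ay
        }
      }
    }
    if (doMech) {
      mw <- numeric(9); msum <- 0
      for (t in c(1L, 2L, 3L, 4L, 6L, 7L, 8L, 9L)) {
        ii <- i + .DI[t]; jj <- j + .DJ[t]
        if (ii >= 1L && ii <= m && jj >= 1L && jj <= nm) {
          v <- conv[ii, jj] - 1
          if (v > 0) { mw[t] <- v; msum <- msum + v }
        }
      }
      if (msum > 0) w <- w + (q / msum) * mw
    }
    w[5L] <- 0
    tot <- sum(w)
    if (tot <= 0) next
    if (tot > 1) { w <- w / tot; tot <- 1 }
    x <- runif(1)
    if (x >= tot) next          # residual probability: stay
    sel <- 1L; acc <- w[1L]
    while (x >= acc) { sel <- sel + 1L; acc <- acc + w[sel] }
    if (sel == 5L) next
    ti <- i + .DI[sel]; tj <- j + .DJ[sel]
    if (ti >= 1L && ti <= m && tj >= 1L && tj <= nm && occ[ti, tj] == 0L) {
      occ[i, j] <- 0L; occ[ti, tj] <- 1L
      ri[k] <- ti; ci[k] <- tj
    }
  }
  list(occ = occ, ids = ids, ri = ri, ci = ci, divisions = divStep,
       nextId = nextId)
}

#' Advance the automaton by one iteration
#'
#' Applies one full time step: cells act one at a time in a fresh uniformly
#' shuffled order; each cell first draws proliferation (probability `alpha`
#' when enabled; the mother stays and the daughter takes a uniformly chosen
#' free 8-neighbour, or nothing happens if none is free), otherwise it
#' samples a movement offset from its composed probability kernel and moves
#' only if the target site is free (volume exclusion — occupied targets
#' cancel the move). The chemotactic and mechanical kernels are evaluated on
#' the field and occupancy frozen at step entry; exclusion checks use the
#' live lattice. The chemoattractant field is then advanced once by
#' [chemoStep()] (with `fieldUpdate = "before"` in the parameters, the field
#' moves first instead); with chemotaxis off the field is left untouched.
#'
#' @param state a [CellState-class].
#' @param field a [ChemoField-class] of the same shape.
#' @param params a [SimulationParams-class].
#' @param flags a [MechanismFlags-class].
#' @return list with components `state`, `field` and `divisions` (a
#'   data.frame of `mother_id`, `daughter_id` for this step).
#' @export
advanceState <- function(state, field, params, flags = mechanismFlags()) {
  stopifnot(is(state, "CellState"), is(field, "ChemoField"),
            is(params, "SimulationParams"), is(flags, "MechanismFlags"))
  U <- field@values
  if (params@fieldUpdate == "before" && flags@chemoOn)
    U <- .chemoStepMatrix(U, state@occupancy, chemoScheme(params)@lam,
                          params@c1 * params@dt, params@c2 * params@dt)
  res <- .advanceCore(state@occupancy, state@cells$cell_id, state@cells$row,
                      state@cells$col, U, params, flags,
                      nextId = max(state@cells$cell_id, 0L) + 1L)
  if (params@fieldUpdate == "after" && flags@chemoOn)
    U <- .chemoStepMatrix(U, res$occ, chemoScheme(params)@lam,
                          params@c1 * params@dt, params@c2 * params@dt)
  divs <- if (length(res$divisions)) {
    dd <- do.call(rbind, res$divisions)
    data.frame(mother_id = dd[, 1], daughter_id = dd[, 2])
  } else data.frame(mother_id = integer(), daughter_id = integer())
  list(
    state = new("CellState",
                occupancy = res$occ,
                cells = data.frame(cell_id = res$ids, row = res$ri, col = res$ci),
                timeIndex = state@timeIndex + 1),
    field = new("ChemoField", values = U),
    divisions = divs
  )
}

#' Run a spheroid migration simulation
#'
#' Seeds the RNG from `params@seed`, builds the initial `d x d` spheroid
#' and zero chemical field, iterates the automaton `nSteps` times and
#' records every cell's lattice position at every step (step 0 included).
#' Identical `(params, d, flags, nSteps)` give bitwise-identical results.
#'
#' @param params a [SimulationParams-class].
#' @param d spheroid side in sites.
#' @param flags a [MechanismFlags-class].
#' @param nSteps number of iterations; defaults to the count covering
#'   `totalTimeH` at the step implied by `dt` (205 for the study defaults).
#' @param recordFields integer steps at which to keep a copy of the
#'   chemical field (named list in the result); empty by default.
#' @return a [SimulationResult-class].
#' @examples
#' p <- makeParams(m = 60, seed = 1)
#' res <- runSimulation(p, d = 5, nSteps = 20)
#' head(latticeTracks(res))
#' @export
runSimulation <- function(params, d, flags = mechanismFlags(),
                          nSteps = nStepsFor(params@totalTimeH,
                                             params@dt * params@totalTimeH * 60),
                          recordFields = integer()) {
  stopifnot(is(params, "SimulationParams"), is(flags, "MechanismFlags"))
  nSteps <- as.integer(nSteps)
  if (nSteps < 1L) stop("'nSteps' must be at least 1")
  set.seed(as.integer(params@seed))
  init <- initSpheroid(params@m, d)
  occ <- init$state@occupancy
  ids <- init$state@cells$cell_id
  ri <- init$state@cells$row
  ci <- init$state@cells$col
  U <- init$field@values
  lam <- chemoScheme(params)@lam
  c1dt <- params@c1 * params@dt
  c2dt <- params@c2 * params@dt
  nextId <- max(ids) + 1L
  idsL <- vector("list", nSteps + 1L)
  riL <- vector("list", nSteps + 1L)
  ciL <- vector("list", nSteps + 1L)
  stepL <- vector("list", nSteps + 1L)
  idsL[[1L]] <- ids; riL[[1L]] <- ri; ciL[[1L]] <- ci
  stepL[[1L]] <- rep.int(0L, length(ids))
  divL <- list()
  snaps <- list()
  if (0L %in% recordFields) snaps[["step0"]] <- U
  for (s in seq_len(nSteps)) {
    if (params@fieldUpdate == "before" && flags@chemoOn)
      U <- .chemoStepMatrix(U, occ, lam, c1dt, c2dt)
    res <- .advanceCore(occ, ids, ri, ci, U, params, flags, nextId)
    occ <- res$occ; ids <- res$ids; ri <- res$ri; ci <- res$ci
    nextId <- res$nextId
    if (params@fieldUpdate == "after" && flags@chemoOn)
      U <- .chemoStepMatrix(U, occ, lam, c1dt, c2dt)
    if (length(res$divisions))
      divL[[length(divL) + 1L]] <- cbind(s, do.call(rbind, res$divisions))
    idsL[[s + 1L]] <- ids; riL[[s + 1L]] <- ri; ciL[[s + 1L]] <- ci
    stepL[[s + 1L]] <- rep.int(s, length(ids))
    if (s %in% recordFields) snaps[[paste0("step", s)]] <- U
  }
  tracks <- data.frame(
    cell_id = unlist(idsL, use.names = FALSE),
    step = unlist(stepL, use.names = FALSE),
    row = unlist(riL, use.names = FALSE),
    col = unlist(ciL, use.names = FALSE)
  )
  divisions <- if (length(divL)) {
    dd <- do.call(rbind, divL)
    data.frame(step = dd[, 1], mother_id = dd[, 2], daughter_id = dd[, 3])
  } else data.frame(step = integer(), mother_id = integer(), daughter_id = integer())
  new("SimulationResult",
      params = params, flags = flags, tracks = tracks, divisions = divisions,
      finalState = new("CellState",
                       occupancy = occ,
                       cells = data.frame(cell_id = ids, row = ri, col = ci),
                       timeIndex = nSteps),
      finalField = new("ChemoField", values = U),
      fieldSnapshots = snaps, nSteps = nSteps)
}

#' Run a cohort of spheroid simulations
#'
#' One simulation per (diameter, seed) pair, the replication unit of the
#' migration assays (24 spheroids spanning 50-160 um in the reference
#' design). Diameters in micrometres are mapped to lattice sites by
#' `d = round(diameter / cellSizeUm)`; seeds default to `params@seed`
#' plus the run index. Vectors of unequal length are recycled pairwise to
#' the longer one, so a single diameter with `n` seeds gives `n`
#' independent replicates.
#'
#' @param diametersUm numeric vector of initial spheroid diameters (um).
#' @param params a [SimulationParams-class].
#' @param flags a [MechanismFlags-class].
#' @param nSteps iterations per run (default as in [runSimulation()]).
#' @param seeds optional integer vector of per-run seeds.
#' @return list of [SimulationResult-class], one per run.
#' @export
runCohort <- function(diametersUm, params, flags = mechanismFlags(),
                      nSteps = nStepsFor(params@totalTimeH,
                                         params@dt * params@totalTimeH * 60),
                      seeds = NULL) {
  if (!length(diametersUm)) stop("'diametersUm' must not be empty")
  if (is.null(seeds)) seeds <- params@seed + seq_along(diametersUm) - 1
  if (!length(seeds)) stop("'seeds' must not be empty")
  nRuns <- max(length(diametersUm), length(seeds))
  diametersUm <- rep_len(diametersUm, nRuns)
  seeds <- rep_len(seeds, nRuns)
  lapply(seq_len(nRuns), function(k) {
    d <- as.integer(round(diametersUm[k] / params@cellSizeUm))
    p <- params
    p@seed <- seeds[k]
    runSimulation(p, d = d, flags = flags, nSteps = nSteps)
  })
}
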