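# Vectorised explicit step on a bare matrix; `occ` may be integer or numeric.
.chemoStepMatrix <- function(U, occ, lam, c1dt, c2dt) {
  m <- nrow(U); n <- ncol(U)
  up    <- rbind(0, U[-m, , drop = FALSE])
  down  <- rbind(U[-1, , drop = FALSE], 0)
  left  <- cbind(0, U[, -n, drop = FALSE])
  right <- cbind(U[, -1, drop = FALSE], 0)
  (1 - 4 * lam) * U + lam * (up + down + left + right) +
    c1dt * occ - c2dt * U * occ
}

#' One explicit finite-difference step of the chemoattractant field
#'
#' Advances the reaction-diffusion equation
#' `du/dt = D (d2u/dx2 + d2u/dy2) + c1 n - c2 n u`
#' by one time step with the explicit five-point stencil: at every site
#' `U'[i,j] = (1 - 4 lam) U[i,j] + lam (U[i-1,j] + U[i+1,j] + U[i,j-1] +
#' U[i,j+1]) + c1 dt N[i,j] - c2 dt U[i,j] N[i,j]`, with `lam = D dt / h^2`
#' and zero-Dirichlet boundaries (concentration outside the lattice is 0).
#' Production is proportional to cell occupancy (cells secrete the
#' attractant), degradation to the local concentration at occupied sites.
#' Under the validity invariants (`lam <= 1/4`, `c2 dt <= 1`) the update
#' preserves nonnegativity.
#'
#' @param field a [ChemoField-class] (or bare matrix) at time t.
#' @param state a [CellState-class] (or bare 0/1 occupancy matrix), same
#'   shape.
#' @param params a [SimulationParams-class] supplying `D`, `c1`, `c2`, `dt`
#'   and `h`.
#' @param scheme optional [ChemoScheme-class]; defaults to
#'   `chemoScheme(params)`.
#' @return an object of the same kind as `field` at time t + dt.
#' @export
chemoStep <- function(field, state, params, scheme = chemoScheme(params)) {
  isField <- is(field, "ChemoField")
  U <- if (isField) field@values else field
  occ <- if (is(state, "CellState")) state@occupancy else state
  if (!is.matrix(U) || !is.matrix(occ) || !identical(dim(U), dim(occ)))
    stop("field and occupancy must be matrices of identical shape")
  if (!all(is.finite(U))) stop("non-finite concentrations in the field")
  out <- .chemoStepMatrix(U, occ, scheme@lam, params@c1 * params@dt,
                          params@c2 * params@dt)
  if (isField) new("ChemoField", values = out) else out
}
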