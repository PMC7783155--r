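# Offsets convention for all 3x3 kernels: rows are di = -1, 0, 1 and
# columns dj = -1, 0, 1 relative to the focal cell (matrix indexing, so
# di = +1 is one row down, dj = +1 is one column right).

.OFF <- expand.grid(di = -1:1, dj = -1:1, KEEP.OUT.ATTRS = FALSE)

.gaussWeights <- function(sigma) {
  di <- matrix(rep(-1:1, 3), 3, 3)
  dj <- t(di)
  w <- exp(-(di^2 + dj^2) / (2 * sigma^2))
  w[2, 2] <- 0
  w / sum(w)
}

#' Random-movement Gaussian kernel
#'
#' The 3x3 Gaussian stencil driving Brownian movement: weights proportional
#' to `exp(-(di^2 + dj^2) / (2 sigma^2))` at the eight neighbouring offsets,
#' a zero centre (the cell is encouraged to move away), renormalised to sum
#' exactly 1. The study uses `sigma = 2` sites.
#'
#' @param sigma standard deviation in lattice sites; positive.
#' @return a [ProbabilityKernel-class] summing to 1 with zero centre.
#' @examples
#' kernelWeights(gaussianKernel(2))
#' @export
gaussianKernel <- function(sigma) {
  stopifnot(is.numeric(sigma), length(sigma) == 1L, is.finite(sigma), sigma > 0)
  new("ProbabilityKernel", weights = .gaussWeights(sigma))
}

# Weighted gradient at (i, j); outside-lattice concentrations resolve per
# `boundary` ("zero" pads with 0, "error" refuses edge sites).
.gradientAt <- function(U, i, j, boundary = c("zero", "error")) {
  boundary <- match.arg(boundary)
  m <- nrow(U); n <- ncol(U)
  if (boundary == "error" && (i <= 1L || i >= m || j <= 1L || j >= n))
    stop("site on the lattice edge; use boundary = \"zero\" to clamp")
  gv <- function(a, b) if (a >= 1L && a <= m && b >= 1L && b <= n) U[a, b] else 0
  sat <- (1 + 3 * U[i, j])^2
  c(mux = (gv(i, j + 1L) - gv(i, j - 1L)) / sat,
    muy = (gv(i + 1L, j) - gv(i - 1L, j)) / sat)
}

# Chemotactic 3x3 weights from a precomputed gradient; ties in |mu| broken
# uniformly at random (consumes one uniform draw only on a tie).
.chemoWeightsFromMu <- function(mux, muy) {
  w <- matrix(0, 3, 3)
  ax <- abs(mux); ay <- abs(muy)
  if (ax == 0 && ay == 0) return(w)
  useX <- if (ax > ay) TRUE else if (ay > ax) FALSE else runif(1) < 0.5
  if (useX) {
    w[2, if (mux > 0) 3 else 1] <- ax
  } else {
    w[if (muy > 0) 3 else 1, 2] <- ay
  }
  w
}

#' Chemotactic movement kernel at one site
#'
#' Samples the chemoattractant field around a cell and computes the weighted
#' gradient with receptor saturation,
#' `mu_x = (U[i, j+1] - U[i, j-1]) / (1 + 3 u)^2` (and the analogue in `y`),
#' where `u` is the concentration at the cell's own site. The returned
#' kernel is all-zero when the field is locally uniform; otherwise it holds
#' the single value `|mu|` at the cardinal offset pointing up the axis of
#' larger `|mu|` (an attractant direction; a repellent `cf < 0` reverses it
#' during composition). Ties `|mu_x| = |mu_y|` are broken uniformly at
#' random.
#'
#' @param field a [ChemoField-class] or bare concentration matrix.
#' @param site integer `(row, col)` of the cell.
#' @param boundary `"error"` (default) rejects sites on the lattice edge;
#'   `"zero"` treats outside concentrations as zero, matching the solver's
#'   Dirichlet boundary.
#' @return a [ProbabilityKernel-class] with at most one nonzero entry.
#' @export
chemoKernel <- function(field, site, boundary = c("error", "zero")) {
  boundary <- match.arg(boundary)
  U <- if (is(field, "ChemoField")) field@values else field
  stopifnot(is.matrix(U), length(site) == 2L)
  mu <- .gradientAt(U, as.integer(site[1]), as.integer(site[2]),
                    boundary = if (boundary == "error") "error" else "zero")
  new("ProbabilityKernel", weights = .chemoWeightsFromMu(mu[["mux"]], mu[["muy"]]))
}

# Occupancy convolved with the all-ones window of side 2*order+1
# (zero-padded), vectorised over the whole lattice.
.convOnes <- function(occ, order) {
  m <- nrow(occ); n <- ncol(occ); k <- as.integer(order)
  pad <- matrix(0, m + 2L * k, n + 2L * k)
  pad[(k + 1L):(k + m), (k + 1L):(k + n)] <- occ
  out <- matrix(0, m, n)
  for (a in -k:k) for (b in -k:k)
    out <- out + pad[(k + 1L + a):(k + m + a), (k + 1L + b):(k + n + b)]
  out
}

# Mechanical 3x3 weights from the precomputed convolution; `cv` must carry
# the focal cell's own contribution (it is subtracted here).
.mechWeightsFromConv <- function(conv, i, j) {
  m <- nrow(conv); n <- ncol(conv)
  w <- matrix(0, 3, 3)
  for (a in -1:1) for (b in -1:1) {
    ii <- i + a; jj <- j + b
    if (ii >= 1L && ii <= m && jj >= 1L && jj <= n)
      w[a + 2L, b + 2L] <- conv[ii, jj] - 1
  }
  w[2, 2] <- 0
  w[w < 0] <- 0
  s <- sum(w)
  if (s > 0) w / s else w
}

#' Mechanical interaction kernel at one occupied site
#'
#' Convolves the occupancy lattice with an all-ones window of side
#' `2 * order + 1`, crops the 3x3 patch centred on the focal cell, subtracts
#' the cell's own contribution to the counts, zeroes the centre and
#' normalises to sum 1 — a map of attractive forces toward neighbouring
#' cells. An isolated cell yields the all-zero kernel. Movement is always to
#' adjacent sites, so `order = 2` widens the window cells are sensed over
#' but still emits a 3x3 kernel.
#'
#' @param state a [CellState-class] or bare 0/1 occupancy matrix.
#' @param site integer `(row, col)`; must be occupied.
#' @param order neighbour interaction range, 1 or 2.
#' @return a [ProbabilityKernel-class] (sum 1, or all-zero for an isolated
#'   cell).
#' @export
mechanicalKernel <- function(state, site, order = 1) {
  occ <- if (is(state, "CellState")) state@occupancy else state
  stopifnot(is.matrix(occ), length(site) == 2L, order %in% c(1, 2))
  i <- as.integer(site[1]); j <- as.integer(site[2])
  if (occ[i, j] != 1) stop("mechanical kernel requires an occupied focal site")
  cv <- .convOnes(occ, order)
  new("ProbabilityKernel", weights = .mechWeightsFromConv(cv, i, j))
}

# Core composition on bare matrices; returns weights summing to at most 1,
# the residual being the stay probability.
.composeWeights <- function(gw, cw, iw, r, cf, q) {
  if (cf < 0 && any(cw > 0)) {
    # repellent: push down-gradient, i.e. to the reflected offset
    cw <- cw[3:1, 3:1]
    cf <- -cf
  }
  w <- r * gw + cf * cw + q * iw
  w[w < 0] <- 0
  w[2, 2] <- 0
  s <- sum(w)
  if (s > 1) w / s else w
}

#' Compose the per-cell movement probability kernel
#'
#' Weighted combination of the mechanism kernels,
#' `P' = r * G + cf * C + q * I`. Negative entries are clipped to zero and,
#' when the total exceeds 1, the kernel is normalised to sum 1. A total
#' below 1 is kept as is: the residual `1 - sum(P)` is the probability of
#' staying put, which is what makes `r` alone act as the probability of
#' performing a random step (no renormalisation when only random movement is
#' active). A repellent chemoattractant (`cf < 0`) contributes `|cf| * C`
#' reflected through the centre, i.e. movement down-gradient. The all-zero
#' kernel (cell certainly stays) is returned when every contribution
#' vanishes.
#'
#' @param G,C,I [ProbabilityKernel-class] objects: random, chemotactic and
#'   mechanical kernels (pass `zeroKernel()` for an inactive mechanism).
#' @param params a [SimulationParams-class] supplying `r`, `cf` and `q`.
#' @return a [ProbabilityKernel-class] with zero centre, summing to at most 1.
#' @examples
#' p <- makeParams(cf = 0, q = 0)
#' composeProbability(gaussianKernel(2), zeroKernel(), zeroKernel(), p)
#' @export
composeProbability <- function(G, C, I, params) {
  w <- .composeWeights(kernelWeights(G), kernelWeights(C), kernelWeights(I),
                       params@r, params@cf, params@q)
  new("ProbabilityKernel", weights = w)
}

#' @rdname composeProbability
#' @export
zeroKernel <- function() new("ProbabilityKernel", weights = matrix(0, 3, 3))
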