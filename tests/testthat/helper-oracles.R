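# Independent oracles kept deliberately naive (double loops, brute-force
# enumeration) so they share no code path with the implementation.

# Five-point explicit stencil, zero concentration outside the lattice.
chemoStepOracle <- function(U, N, lam, c1dt, c2dt) {
  m <- nrow(U); n <- ncol(U)
  out <- matrix(0, m, n)
  at <- function(i, j) if (i >= 1 && i <= m && j >= 1 && j <= n) U[i, j] else 0
  for (i in seq_len(m)) for (j in seq_len(n)) {
    out[i, j] <- (1 - 4 * lam) * U[i, j] +
      lam * (at(i - 1, j) + at(i + 1, j) + at(i, j - 1) + at(i, j + 1)) +
      c1dt * N[i, j] - c2dt * U[i, j] * N[i, j]
  }
  out
}

# Diffusive mass lost over the zero-Dirichlet boundary in one step:
# every off-lattice neighbour drains lam * U from its boundary site.
boundaryOutflowOracle <- function(U, lam) {
  m <- nrow(U); n <- ncol(U)
  loss <- 0
  for (i in seq_len(m)) for (j in seq_len(n)) {
    k <- sum(c(i == 1, i == m, j == 1, j == n))
    loss <- loss + k * lam * U[i, j]
  }
  loss
}

# Brute-force mechanical kernel: count occupied sites inside the ones
# window around each neighbouring site, subtract the focal cell, zero the
# centre, normalise.
mechKernelOracle <- function(occ, i, j, order = 1) {
  m <- nrow(occ); n <- ncol(occ)
  w <- matrix(0, 3, 3)
  for (a in -1:1) for (b in -1:1) {
    ii <- i + a; jj <- j + b
    if (ii < 1 || ii > m || jj < 1 || jj > n) next
    cnt <- 0
    for (p in -order:order) for (q in -order:order) {
      pi <- ii + p; qj <- jj + q
      if (pi >= 1 && pi <= m && qj >= 1 && qj <= n && occ[pi, qj] == 1) cnt <- cnt + 1
    }
    # the focal cell always falls inside the window of an adjacent site
    w[a + 2, b + 2] <- cnt - 1
  }
  w[2, 2] <- 0
  w[w < 0] <- 0
  if (sum(w) > 0) w / sum(w) else w
}

# Rotate a square matrix 90 degrees counter-clockwise.
rot90 <- function(x) t(x)[ncol(x):1, , drop = FALSE]

# A minimal valid track table: `radii` at t0, `radii2` at t1, all cells on
# the positive x-axis around `centroid`.
radialTracks <- function(radii, radii2, centroid = c(0, 0), dtS = 600) {
  n <- length(radii)
  data.frame(
    track_id = rep(seq_len(n), each = 2),
    time_s = rep(c(0, dtS), n),
    x_um = centroid[1] + as.vector(rbind(radii, radii2)),
    y_um = centroid[2]
  )
}

# Final mean RRM of one simulated spheroid.
finalRRM <- function(result) {
  tr <- resultTracks(result)
  rrm <- meanRRM(tr, initialCentroid(tr))
  rrm$rrm[nrow(rrm)]
}
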