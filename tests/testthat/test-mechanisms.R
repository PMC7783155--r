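test_that("Gaussian kernel sums to 1, has a zero centre and the right decay", {
  G <- kernelWeights(gaussianKernel(2))
  expect_equal(sum(G), 1)
  expect_identical(G[2, 2], 0)
  # corner-to-edge ratio exp(-2/8) / exp(-1/8) = exp(-1/8)
  expect_equal(G[1, 1] / G[1, 2], exp(-1 / 8))
  expect_error(gaussianKernel(0))
  expect_error(gaussianKernel(-1))
})

test_that("Gaussian kernel is invariant under the eight square symmetries", {
  G <- kernelWeights(gaussianKernel(2))
  expect_identical(G, t(G))
  expect_identical(G, rot90(G))
  expect_identical(G, G[3:1, ])
  expect_identical(G, G[, 3:1])
})

test_that("chemotactic kernel follows the saturated weighted gradient", {
  # locally uniform field: no gradient, all-zero kernel
  U <- matrix(0.7, 5, 5)
  expect_true(all(kernelWeights(chemoKernel(U, c(3, 3))) == 0))

  # pure x-gradient: U[i, j-1] = 0, U[i, j] = u0, U[i, j+1] = 2*delta
  delta <- 0.05
  for (u0 in c(0, 0.2, 1)) {
    U <- matrix(0, 5, 5)
    U[3, 3] <- u0
    U[3, 4] <- 2 * delta
    w <- kernelWeights(chemoKernel(U, c(3, 3)))
    expect_equal(w[2, 3], 2 * delta / (1 + 3 * u0)^2)  # east entry
    expect_equal(sum(w != 0), 1)
  }
  # receptor saturation: same gradient, higher local concentration, weaker pull
  mk <- function(u0) {
    U <- matrix(0, 5, 5); U[3, 3] <- u0; U[3, 4] <- 2 * delta
    max(kernelWeights(chemoKernel(U, c(3, 3))))
  }
  expect_gt(mk(0.1), mk(0.5))

  # dominant y-gradient wins the axis choice and picks the downhill/uphill sign
  U <- matrix(0, 5, 5); U[4, 3] <- 1; U[3, 4] <- 0.2
  w <- kernelWeights(chemoKernel(U, c(3, 3)))
  expect_gt(w[3, 2], 0)  # toward larger row (up-gradient in y)
  expect_equal(sum(w != 0), 1)

  # edges rejected unless clamped to the Dirichlet boundary
  expect_error(chemoKernel(U, c(1, 3)), "edge")
  expect_s4_class(chemoKernel(U, c(1, 3), boundary = "zero"), "ProbabilityKernel")
})

test_that("mechanical kernel matches the brute-force convolution oracle", {
  # isolated cell: self-subtraction leaves nothing
  occ <- matrix(0L, 7, 7); occ[4, 4] <- 1L
  expect_true(all(kernelWeights(mechanicalKernel(occ, c(4, 4))) == 0))

  # one neighbour due east: five equal 1/5 weights on the east-side offsets
  occ[4, 5] <- 1L
  w <- kernelWeights(mechanicalKernel(occ, c(4, 4)))
  expected <- matrix(0, 3, 3)
  expected[, 2:3] <- 1 / 5
  expected[2, 2] <- 0
  expect_equal(w, expected)
  expect_equal(w, mechKernelOracle(occ, 4, 4))

  # fully surrounded: strictly positive on all eight offsets, sum 1
  occ <- matrix(0L, 7, 7); occ[3:5, 3:5] <- 1L
  w <- kernelWeights(mechanicalKernel(occ, c(4, 4)))
  expect_equal(sum(w), 1)
  expect_true(all(w[-5] > 0))
  expect_identical(w[2, 2], 0)

  expect_error(mechanicalKernel(occ, c(1, 1)), "occupied")
})

test_that("mechanical kernel equals the oracle on random neighbourhoods, both orders", {
  set.seed(7)
  for (k in 1:30) {
    occ <- matrix(rbinom(81, 1, 0.4), 9, 9)
    occ[5, 5] <- 1L
    for (ord in c(1, 2)) {
      expect_equal(kernelWeights(mechanicalKernel(occ, c(5, 5), order = ord)),
                   mechKernelOracle(occ, 5, 5, order = ord),
                   tolerance = 1e-12)
    }
  }
})

test_that("mechanical kernel is equivariant under lattice rotation", {
  set.seed(8)
  for (k in 1:10) {
    occ <- matrix(rbinom(49, 1, 0.4), 7, 7)
    occ[4, 4] <- 1L
    w <- kernelWeights(mechanicalKernel(occ, c(4, 4)))
    wr <- kernelWeights(mechanicalKernel(rot90(occ), c(4, 4)))
    expect_equal(wr, rot90(w), tolerance = 1e-12)
  }
})

test_that("probability composition weighs, clips and renormalises as specified", {
  p <- makeParams()
  G <- gaussianKernel(2)
  # with no chemotactic or mechanical contribution and r = 1, P = G
  expect_equal(kernelWeights(composeProbability(G, zeroKernel(), zeroKernel(), p)),
               kernelWeights(G))

  # worked composition: C = 0.01 at east, I = 1/5 on the five east-side offsets
  cw <- matrix(0, 3, 3); cw[2, 3] <- 0.01
  iw <- matrix(0, 3, 3); iw[, 2:3] <- 1 / 5; iw[2, 2] <- 0
  C <- new("ProbabilityKernel", weights = cw)
  I <- new("ProbabilityKernel", weights = iw)
  raw <- kernelWeights(G) + 20 * cw + 0.3 * iw
  expect_equal(kernelWeights(composeProbability(G, C, I, p)), raw / sum(raw))

  # r alone is a movement probability: no renormalisation below total 1
  pr <- makeParams(r = 0.4, cf = 0, q = 0)
  w <- kernelWeights(composeProbability(G, zeroKernel(), zeroKernel(), pr))
  expect_equal(sum(w), 0.4)
  expect_equal(w, 0.4 * kernelWeights(G))

  # repellent: the chemotactic mass flips to the opposite offset
  prep <- makeParams(cf = -20, r = 0, q = 0)
  w <- kernelWeights(composeProbability(zeroKernel(), C, zeroKernel(), prep))
  expect_equal(w[2, 1], 0.2)  # |cf| * C at the reflected (west) offset
  expect_equal(sum(w), 0.2)

  # everything zero: degenerate stay-put kernel
  w0 <- kernelWeights(composeProbability(zeroKernel(), zeroKernel(), zeroKernel(), p))
  expect_true(all(w0 == 0))
})

test_that("one chemo step from a clean field deposits c1*dt at occupied sites only", {
  p <- makeParams()
  m <- 9
  occ <- matrix(0L, m, m); occ[5, 5] <- 1L
  U1 <- chemoStep(matrix(0, m, m), occ, p)
  expect_equal(U1[5, 5], p@c1 * p@dt)
  expect_equal(U1[5, 5], 1.701389e-4, tolerance = 1e-6)
  expect_true(all(U1[-which(occ == 1L)] == 0))
  # no cells at all: the field stays identically zero
  expect_true(all(chemoStep(matrix(0, m, m), matrix(0L, m, m), p) == 0))
})

test_that("chemo solver matches the double-loop stencil oracle elementwise", {
  set.seed(21)
  p <- makeParams()
  sch <- chemoScheme(p)
  for (k in 1:50) {
    m <- sample(5:20, 1); n <- sample(5:20, 1)
    U <- matrix(runif(m * n, 0, 2), m, n)
    N <- matrix(rbinom(m * n, 1, 0.3), m, n)
    got <- chemoStep(U, N, p)
    want <- chemoStepOracle(U, N, sch@lam, p@c1 * p@dt, p@c2 * p@dt)
    expect_equal(got, want, tolerance = 1e-12)
  }
})

test_that("chemo mass balance: production minus degradation minus boundary outflow", {
  set.seed(22)
  p <- makeParams()
  lam <- chemoScheme(p)@lam
  for (k in 1:20) {
    m <- sample(6:20, 1)
    U <- matrix(runif(m * m, 0, 3), m, m)
    N <- matrix(rbinom(m * m, 1, 0.3), m, m)
    U1 <- chemoStep(U, N, p)
    lhs <- sum(U1) - sum(U)
    rhs <- p@c1 * p@dt * sum(N) - p@c2 * p@dt * sum(U * N) -
      boundaryOutflowOracle(U, lam)
    expect_equal(lhs, rhs, tolerance = 1e-10)
  }
})

test_that("pure diffusion conserves interior mass and never gains it", {
  p <- makeParams(c1 = 0, c2 = 0)
  m <- 21
  U <- matrix(0, m, m); U[9:13, 9:13] <- runif(25)
  N <- matrix(0L, m, m)
  total0 <- sum(U)
  for (s in 1:5) U <- chemoStep(U, N, p)   # support stays far from the edge
  expect_equal(sum(U), total0, tolerance = 1e-12)
  # with mass at the boundary, zero-Dirichlet leaks: non-increasing
  U <- matrix(runif(m * m), m, m)
  expect_lt(sum(chemoStep(U, N, p)), sum(U))
})

test_that("chemo step preserves nonnegativity when 4*lambda + c2*dt <= 1", {
  # at an occupied site the centre coefficient is 1 - 4*lambda - c2*dt,
  # so nonnegativity needs the joint bound (the study defaults satisfy it)
  set.seed(23)
  for (k in 1:30) {
    dt <- runif(1, 1e-4, 0.005)
    D <- runif(1, 0, 0.25 / dt)
    c2 <- runif(1, 0, (1 - 4 * D * dt) / dt)
    p <- makeParams(D = D, c2 = c2, dt = dt, c1 = runif(1, 0, 0.1))
    m <- sample(5:12, 1)
    U <- matrix(runif(m * m, 0, 5), m, m)
    N <- matrix(rbinom(m * m, 1, 0.5), m, m)
    expect_true(all(chemoStep(U, N, p) >= 0))
  }
})

test_that("chemo step rejects malformed input", {
  p <- makeParams()
  expect_error(chemoStep(matrix(0, 4, 4), matrix(0L, 5, 5), p), "shape")
  U <- matrix(0, 4, 4); U[1, 1] <- NaN
  expect_error(chemoStep(U, matrix(0L, 4, 4), p), "finite")
})
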