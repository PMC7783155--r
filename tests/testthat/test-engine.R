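# Engine tests run on small lattices; the full-scale study conditions are
# exercised by the acceptance suite.

smallParams <- function(...) makeParams(m = 40, ...)

test_that("advancing one step preserves cell count and exclusion", {
  p <- smallParams(seed = 5)
  init <- initSpheroid(p@m, 5)
  set.seed(5)
  out <- advanceState(init$state, init$field, p, mechanismFlags())
  expect_s4_class(out$state, "CellState")   # validity enforces exclusion
  expect_equal(nrow(cellTable(out$state)), 25)
  expect_true(all(occupancy(out$state) %in% 0:1))
  expect_equal(sum(occupancy(out$state)), 25)
  expect_equal(out$state@timeIndex, 1)
  expect_equal(nrow(out$divisions), 0)
})

test_that("two adjacent cells can never overlap under sequential update", {
  p <- makeParams(m = 6, cf = 0, q = 1, seed = 9)
  occ <- matrix(0L, 6, 6); occ[3, 3] <- 1L; occ[3, 4] <- 1L
  st <- new("CellState", occupancy = occ,
            cells = data.frame(cell_id = 1:2, row = c(3L, 3L), col = c(3L, 4L)),
            timeIndex = 0)
  fl <- new("ChemoField", values = matrix(0, 6, 6))
  set.seed(9)
  for (s in 1:50) {
    out <- advanceState(st, fl, p, mechanismFlags(chemotaxis = FALSE))
    st <- out$state
    expect_true(all(occupancy(st) %in% 0:1))
    expect_equal(sum(occupancy(st)), 2)
  }
})

test_that("a certain division leaves the mother still and places one daughter", {
  p <- smallParams(alpha = 1, seed = 3)
  init <- initSpheroid(p@m, 1)
  mother <- cellTable(init$state)
  set.seed(3)
  out <- advanceState(init$state, init$field, p,
                      mechanismFlags(proliferation = TRUE))
  cl <- cellTable(out$state)
  expect_equal(nrow(cl), 2)
  expect_equal(cl[cl$cell_id == 1, c("row", "col")],
               mother[, c("row", "col")])
  daughter <- cl[cl$cell_id == 2, ]
  expect_lte(max(abs(c(daughter$row - mother$row, daughter$col - mother$col))), 1)
  expect_equal(out$divisions,
               data.frame(mother_id = 1, daughter_id = 2))
})

test_that("with alpha = 0 the cell count is conserved over a full run", {
  p <- smallParams(seed = 2)
  res <- runSimulation(p, d = 4, nSteps = 60)
  tr <- latticeTracks(res)
  counts <- table(tr$step)
  expect_true(all(counts == 16))
  expect_equal(nrow(divisionEvents(res)), 0)
  # exclusion at every recorded step
  for (s in unique(tr$step)) {
    at <- tr[tr$step == s, ]
    expect_false(anyDuplicated(at[, c("row", "col")]) > 0)
  }
})

test_that("proliferation grows the population and logs consistent events", {
  p <- smallParams(alpha = 0.05, seed = 4)
  res <- runSimulation(p, d = 3, nSteps = 40)
  div <- divisionEvents(res)
  expect_gt(nrow(div), 0)
  expect_equal(nrow(cellTable(res)), 9 + nrow(div))
  # daughters appear in the tracks from their birth step onward
  tr <- latticeTracks(res)
  for (k in seq_len(nrow(div))) {
    born <- tr[tr$cell_id == div$daughter_id[k], ]
    expect_equal(min(born$step), div$step[k])
  }
})

test_that("identical parameters and seed reproduce a run bit-exactly", {
  p <- smallParams(seed = 31)
  a <- runSimulation(p, d = 5, nSteps = 30)
  b <- runSimulation(p, d = 5, nSteps = 30)
  expect_identical(latticeTracks(a), latticeTracks(b))
  expect_identical(occupancy(a), occupancy(b))
  expect_identical(fieldValues(a), fieldValues(b))
  c <- runSimulation(makeParams(m = 40, seed = 32), d = 5, nSteps = 30)
  expect_false(identical(latticeTracks(a), latticeTracks(c)))
})

test_that("runs record positions at every step including step zero", {
  p <- smallParams(seed = 1)
  res <- runSimulation(p, d = 2, nSteps = 1)
  expect_setequal(unique(latticeTracks(res)$step), c(0, 1))
  expect_error(runSimulation(p, d = 2, nSteps = 0), "at least 1")
  snaps <- runSimulation(p, d = 2, nSteps = 3, recordFields = c(0, 2))
  expect_named(snaps@fieldSnapshots, c("step0", "step2"))
})

test_that("ablation switches exactly the named mechanism off, idempotently", {
  fl <- mechanismFlags()
  off <- ablate(fl, "chemotaxis")
  expect_false(off@chemoOn)
  expect_true(off@randomOn && off@mechOn && off@proliferationOn)
  expect_identical(ablate(off, "chemotaxis"), off)
  expect_false(ablate(fl, "mechanics")@mechOn)
  expect_false(ablate(fl, "random")@randomOn)
  expect_false(ablate(fl, "proliferation")@proliferationOn)
  expect_error(ablate(fl, "gravity"))
})

test_that("cohorts map diameters to sites and honour pairwise seeds", {
  p <- smallParams()
  res <- runCohort(c(50, 80), p, nSteps = 2)
  expect_length(res, 2)
  expect_equal(nrow(latticeTracks(res[[1]])[latticeTracks(res[[1]])$step == 0, ]), 25)
  expect_equal(nrow(latticeTracks(res[[2]])[latticeTracks(res[[2]])$step == 0, ]), 64)
  # single diameter, several seeds: independent replicates
  reps <- runCohort(60, p, nSteps = 5, seeds = c(11, 12, 13))
  expect_length(reps, 3)
  expect_equal(vapply(reps, function(r) r@params@seed, numeric(1)), c(11, 12, 13))
  expect_false(identical(latticeTracks(reps[[1]]), latticeTracks(reps[[2]])))
  # 160 um at 10 um sites is a 16-site spheroid
  r160 <- runCohort(160, makeParams(m = 60), nSteps = 1)
  expect_equal(sum(latticeTracks(r160[[1]])$step == 0), 256)
  expect_error(runCohort(numeric(), p), "empty")
})

test_that("a lone random walker spreads diffusively (MSD linear in step count)", {
  ronly <- mechanismFlags(chemotaxis = FALSE, mechanics = FALSE, proliferation = FALSE)
  nrep <- 60
  steps <- 40
  sq <- matrix(0, nrep, steps + 1)
  for (k in seq_len(nrep)) {
    p <- makeParams(m = 31, seed = 400 + k)
    tr <- latticeTracks(runSimulation(p, d = 1, flags = ronly, nSteps = steps))
    sq[k, ] <- (tr$row - tr$row[1])^2 + (tr$col - tr$col[1])^2
  }
  msd <- colMeans(sq)
  fit <- lm(msd ~ seq(0, steps))
  expect_gt(summary(fit)$r.squared, 0.95)
  expect_gt(coef(fit)[2], 0)
})
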