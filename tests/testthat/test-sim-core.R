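test_that("SAW initialisation honours its geometric contract", {
  # degenerate single bead sits at the box centre
  c1 <- initSawConformation(1, 20, seed = 1)
  expect_equal(c1@beadPos, matrix(10, 1, 3), ignore_attr = TRUE)
  # determinism: identical coordinates for the same seed
  a <- initSawConformation(10, 20, seed = 7)
  b <- initSawConformation(10, 20, seed = 7)
  expect_identical(a@beadPos, b@beadPos)
  expect_identical(a@beadVel, b@beadVel)
  # all-pairs scan: unit bonds, nonbonded clearance >= 1 sigma
  cf <- initSawConformation(50, 30, seed = 11)
  d <- as.matrix(dist(cf@beadPos))
  bonds <- d[cbind(1:49, 2:50)]
  expect_equal(bonds, rep(1, 49), tolerance = 1e-12)
  nb <- d; diag(nb) <- NA
  nb[cbind(1:49, 2:50)] <- NA; nb[cbind(2:50, 1:49)] <- NA
  expect_gte(min(nb, na.rm = TRUE), 1)
  # an impossible box fails with a clear message
  expect_error(initSawConformation(500, 3, seed = 1), "box too small")
})

test_that("Langevin stepping is deterministic and preserves FENE bonds", {
  m <- buildCompartmentModel(nBeads = 20, blockSize = 10, g = 1e5)
  cfg <- simulationConfig(boxL = 15, binderCounts = c(A = 5, B = 5))
  cf <- initSawConformation(20, 15, seed = 2, binderCounts = c(A = 5, B = 5))
  s1 <- langevinStep(cf, m, cfg, nSteps = 200, seed = 5)
  s2 <- langevinStep(cf, m, cfg, nSteps = 200, seed = 5)
  expect_identical(s1@beadPos, s2@beadPos)
  expect_identical(s1@binderPos, s2@binderPos)
  bond <- sqrt(rowSums((s1@beadPos[-1, ] - s1@beadPos[-20, ])^2))
  expect_true(all(bond < 1.6))
  # different seeds diverge
  s3 <- langevinStep(cf, m, cfg, nSteps = 200, seed = 6)
  expect_false(identical(s1@beadPos, s3@beadPos))
})

test_that("zeta = 0 reduces to NVE velocity Verlet with bounded energy drift", {
  m <- buildCompartmentModel(nBeads = 20, blockSize = 20, g = 1e5)
  # thermalise first so the drift bound is measured at equilibrium
  cfgT <- simulationConfig(boxL = 15, binderCounts = c(A = 8, B = 0))
  cf <- initSawConformation(20, 15, seed = 3, binderCounts = c(A = 8, B = 0))
  cf <- langevinStep(cf, m, cfgT, nSteps = 3000, seed = 42)
  cfgN <- simulationConfig(zeta = 0, boxL = 15,
                           nEquilSteps = 0, nProductionSteps = 1e4,
                           sampleInterval = 100,
                           binderCounts = c(A = 8, B = 0))
  ea <- chrom4d:::engineArgs(m, cfgN, cf)
  res <- chrom4d:::.cpp_run_engine(cf@beadPos, cf@beadVel, cf@binderPos,
                                   cf@binderVel, ea$typeIdx, ea$eps, m@rInt,
                                   15, 0.01, 0, 1, 10000L, 100L, 9L, FALSE,
                                   chrom4d:::emptyLegs(),
                                   chrom4d:::emptyHalted(),
                                   ea$orient, ea$prob, 0, TRUE, 0L,
                                   1.6, 30, 10, 1.1)
  E <- res$ke + res$pe
  # declared bound: < 5% relative drift over 1e4 steps at dt = 0.01 (the
  # attraction cutoff carries a force discontinuity; see the vignette)
  expect_lt((max(E) - min(E)) / abs(mean(E)), 0.05)
})

test_that("replica scheduling yields the exact frame count and distinct endpoints", {
  m <- buildCompartmentModel(nBeads = 15, blockSize = 15, g = 1e5)
  cfg <- simulationConfig(nEquilSteps = 1e3, nProductionSteps = 1e4,
                          sampleInterval = 1e3, nReplicas = 2,
                          seeds = c(5L, 9L), boxL = 15,
                          binderCounts = c(A = 4, B = 0))
  ens <- runReplicas(m, cfg)
  expect_length(trajectories(ens), 2)
  for (tr in trajectories(ens)) {
    expect_equal(dim(tr@frames)[3], 10)           # 1e4 / 1e3 frames
    expect_equal(diff(tr@times), rep(1e3, 9))
  }
  t1 <- trajectories(ens)[[1]]; t2 <- trajectories(ens)[[2]]
  expect_false(identical(t1@frames[, , 10], t2@frames[, , 10]))
  # determinism of the whole pipeline under identical seeds
  ens2 <- runReplicas(m, cfg)
  expect_identical(trajectories(ens2)[[1]]@frames, t1@frames)
})

test_that("cell/Verlet neighbour forces match the all-pairs reference", {
  m <- buildCompartmentModel(nBeads = 30, blockSize = 10, g = 1e5)
  cf <- initSawConformation(30, 18, seed = 13,
                            binderCounts = c(A = 10, B = 10))
  cfg <- simulationConfig(boxL = 18, binderCounts = c(A = 10, B = 10))
  cf <- langevinStep(cf, m, cfg, nSteps = 500, seed = 77)
  ea <- chrom4d:::engineArgs(m, cfg, cf)
  fList <- chrom4d:::.cpp_compute_forces(cf@beadPos, cf@binderPos, ea$typeIdx,
                                         ea$eps, m@rInt, 18, FALSE, 1.6, 30)
  fAll <- chrom4d:::.cpp_compute_forces(cf@beadPos, cf@binderPos, ea$typeIdx,
                                        ea$eps, m@rInt, 18, TRUE, 1.6, 30)
  expect_equal(fList, fAll, tolerance = 1e-12)
})

test_that("binder-mediated attraction collapses a cognate homopolymer", {
  # coil-globule contrast at small N: affinity 3.8 vs no attraction
  rgOf <- function(aff, seed) {
    m <- buildTadModel("plain", nBeads = 60, affinity = 3.8)
    m@extrusion@nExtruders <- 0L
    if (aff == 0) m@affinity[] <- 0
    cfg <- simulationConfig(nEquilSteps = 2e4, nProductionSteps = 2e4,
                            sampleInterval = 2e3, boxL = 20,
                            seeds = seed, binderCounts = c(B1 = 30))
    tr <- runSimulation(m, cfg, seed = seed)
    mean(vapply(seq_len(dim(tr@frames)[3]), function(f)
      gyrationShape(tr@frames[, , f])$rg, numeric(1)))
  }
  rgOpen <- mean(vapply(1:2, function(s) rgOf(0, s), numeric(1)))
  rgGlob <- mean(vapply(3:4, function(s) rgOf(3.8, s), numeric(1)))
  expect_lt(rgGlob, rgOpen * 0.75)
})
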