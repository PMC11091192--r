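test_that("extruder seeding places the exact count on disjoint adjacent pairs", {
  p <- extrusionParams(nExtruders = 10)
  ex <- seedExtruders(p, nBeads = 100, seed = 3)
  expect_equal(nrow(ex), 10)
  expect_true(all(ex$j == ex$i + 1))
  expect_false(anyDuplicated(c(ex$i, ex$j)) > 0)
  expect_error(seedExtruders(extrusionParams(nExtruders = 60), nBeads = 100),
               "without overlap")
  # separation arithmetic: 120 beads separation on a 1200-bead polymer
  p2 <- extrusionParams(separationKb = 120, nBeads = 1200, g = 1000)
  expect_equal(p2@nExtruders, 10L)
  # zero extruders is the pure phase-separation model
  expect_equal(nrow(seedExtruders(extrusionParams(nExtruders = 0), 50)), 0)
})

test_that("a free extruder slides symmetrically outward", {
  ex <- data.frame(i = 10L, j = 20L, haltedLeft = FALSE, haltedRight = FALSE)
  out <- extrusionStep(ex, nBeads = 100, seed = 1)
  expect_equal(out$i, 9L)
  expect_equal(out$j, 21L)
  # polymer ends: legs wait without wraparound
  ex2 <- data.frame(i = 0L, j = 99L, haltedLeft = FALSE, haltedRight = FALSE)
  out2 <- extrusionStep(ex2, nBeads = 100, seed = 1)
  expect_equal(out2$i, 0L)
  expect_equal(out2$j, 99L)
})

test_that("extruders never cross and block each other without pass-through", {
  # exhaustive small-case: walk many updates, assert disjoint leg occupancy
  # and no interleaving (i1 < i2 < j1 < j2 forbidden) at every update
  for (seed in 1:5) {
    ex <- seedExtruders(extrusionParams(nExtruders = 6), nBeads = 30,
                        seed = seed)
    for (u in 1:40) {
      ex <- extrusionStep(ex, nBeads = 30, seed = seed * 100 + u)
      occ <- c(ex$i, ex$j)
      expect_false(anyDuplicated(occ) > 0)
      for (a in seq_len(nrow(ex))) for (b in seq_len(nrow(ex))) {
        if (a == b) next
        crossing <- ex$i[a] < ex$i[b] & ex$i[b] < ex$j[a] & ex$j[a] < ex$j[b]
        expect_false(crossing)
      }
    }
  }
  # deterministic head-on block: two extruders converging on one bead
  ex <- data.frame(i = c(5L, 12L), j = c(10L, 20L),
                   haltedLeft = FALSE, haltedRight = FALSE)
  out <- extrusionStep(ex, nBeads = 30, seed = 2)
  # bead 11 can hold at most one leg; neither order crosses
  expect_true(out$j[1] <= out$i[2])
})

test_that("opposing anchors halt legs per the orientation convention", {
  # forward anchor blocks leftward-travelling (left) legs at p = 1
  anch <- anchorSet(bead = 8L, orientation = "forward", prob = 1)
  ex <- data.frame(i = 10L, j = 20L, haltedLeft = FALSE, haltedRight = FALSE)
  for (u in 1:5) ex <- extrusionStep(ex, anch, nBeads = 40, seed = u)
  expect_equal(ex$i, 8L)            # sits on the anchor bead
  expect_true(ex$haltedLeft)
  expect_equal(ex$j, 25L)           # free leg keeps extruding (one-sided)
  # transparent at p = 0
  anch0 <- anchorSet(bead = 8L, orientation = "forward", prob = 0)
  ex0 <- data.frame(i = 10L, j = 20L, haltedLeft = FALSE, haltedRight = FALSE)
  for (u in 1:5) ex0 <- extrusionStep(ex0, anch0, nBeads = 40, seed = u)
  expect_equal(ex0$i, 5L)
  expect_false(ex0$haltedLeft)
  # reverse anchor blocks rightward legs, leaves leftward travel alone
  anchR <- anchorSet(bead = 22L, orientation = "reverse", prob = 1)
  exR <- data.frame(i = 10L, j = 20L, haltedLeft = FALSE, haltedRight = FALSE)
  for (u in 1:5) exR <- extrusionStep(exR, anchR, nBeads = 40, seed = u)
  expect_equal(exR$j, 22L)
  expect_true(exR$haltedRight)
  expect_equal(exR$i, 5L)
})

test_that("detachment conserves the extruder count and respects kOff = 0", {
  p0 <- extrusionParams(nExtruders = 8, processivityKb = NULL)
  ex <- seedExtruders(p0, nBeads = 60, seed = 4)
  out <- detachRebind(ex, p0, nBeads = 60, nUpdates = 50, seed = 9)
  expect_identical(out$extruders, ex)          # kOff = 0: nothing happens
  expect_length(out$loopLengths, 0)
  pHot <- extrusionParams(nExtruders = 8, processivityKb = 10, g = 1000)
  out2 <- detachRebind(ex, pHot, nBeads = 60, nUpdates = 50, seed = 9)
  expect_equal(nrow(out2$extruders), 8)        # count invariant
  expect_gt(length(out2$loopLengths), 0)
})

test_that("mean extruded loop length matches the processivity relation", {
  # sparse regime: one extruder on a long polymer, no anchors; the mean
  # extruded length at detachment approaches proc = 2 g / kOff
  g <- 1000; procKb <- 40                       # 40 beads per loop
  p <- extrusionParams(nExtruders = 1, processivityKb = procKb, g = g)
  sim <- simulateExtrusion(p, nBeads = 4000, nUpdates = 30000, seed = 12)
  expect_gt(length(sim$loopLengths), 500)
  meanBeads <- mean(sim$loopLengths)
  expect_equal(meanBeads * g / 1000, procKb, tolerance = 0.1)
})

test_that("anchor sets derive from binned signal by max-normalisation", {
  expect_warning(a0 <- anchorsFromSignal(c(0, 0, 0)), "all-zero")
  expect_length(a0, 0)
  sig <- c(0, 2, 0, 8, 4)
  a <- anchorsFromSignal(sig, strand = c(".", "+", ".", "-", "."))
  expect_equal(a@bead, c(1L, 3L, 4L))
  expect_equal(a@prob, c(0.25, 1, 0.5))        # bin with max signal -> p = 1
  expect_equal(a@orientation, c("forward", "reverse", "bidirectional"))
})

test_that("rebound extruders forget their anchor engagement and halts", {
  # an anchored-halted extruder that detaches is reborn unhalted
  p <- extrusionParams(nExtruders = 2, processivityKb = 4, g = 1000)
  ex <- data.frame(i = c(10L, 30L), j = c(12L, 32L),
                   haltedLeft = c(TRUE, TRUE), haltedRight = c(TRUE, TRUE))
  out <- detachRebind(ex, p, nBeads = 60, nUpdates = 200, seed = 31)
  expect_gt(length(out$loopLengths), 0)
  expect_false(any(out$extruders$haltedLeft))
  expect_false(any(out$extruders$haltedRight))
})
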