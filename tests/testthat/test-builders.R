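test_that("compartment model arithmetic and invariants", {
  m <- buildCompartmentModel(nBeads = 900, blockSize = 75, g = 1e5)
  expect_equal(genomicContent(m), 90e6)
  expect_equal(sum(beadTypes(m) == "A"), 450)
  # blocks of 75: 7.5 Mb per block at 100 kb per bead
  expect_equal(beadTypes(m)[1:76], c(rep("A", 75), "B"))
  # a single block is the homopolymer special case
  m1 <- buildCompartmentModel(nBeads = 100, blockSize = 100)
  expect_true(all(beadTypes(m1) == "A"))
  # phase-separation condition is enforced
  expect_error(buildCompartmentModel(eAA = 3.0, eAB = 3.1),
               "micro-phase separation")
  expect_warning(buildCompartmentModel(nBeads = 1000, blockSize = 75),
                 "incomplete")
  # affinity wiring: homo on cognate beads, hetero elsewhere
  expect_equal(unname(m@affinity["A", 1]), 3.3)
  expect_equal(unname(m@affinity["A", 76]), 3.1)
  expect_equal(unname(m@affinity["B", 76]), 3.3)
})

test_that("eigenvector builder interpolates gaps and assigns ties to A", {
  mAll <- buildFromEigenvector(rep(0.5, 20))
  expect_true(all(beadTypes(mAll) == "A"))
  m <- buildFromEigenvector(c(1, NA, -1))
  # middle interpolates to 0, tie assigned to A by the declared rule
  expect_equal(beadTypes(m), c("A", "A", "B"))
  mChr <- buildFromEigenvector(rep(c(1, -1), length.out = 1353))
  expect_equal(nBeads(mChr), 1353L)
  expect_error(buildFromEigenvector(c(NA, NA)), "undefined everywhere")
})

test_that("TAD templates match their declared geometry", {
  m <- buildTadModel("plain")
  expect_equal(nBeads(m), 1000L)
  expect_equal(m@g, 5000)
  expect_equal(anchors(m)@bead, seq(0L, 999L, by = 120L))
  expect_true(all(anchors(m)@orientation == "bidirectional"))
  expect_true(all(anchors(m)@prob == 0.5))
  # consecutive anchors enclose 600 kb: the mean TAD size
  expect_equal(diff(anchors(m)@bead)[1] * m@g / 1000, 600)
  expect_warning(buildTadModel("plain", affinity = 4.0), "3.1-3.8")
  mc <- buildTadModel("with_compartments")
  expect_equal(mc@g, 1e4)
  expect_equal(sum(beadTypes(mc) == "A"), 500)
  expect_equal(rle(beadTypes(mc))$lengths, rep(250, 4))   # A-B-A-B
  expect_equal(length(anchors(mc)@bead), 20)              # 4 blocks x 5 TADs
})

test_that("locus builder sizes, tails and the infected transform", {
  p800 <- new("BindingProfile",
              counts = matrix(rep(c(1L, 0L), each = 400), 2, 800,
                              byrow = TRUE),
              binBp = 500, typeLabels = c("t1", "t2"))
  m <- buildLocusModel(p800, tails = 50)
  expect_equal(nBeads(m), 900L)                           # DDX58-sized
  p780 <- new("BindingProfile", counts = matrix(1L, 1, 780), binBp = 500,
              typeLabels = "t1")
  expect_equal(nBeads(buildLocusModel(p780, tails = 50)), 880L)  # IFIT-sized
  expect_equal(m@rInt, 2.5)
  expect_true(all(beadTypes(m)[1:50] == "inert"))
  expect_true(all(m@affinity[, 1:50] == 0))
  # anchors shift past the left tail
  anch <- anchorSet(10L, "forward", 0.9)
  m2 <- buildLocusModel(p780, anchors = anch, tails = 50)
  expect_equal(anchors(m2)@bead, 60L)
  # infected transform: halved extruders, 15-20% affinity reduction
  mock <- buildLocusModel(p780, tails = 50, separationKb = 55)
  inf <- infectedVariant(mock)
  expect_equal(inf@extrusion@nExtruders,
               as.integer(round(mock@extrusion@nExtruders / 2)))
  expect_equal(extruderSeparationKb(inf@extrusion, nBeads(inf), inf@g),
               2 * extruderSeparationKb(mock@extrusion, nBeads(mock), mock@g),
               tolerance = 0.03)
  nz <- mock@affinity > 0
  expect_equal(inf@affinity[nz] / mock@affinity[nz],
               rep(0.825, sum(nz)))
})

test_that("models round-trip exactly through their JSON files", {
  prof <- tinyProfile()
  anch <- anchorSet(c(5L, 40L), c("forward", "reverse"), c(0.9, 0.7))
  m <- buildLocusModel(prof, anchors = anch, tails = 10)
  f <- tempfile(fileext = ".json")
  writePolymerModel(m, f)
  m2 <- readPolymerModel(f)
  expect_equal(m2@beadTypes, m@beadTypes)
  expect_equal(m2@affinity, m@affinity, ignore_attr = TRUE)
  expect_equal(m2@anchors@bead, m@anchors@bead)
  expect_equal(m2@anchors@prob, m@anchors@prob)
  expect_equal(m2@extrusion@nExtruders, m@extrusion@nExtruders)
  expect_equal(m2@extrusion@kOff, m@extrusion@kOff)
  expect_equal(m2@g, m@g)
  expect_equal(genomicContent(m2), nBeads(m2) * m2@g)
})
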