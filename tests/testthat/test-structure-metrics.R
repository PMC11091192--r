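test_that("gyration tensor matches the direct double-sum identity", {
  set.seed(6)
  p <- matrix(rnorm(30), 10, 3)
  sh <- gyrationShape(p)
  # independent identity: G = 1/(2 N^2) sum_ij (xi - xj) outer (xi - xj)
  n <- nrow(p)
  G2 <- matrix(0, 3, 3)
  for (i in 1:n) for (j in 1:n) {
    d <- p[i, ] - p[j, ]
    G2 <- G2 + outer(d, d)
  }
  G2 <- G2 / (2 * n^2)
  expect_equal(sh$tensor, G2, tolerance = 1e-12)
  expect_equal(sum(diag(sh$tensor)), sh$rg^2, tolerance = 1e-12)
  # trace(G) equals the mean squared distance to the centre of mass
  cm <- colMeans(p)
  expect_equal(sh$rg^2, mean(rowSums(sweep(p, 2, cm)^2)), tolerance = 1e-12)
})

test_that("shape descriptors hit their closed-form extremes", {
  rod <- cbind(0:9, 0, 0)
  shRod <- gyrationShape(rod)
  expect_equal(shRod$anisotropy, 1)
  expect_gt(shRod$asphericity, 0)
  octa <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                c(0, 0, 1), c(0, 0, -1))
  shOct <- gyrationShape(octa)
  expect_equal(shOct$anisotropy, 0, tolerance = 1e-12)
  expect_equal(shOct$asphericity, 0, tolerance = 1e-12)
  expect_error(gyrationShape(matrix(0, 1, 3)), "at least 2")
})

test_that("shape descriptors are invariant under rigid motions", {
  set.seed(7)
  p <- matrix(rnorm(45), 15, 3)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), 0, sin(th), cos(th), 0, 0, 0, 1), 3)
  p2 <- sweep(p %*% R, 2, c(3, -2, 5), `+`)
  a <- gyrationShape(p); b <- gyrationShape(p2)
  expect_equal(a$anisotropy, b$anisotropy, tolerance = 1e-10)
  expect_equal(a$asphericity, b$asphericity, tolerance = 1e-10)
  expect_equal(a$rg, b$rg, tolerance = 1e-10)
})

test_that("hull volumes match analytic solids and an independent reference", {
  tetra <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  expect_equal(hullVolume(tetra), 1 / 6, tolerance = 1e-12)
  cube <- as.matrix(expand.grid(c(0, 2), c(0, 2), c(0, 2)))
  expect_equal(hullVolume(cube), 8, tolerance = 1e-12)
  th <- 0.4
  R <- matrix(c(cos(th), 0, sin(th), 0, 1, 0, -sin(th), 0, cos(th)), 3)
  expect_equal(hullVolume(cube %*% R), 8, tolerance = 1e-10)
  # interior points change nothing
  expect_equal(hullVolume(rbind(cube, c(1, 1, 1))), 8, tolerance = 1e-12)
  # frozen reference volume computed with an independent hull implementation
  pts <- rbind(
    c(0.0, 0.0, 0.0), c(2.0, 0.1, -0.2), c(-1.5, 1.8, 0.4),
    c(0.3, -2.1, 1.1), c(1.2, 1.3, 2.2), c(-0.7, -1.4, -1.9),
    c(2.4, -1.1, 0.6), c(-2.2, 0.5, -0.8), c(0.9, 2.4, -1.3),
    c(-1.1, -0.6, 2.0), c(1.7, 0.8, -2.1), c(-0.4, 1.1, 1.6))
  expect_equal(hullVolume(pts), 31.08016666666667, tolerance = 1e-9)
  # physical units scale with the cube of sigma
  expect_equal(hullVolume(tetra, sigmaNm = 30), 30^3 / 6, tolerance = 1e-9)
  expect_error(hullVolume(matrix(rnorm(9), 3, 3)), "at least 4")
  flat <- cbind(matrix(rnorm(20), 10, 2), 0)
  expect_error(hullVolume(flat), "coplanar")
})

test_that("length and time mappings evaluate their stated relations", {
  expect_equal(mapLengthScale(500), (500 / 6.6e9)^(1 / 3) * 7000)
  expect_equal(mapLengthScale(500), 30, tolerance = 0.02)   # ~30 nm
  expect_equal(mapLengthScale(6.6e9), 7000)
  expect_equal(mapLengthScale(1000) / mapLengthScale(500), 2^(1 / 3))
  expect_error(mapLengthScale(0), "positive")
  # tau scales as sigma^3 and linearly in eta
  expect_equal(mapTimeScale(0.2, 60) / mapTimeScale(0.2, 30), 8)
  expect_equal(mapTimeScale(0.4, 30) / mapTimeScale(0.2, 30), 2)
})

test_that("distance series and smoothing behave on hand-built inputs", {
  fr <- array(0, dim = c(3, 3, 3))
  fr[2, 1, ] <- c(3, 4, 5)          # bead 1 moves along x
  tr <- new("Trajectory", frames = fr, times = c(0, 1000, 2000),
            replicaId = 1L, boxL = 50, g = 500)
  ser <- distanceSeries(tr, 0, 1, sigmaNm = 10)
  expect_equal(ser@distanceNm, c(30, 40, 50))
  expect_warning(z <- distanceSeries(tr, 1, 1, sigmaNm = 10), "identical")
  expect_equal(z@distanceNm, c(0, 0, 0))
  expect_error(distanceSeries(tr, 0, 99), "outside the polymer")
  # smoothing: constants unchanged, linear ramps exact, variance reduced
  expect_equal(smoothSeries(rep(2, 10), 5), rep(2, 10))
  ramp <- seq(0, 9)
  expect_equal(smoothSeries(ramp, 5), ramp, tolerance = 1e-10)
  set.seed(8)
  noisy <- sin(seq(0, 4 * pi, length.out = 100)) + rnorm(100, 0, 0.5)
  expect_lt(var(diff(smoothSeries(noisy, 9))), var(diff(noisy)))
  expect_error(smoothSeries(1:3, 5), "window longer")
  expect_error(smoothSeries(1:10, 4), "odd")
})

test_that("contact times tile the series and follow the run-length oracle", {
  # pattern below-below-above-below: durations [2, 1] and gap [1] when
  # edge runs are kept; censored means exclude the edge-touching runs
  x <- c(100, 100, 200, 100)
  all <- contactTimes(x, thresholdNm = 150, dropEdgeRuns = FALSE)
  expect_equal(all$durations, c(2, 1))
  expect_equal(all$gaps, 1)
  cens <- contactTimes(x, thresholdNm = 150)
  expect_equal(length(cens$durations), 0)
  expect_equal(cens$gaps, 1)
  expect_equal(cens$edgeRuns, 2)
  # full-below series: a single duration spanning everything
  allBelow <- contactTimes(rep(10, 7), thresholdNm = 150,
                           dropEdgeRuns = FALSE)
  expect_equal(allBelow$durations, 7)
  # never below: explicit empty no-contact result
  none <- contactTimes(rep(500, 5), thresholdNm = 150, dropEdgeRuns = FALSE)
  expect_equal(length(none$durations), 0)
  expect_true(is.na(none$meanContact))
  # durations + gaps + edges exactly tile arbitrary series
  set.seed(9)
  for (rep in 1:5) {
    y <- runif(50, 0, 300)
    r <- contactTimes(y, thresholdNm = 150, dropEdgeRuns = FALSE)
    expect_equal(sum(r$durations) + sum(r$gaps), 50)
  }
})

test_that("co-occurrence fraction equals the brute-force frame scan", {
  set.seed(10)
  fr <- cloudFrames(10, 40, sd = 3, seed = 10)
  tr <- new("Trajectory", frames = fr, times = seq_len(40) * 1000,
            replicaId = 1L, boxL = 50, g = 500)
  sigmaNm <- mapLengthScale(500)
  els <- c(1L, 4L, 7L)
  got <- cooccurrenceFraction(tr, els, thresholdNm = 150, sigmaNm = sigmaNm)
  thrSigma <- 150 / sigmaNm
  brute <- mean(vapply(1:40, function(f) {
    d <- as.matrix(dist(fr[els + 1, , f]))
    all(d[upper.tri(d)] < thrSigma)
  }, logical(1)))
  expect_equal(got, brute, tolerance = 1e-12)
  # pinned-together elements give 1, far-apart give 0
  frSame <- pointFrames(5, 3)
  trSame <- new("Trajectory", frames = frSame, times = 1:3 * 1000,
                replicaId = 1L, boxL = 50, g = 500)
  expect_equal(cooccurrenceFraction(trSame, c(0L, 1L, 2L), 150), 1)
  expect_equal(cooccurrenceFraction(tr, els, thresholdNm = 1e-6), 0)
  expect_error(cooccurrenceFraction(tr, c(1L, 1L, 2L), 150), "distinct")
})
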