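test_that("simplex fit recovers an exact basis member", {
  set.seed(1)
  basis <- lapply(1:4, function(k) matrix(runif(25), 5))
  fit <- fitSimplexCombination(basis[[2]], basis)
  expect_equal(unname(coef(fit)), c(0, 1, 0, 0), tolerance = 1e-8)
  expect_lt(fit@objective, 1e-12)
})

test_that("planted mixtures are recovered within 0.05 and error vanishes with noise", {
  set.seed(2)
  B1 <- matrix(runif(100), 10); B2 <- matrix(runif(100), 10)
  for (noise in c(0.02, 0.002, 0)) {
    target <- 0.7 * B1 + 0.3 * B2 + matrix(rnorm(100, 0, noise), 10)
    fit <- fitSimplexCombination(target, list(B1 = B1, B2 = B2))
    tol <- max(5 * noise, 1e-8)
    expect_equal(coef(fit)[["B1"]], 0.7, tolerance = max(0.05, tol))
    expect_equal(coef(fit)[["B2"]], 0.3, tolerance = max(0.05, tol))
  }
  # noise -> 0 gives essentially exact recovery
  target0 <- 0.7 * B1 + 0.3 * B2
  fit0 <- fitSimplexCombination(target0, list(B1 = B1, B2 = B2))
  expect_equal(unname(coef(fit0)), c(0.7, 0.3), tolerance = 1e-8)
})

test_that("duplicated basis elements put their mass on the first duplicate", {
  set.seed(3)
  B1 <- matrix(runif(36), 6); B2 <- matrix(runif(36), 6)
  target <- 0.5 * B1 + 0.5 * B2
  fit <- fitSimplexCombination(target, list(a = B1, b = B1, c = B2))
  expect_equal(coef(fit)[["a"]], 0.5, tolerance = 1e-6)
  expect_equal(coef(fit)[["b"]], 0)
  # objective unchanged relative to the deduplicated problem
  ref <- fitSimplexCombination(target, list(B1, B2))
  expect_equal(fit@objective, ref@objective, tolerance = 1e-10)
})

test_that("the optimum beats every single-basis vertex", {
  set.seed(4)
  basis <- lapply(1:5, function(k) rnorm(40))
  target <- 0.2 * basis[[1]] + 0.5 * basis[[3]] + 0.3 * basis[[5]] +
    rnorm(40, 0, 0.05)
  fit <- fitSimplexCombination(target, basis)
  for (k in 1:5)
    expect_lte(fit@objective, sum((basis[[k]] - target)^2) + 1e-9)
})

test_that("contact-probability fitting recovers scale and planted weights", {
  s <- 0:199
  g <- 5000
  mk <- function(alpha, amp) amp * (1 + s)^-alpha
  # pure rescaling: one basis curve equal to target x 2
  target <- mk(1.1, 1)
  fit <- fitContactProbability(target, list(b = 2 * target), g = g)
  expect_equal(fit@scale, 0.5, tolerance = 1e-8)
  expect_equal(unname(coef(fit)), 1)
  expect_lt(fit@objective, 1e-12)
  # four-curve basis with planted weights (mirrors affinity x extruder
  # grids: decay differences plus TAD-scale shoulders from extrusion)
  shoulder <- exp(-((s - 60)^2) / 400)
  basis <- list(a = mk(0.9, 1), b = mk(1.4, 1),
                c = mk(1.1, 1) + 0.3 * shoulder,
                d = mk(0.6, 0.8) * exp(-s / 120))
  w <- c(0.45, 0.3, 0.15, 0.1)
  target2 <- 1.7 * (w[1] * basis$a + w[2] * basis$b + w[3] * basis$c +
                      w[4] * basis$d)
  set.seed(5)
  target2 <- target2 * exp(rnorm(200, 0, 0.005))
  fit2 <- fitContactProbability(target2, basis, g = g)
  expect_equal(unname(coef(fit2)), w, tolerance = 0.05)
  expect_equal(fit2@scale, 1.7, tolerance = 0.1)
  expect_error(fitContactProbability(target, list(b = target), g = g,
                                     fitRangeBp = c(1e9, 2e9)),
               "excludes every point")
})

test_that("saddle-target and profile-target fits agree on the best coefficient", {
  # same planted two-component mixture read out through two summaries
  smA <- synthCompartmentMap(nBins = 120, blockSize = 20, strength = 0.5,
                             noise = 0, seed = 11)
  smB <- synthCompartmentMap(nBins = 120, blockSize = 20, strength = 0.15,
                             noise = 0, seed = 11)
  w <- 0.65
  mixMap <- w * contactMatrix(smA$map) + (1 - w) * contactMatrix(smB$map)
  e1 <- smA$e1
  sadMix <- saddleMatrix(saddlePlot(mixMap, e1, nBins = 12))
  sadA <- saddleMatrix(saddlePlot(contactMatrix(smA$map), e1, nBins = 12))
  sadB <- saddleMatrix(saddlePlot(contactMatrix(smB$map), e1, nBins = 12))
  fitSad <- fitSimplexCombination(sadMix, list(A = sadA, B = sadB))
  e1Mix <- computeE1(mixMap, e1)
  e1A <- computeE1(contactMatrix(smA$map), e1)
  e1B <- computeE1(contactMatrix(smB$map), e1)
  fitE1 <- fitSimplexCombination(e1Mix, list(A = e1A, B = e1B))
  expect_lt(abs(coef(fitSad)[["A"]] - coef(fitE1)[["A"]]), 0.15)
})
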