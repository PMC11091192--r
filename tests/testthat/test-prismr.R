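test_that("the forward model composes background and co-occupancy", {
  # empty profile: pure power-law background
  P0 <- matrix(0L, 2, 30)
  m0 <- contactMatrix(predictedMap(P0, gamma = 1))
  s <- abs(outer(1:30, 1:30, `-`))
  expect_equal(m0[s > 0], (1 + s[s > 0])^-1, tolerance = 1e-12)
  expect_equal(diag(m0), rep(1, 30))
  # two orthogonal block types enrich their own blocks, not across
  P <- matrix(0L, 2, 40)
  P[1, 1:15] <- 1L; P[2, 26:40] <- 1L
  m <- contactMatrix(predictedMap(P, beta = 0.3))
  bg <- contactMatrix(predictedMap(matrix(0L, 2, 40)))
  within1 <- m[2, 14]; within2 <- m[28, 39]; across <- m[2, 39]
  expect_gt(within1, bg[2, 14])
  expect_gt(within2, bg[28, 39])
  expect_equal(across, bg[2, 39], tolerance = 1e-12)
  # symmetry for arbitrary profiles
  set.seed(11)
  Pr <- matrix(rbinom(3 * 25, 1, 0.3), 3, 25)
  mr <- contactMatrix(predictedMap(Pr))
  expect_equal(mr, t(mr))
})

test_that("the annealing cost separates fit and parsimony terms", {
  prof <- tinyProfile(n = 60)
  target <- predictedMap(prof)
  expect_equal(saCost(prof, target, lambda = 0), 0, tolerance = 1e-12)
  # the penalty is exactly linear in the site count
  lam <- 0.37
  expect_equal(saCost(prof, target, lambda = lam),
               lam * sum(profileMatrix(prof)), tolerance = 1e-10)
  # nonnegative against arbitrary targets
  set.seed(12)
  noisy <- contactMatrix(target) * exp(rnorm(3600, 0, 0.2))
  noisy <- pmin((noisy + t(noisy)) / 2, 1); diag(noisy) <- 1
  expect_gte(saCost(prof, noisy, lambda = 0.01), 0)
  # R cost agrees with the annealer's internal cost at its solution
  cfg <- new("SAConfig", nTypesRange = 2L, nTemps = 25L, movesPerBead = 8,
             lambda = 1e-3, seed = 4L)
  res <- inferBindingSites(contactMatrix(target), cfg)
  expect_equal(saCost(res$profile, contactMatrix(target), lambda = 1e-3),
               res$cost, tolerance = 1e-8)
})

test_that("annealing recovers a planted two-type profile", {
  prof <- tinyProfile(n = 120, seed = 13)
  target <- synthLocusMap(prof, noise = 0.05, seed = 14)
  cfg <- new("SAConfig", nTypesRange = 2L, nTemps = 50L, movesPerBead = 15,
             lambda = 5e-4, seed = 21L)
  res <- inferBindingSites(target, cfg)
  mt <- matchProfileTypes(res$profile, prof)
  expect_gt(min(mt$perType), 0.9)
  # determinism under the seed
  res2 <- inferBindingSites(target, cfg)
  expect_identical(profileMatrix(res2$profile), profileMatrix(res$profile))
})

test_that("an overwhelming penalty empties the profile", {
  prof <- tinyProfile(n = 50)
  target <- predictedMap(prof)
  cfg <- new("SAConfig", nTypesRange = 2L, nTemps = 25L, movesPerBead = 10,
             lambda = 1e6, seed = 2L)
  res <- suppressWarnings(inferBindingSites(target, cfg))
  expect_equal(sum(profileMatrix(res$profile)), 0)
})

test_that("the parsimony rule prefers the smallest adequate type count", {
  prof <- tinyProfile(n = 80, seed = 15)
  target <- predictedMap(prof)
  cfg <- new("SAConfig", nTypesRange = 1:3, nTemps = 40L, movesPerBead = 12,
             lambda = 2e-3, seed = 6L)
  res <- suppressWarnings(inferBindingSites(contactMatrix(target), cfg))
  expect_lte(res$nTypes, 3L)
  expect_equal(nrow(res$byTypes), 3)
  # a planted 2-type structure is not explained by 1 type as cheaply
  c1 <- res$byTypes$cost[res$byTypes$nTypes == 1]
  c2 <- res$byTypes$cost[res$byTypes$nTypes == 2]
  expect_gt(c1, c2 * 0.99)
})

test_that("recovery quality degrades gracefully with planted noise", {
  prof <- tinyProfile(n = 100, seed = 44)
  rAt <- function(noise) {
    target <- synthLocusMap(prof, noise = noise, seed = 45)
    cfg <- new("SAConfig", nTypesRange = 2L, nTemps = 40L,
               movesPerBead = 12, lambda = 5e-4, seed = 46L)
    res <- suppressWarnings(inferBindingSites(target, cfg))
    matchProfileTypes(res$profile, prof)$mean
  }
  rs <- vapply(c(0.02, 0.2, 0.6), rAt, numeric(1))
  expect_gt(rs[1], 0.9)
  # monotone improvement with signal-to-noise (small slack for MC noise)
  expect_gte(rs[1], rs[2] - 0.05)
  expect_gte(rs[2], rs[3] - 0.05)
})
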