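test_that("interval binning is length-weighted with empty bins at zero", {
  # one interval covering one bin exactly
  t1 <- binTrack(data.frame(start = 5000, end = 10000, value = 3),
                 binBp = 5000, nBins = 3)
  expect_equal(trackValues(t1), c(0, 3, 0))
  # an interval spanning two bins equally puts its value in both
  t2 <- binTrack(data.frame(start = 2500, end = 7500, value = 4),
                 binBp = 5000, nBins = 2)
  expect_equal(trackValues(t2), c(4, 4))
  # two half-bin intervals of values a and b average to (a+b)/2
  t3 <- binTrack(data.frame(start = c(0, 2500), end = c(2500, 5000),
                            value = c(2, 6)), binBp = 5000, nBins = 1)
  expect_equal(trackValues(t3), 4)
  # out-of-region intervals are clipped with a warning
  expect_warning(
    t4 <- binTrack(data.frame(start = 0, end = 99000, value = 1),
                   binBp = 5000, nBins = 2), "clipped")
  expect_equal(trackValues(t4), c(1, 1))
  expect_error(binTrack(data.frame(start = 10, end = 10, value = 1)),
               "start < end")
})

test_that("self-correlation survives thresholding and degenerate bands zero all", {
  prof <- tinyProfile(n = 200, seed = 16)
  self <- epiTrack(profileMatrix(prof)[1, ], binBp = 500, mark = "self")
  sig <- crosscorrSignificant(prof, list(self), nBoot = 300, seed = 3)
  expect_equal(sig["type1", "self"], 1, tolerance = 1e-10)
  # pct = (0, 100): the null band swallows everything
  sigAll <- crosscorrSignificant(prof, list(self), nBoot = 300,
                                 pct = c(0, 100), seed = 3)
  expect_true(all(sigAll == 0))
  # constant mark: undefined correlation reported as 0 with a warning
  flat <- epiTrack(rep(2, 200), binBp = 500, mark = "flat")
  expect_warning(sigF <- crosscorrSignificant(prof, list(flat),
                                              nBoot = 50, seed = 1),
                 "constant")
  expect_true(all(sigF[, "flat"] == 0))
})

test_that("the 15/85 band zeroes most null correlations", {
  prof <- plantedProfile(nBeads = 300, nTypes = 4, seed = 17)
  set.seed(18)
  tracks <- lapply(1:5, function(k)
    epiTrack(runif(300), binBp = 500, mark = paste0("m", k)))
  sig <- crosscorrSignificant(prof, tracks, nBoot = 1000, seed = 5)
  # nominal retention under the null is 30%; with 20 entries the zeroed
  # fraction should clearly dominate
  expect_gte(mean(sig == 0), 0.5)
})

test_that("condition-change p-values calibrate at the null and find planted flips", {
  prof <- plantedProfile(nBeads = 250, nTypes = 2, seed = 19)
  rho <- c(ctcf = 0.6, k27 = 0.5, k9 = 0.4)
  trA <- synthTracks(prof, rho, typeOf = c(1, 2, 2), condition = "mock",
                     seed = 20)
  # identical generating conditions (independent draws): p-values are
  # uniform-ish, none systematically small
  trA2 <- synthTracks(prof, rho, typeOf = c(1, 2, 2), condition = "mock",
                      seed = 120)
  res0 <- correlationChangePvalues(prof, prof, trA, trA2, nPerm = 300,
                                   seed = 21)
  expect_gt(median(res0$p), 0.3)
  # planted sign flip of one mark's association ranks first
  rhoB <- rho; rhoB["k27"] <- -0.5
  trB <- synthTracks(prof, rhoB, typeOf = c(1, 2, 2), condition = "inf",
                     seed = 20)
  res1 <- correlationChangePvalues(prof, prof, trA, trB, nPerm = 300,
                                   seed = 22)
  expect_equal(res1$mark[1], "k27")
  expect_lt(res1$p[1], 0.05)
  expect_true(res1$top[1])
  # topK = 0 flags nothing
  res2 <- correlationChangePvalues(prof, prof, trA, trB, nPerm = 50,
                                   topK = 0, seed = 23)
  expect_false(any(res2$top))
})

test_that("permutation nulls are exchangeable for the change statistic", {
  # with no real association the observed change is itself a null draw,
  # so its p-value over repeated independent data is uniform-ish
  prof <- plantedProfile(nBeads = 150, nTypes = 1, seed = 24)
  ranks <- vapply(1:30, function(r) {
    t1 <- synthTracks(prof, c(m = 0), seed = 200 + 2 * r)
    t2 <- synthTracks(prof, c(m = 0), seed = 201 + 2 * r)
    correlationChangePvalues(prof, prof, t1, t2, nPerm = 60,
                             seed = 100 + r)$p[1]
  }, numeric(1))
  expect_gt(mean(ranks), 0.3)
  expect_lt(mean(ranks), 0.75)
  expect_gt(mean(ranks > 0.2), 0.5)
})
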