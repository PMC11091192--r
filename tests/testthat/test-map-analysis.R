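test_that("contact maps match the brute-force oracle and edge cases", {
  # straight rod at A = 2: only |i-j| <= 1 are contacts (d = 2 is not < 2)
  rod <- rodFrames(8)
  cm <- contactMap(rod, A = 2, binBp = 1000)
  expected <- abs(outer(1:8, 1:8, `-`)) <= 1
  expect_equal(contactMatrix(cm), expected + 0, ignore_attr = TRUE)
  # coincident beads give the all-ones matrix
  expect_true(all(contactMatrix(contactMap(pointFrames(6), A = 1,
                                           binBp = 1)) == 1))
  # a single conformation yields binary entries
  cl <- cloudFrames(12, 1)
  expect_true(all(contactMatrix(contactMap(cl, A = 2, binBp = 1)) %in%
                    c(0, 1)))
  # brute-force equivalence on small random ensembles, exact
  fr <- cloudFrames(15, 7, seed = 4)
  for (A in c(1.5, 3)) {
    expect_equal(contactMatrix(contactMap(fr, A = A, binBp = 1)),
                 bruteContactMap(fr, A), tolerance = 1e-12)
  }
})

test_that("contact maps are entry-wise monotone in the threshold", {
  fr <- cloudFrames(20, 5, seed = 9)
  m1 <- contactMatrix(contactMap(fr, A = 2, binBp = 1))
  m2 <- contactMatrix(contactMap(fr, A = 3.5, binBp = 1))
  expect_true(all(m2 - m1 >= 0))
})

test_that("contact probability averages diagonals", {
  m3 <- matrix(c(1, .5, .2, .5, 1, .4, .2, .4, 1), 3)
  expect_equal(contactProbability(m3), c(1, 0.45, 0.2))
  expect_equal(contactProbability(matrix(0.3, 5, 5)), rep(0.3, 5))
  ps <- contactProbability(contactMap(cloudFrames(10, 3), A = 2, binBp = 1))
  expect_equal(ps[1], 1)
  # the global scale multiplies every point
  expect_equal(contactProbability(m3, scale = 2), 2 * c(1, 0.45, 0.2))
})

test_that("consecutive sub-matrix averaging", {
  m <- contactMap(cloudFrames(12, 4), A = 2.5, binBp = 1)
  expect_equal(contactMatrix(averageSubmatrices(m, 1)), contactMatrix(m))
  # k = 2 on a hand 4x4: mean of the two diagonal blocks
  h <- matrix(c(1, .2, .3, .4,
                .2, 1, .5, .6,
                .3, .5, 1, .8,
                .4, .6, .8, 1), 4, byrow = TRUE)
  got <- contactMatrix(averageSubmatrices(h, 2))
  expect_equal(got, (h[1:2, 1:2] + h[3:4, 3:4]) / 2)
  # three identical blocks average to one block
  b <- contactMatrix(contactMap(cloudFrames(4, 2), A = 2, binBp = 1))
  big <- matrix(0, 12, 12)
  for (q in 0:2) big[q * 4 + 1:4, q * 4 + 1:4] <- b
  expect_equal(contactMatrix(averageSubmatrices(big, 3)), b)
  expect_error(averageSubmatrices(h, 0), "k must be")
})

test_that("log2 fold change handles equality, doubling and zeros", {
  a <- matrix(c(1, .4, .4, 1), 2)
  expect_equal(log2FoldChange(a, a), matrix(0, 2, 2))
  expect_equal(log2FoldChange(2 * a, a, pseudocount = 0),
               matrix(1, 2, 2))
  z <- matrix(c(1, 0, 0, 1), 2)
  lfc <- log2FoldChange(z, a, pseudocount = 1e-6)
  expect_true(all(is.finite(lfc)))
  expect_error(log2FoldChange(a, matrix(1, 3, 3)), "same shape")
})

test_that("triplet matrices match the brute-force triple-loop oracle", {
  expect_true(all(contactMatrix(tripletMatrix(pointFrames(5), 0,
                                              threshold = 1)) == 1))
  rod <- rodFrames(12)
  tm <- tripletMatrix(rod, 0, threshold = 5)
  m <- contactMatrix(tm)
  # nonzero only within the first 5 beads (distances < 5 from bead 0)
  expect_true(all(m[6:12, ] == 0) && all(m[, 6:12] == 0))
  expect_equal(m, t(m))
  fr <- cloudFrames(14, 6, seed = 21)
  got <- contactMatrix(tripletMatrix(fr, 3, threshold = 3))
  expect_equal(got, bruteTriplet(fr, 3, 3), tolerance = 1e-12)
  # triplet frequency cannot exceed any of the pairwise frequencies
  cm <- contactMatrix(contactMap(fr, A = 3, binBp = 1))
  for (j in 1:14) for (k in 1:14)
    expect_lte(got[j, k], min(cm[4, j], cm[4, k], cm[j, k]) + 1e-12)
  expect_error(tripletMatrix(fr, 99), "viewpoint")
})

test_that("triplet significance behaves at the null and detects planted signal", {
  fr <- cloudFrames(40, 120, sd = 4, seed = 8)
  # offset-zero control is the target itself: p near 0.5
  ts <- tripletSignificance(fr, c(2, 6, 10), controlOffsetBp = 0, g = 1000,
                            threshold = 4)
  expect_equal(ts$p.value, 0.5, tolerance = 0.05)
  # planted colocalisation of the target triple across conformations
  fr2 <- cloudFrames(40, 250, sd = 4, seed = 9)
  fr2[7, , ] <- fr2[3, , ] + 0.3
  fr2[11, , ] <- fr2[3, , ] - 0.3
  ts2 <- tripletSignificance(fr2, c(2, 6, 10), controlOffsetBp = 2e4,
                             g = 1000, threshold = 4)
  expect_lt(ts2$p.value, 0.01)
  expect_gt(ts2$targetFrequency, ts2$controlFrequency)
  expect_error(tripletSignificance(fr, c(2, 6, 10), controlOffsetBp = 1e9,
                                   g = 1000), "outside the polymer")
})
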