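## Compartment eigenvector, saddle plots, compartment strength.

#' Observed/expected transform of a contact map
#'
#' Divides every diagonal by its mean.  Diagonals with fewer than
#' `minDiagEntries` cells are excluded from the expected-value estimation
#' and take the nearest estimated expected value instead (short-map
#' smoothing rule).
#'
#' @param map a [ContactMap-class] or square matrix.
#' @param minDiagEntries minimum cells per diagonal for its own expected.
#' @return matrix of observed/expected ratios.
#' @export
observedExpected <- function(map, minDiagEntries = 10) {
  m <- if (is(map, "ContactMap")) map@map else map
  n <- nrow(m)
  expected <- rep(NA_real_, n)
  for (s in 0:(n - 1)) {
    idx <- cbind(seq_len(n - s), seq_len(n - s) + s)
    if (nrow(idx) >= minDiagEntries) expected[s + 1] <- mean(m[idx])
  }
  if (all(is.na(expected))) stop("map too small for an expected model")
  known <- which(!is.na(expected))
  if (length(known) < n)
    expected <- stats::approx(known, expected[known], xout = seq_len(n),
                              rule = 2)$y
  oe <- matrix(0, n, n)
  for (s in 0:(n - 1)) {
    idx <- cbind(seq_len(n - s), seq_len(n - s) + s)
    e <- expected[s + 1]
    v <- if (e > 0) m[idx] / e else 0
    oe[idx] <- v
    oe[idx[, c(2, 1), drop = FALSE]] <- v
  }
  oe
}

#' First compartment eigenvector (E1)
#'
#' The leading eigenvector of the Pearson-correlation matrix of the
#' observed/expected map, the standard principal-component readout of A/B
#' compartments.  The sign is flipped so that E1 correlates nonnegatively
#' with `orientationTrack` (any per-bin proxy that is higher in A, such as
#' GC content or gene density).
#'
#' @param map a [ContactMap-class] or square matrix (at least 3 x 3).
#' @param orientationTrack per-bin values fixing the sign convention.
#' @return numeric E1, one value per bin.
#' @export
computeE1 <- function(map, orientationTrack) {
  m <- if (is(map, "ContactMap")) map@map else map
  n <- nrow(m)
  if (n < 3) stop("map too small for observed/expected + PCA")
  if (length(orientationTrack) != n)
    stop("orientation track length must match the map")
  oe <- observedExpected(m)
  if (stats::sd(oe) == 0) stop("degenerate (constant) map: no spectrum")
  cc <- suppressWarnings(stats::cor(oe))
  cc[!is.finite(cc)] <- 0
  eg <- eigen(cc, symmetric = TRUE)
  e1 <- eg$vectors[, 1]
  s <- suppressWarnings(stats::cor(e1, orientationTrack))
  if (!is.na(s) && s < 0) e1 <- -e1
  e1
}

#' Saddle plot of a map over its compartment eigenvector
#'
#' Ranks bins by E1, groups them into `nBins` equal-occupancy (quantile)
#' bins, ascending (strongest B first, strongest A last), and averages the
#' observed/expected contact between every pair of groups.
#'
#' @param map a [ContactMap-class] or square matrix.
#' @param e1 per-bin compartment eigenvector.
#' @param nBins number of saddle bins (default 50).
#' @return a [SaddlePlot-class]
#' @export
saddlePlot <- function(map, e1, nBins = 50) {
  m <- if (is(map, "ContactMap")) map@map else map
  n <- nrow(m)
  if (length(e1) != n) stop("e1 length must match the map")
  if (nBins > n) stop("more saddle bins than map bins")
  oe <- observedExpected(m)
  ord <- order(e1)
  grp <- ceiling(seq_along(ord) / (n / nBins))
  grp <- pmin(grp, nBins)
  groupOf <- integer(n)
  groupOf[ord] <- grp
  gi <- factor(groupOf[row(oe)], levels = seq_len(nBins))
  gj <- factor(groupOf[col(oe)], levels = seq_len(nBins))
  sums <- tapply(as.vector(oe), list(gi, gj), sum)
  cnts <- tapply(rep(1, length(oe)), list(gi, gj), sum)
  sad <- unname(sums / cnts)
  new("SaddlePlot", saddle = sad, nBins = as.integer(nBins),
      e1 = as.numeric(e1))
}

#' Compartment strength from a saddle plot
#'
#' `(mean AA corner + mean BB corner) / (2 * mean AB corner)` over the top
#' and bottom `cornerFraction` of the ranked-E1 bins; equals 1 for a flat
#' saddle and grows with compartmentalisation.
#'
#' @param saddle a [SaddlePlot-class]
#' @param cornerFraction fraction of bins per corner (default 0.2).
#' @return list with `strength`, `AA`, `BB`, `AB` corner means.
#' @export
compartmentStrength <- function(saddle, cornerFraction = 0.2) {
  s <- saddle@saddle
  b <- nrow(s)
  k <- max(1L, as.integer(floor(b * cornerFraction)))
  bb <- mean(s[1:k, 1:k])                      # most-negative-E1 corner
  aa <- mean(s[(b - k + 1):b, (b - k + 1):b])  # most-positive-E1 corner
  ab <- mean(c(s[1:k, (b - k + 1):b], s[(b - k + 1):b, 1:k]))
  if (ab == 0) stop("AB corner mean is zero: strength undefined")
  list(strength = (aa + bb) / (2 * ab), AA = aa, BB = bb, AB = ab)
}
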