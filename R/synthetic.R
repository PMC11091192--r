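## Synthetic-data generators with planted structure.  Every generator is
## deterministic under its seed and emits objects in the same containers
## the analysis layer consumes, so the whole pipeline is testable without
## external data.

lognormNoise <- function(n, level) {
  if (level <= 0) return(rep(1, n))
  exp(stats::rnorm(n, -level^2 / 2, level))
}

symmetrizeCap <- function(m) {
  m[lower.tri(m)] <- t(m)[lower.tri(m)]
  m <- pmin(pmax(m, 0), 1)
  diag(m) <- 1
  m
}

#' Synthetic checkerboard compartment map
#'
#' A power-law distance-decay background modulated by a planted A/B
#' checkerboard: `M[i,j] = (1+|i-j|)^-decay * (1 + w_i w_j)` with
#' `w_i = sqrt(strength) * (+aWeakening for A, -1 for B)`, multiplicative
#' log-normal noise on every cell, symmetrised and capped to `[0, 1]`.
#' `aWeakening < 1` weakens A-A contacts relative to B-B (the infected
#' re-structuring signature), making the BB saddle corner exceed AA.
#'
#' @param nBins map size.
#' @param blockSize beads per compartment block.
#' @param strength checkerboard modulation strength (0 disables; default
#'   0.3).
#' @param decay distance-decay exponent (default 1, crumpled-globule-like).
#' @param noise log-normal noise level (sd of log; default 0.1).
#' @param aWeakening multiplier on the A amplitude (default 1, balanced).
#' @param seed RNG seed.
#' @return list with `map` (a [ContactMap-class]), `labels` (planted
#'   A/B per bin) and `e1` (planted signed indicator, +1 for A).
#' @export
synthCompartmentMap <- function(nBins = 400, blockSize = 50, strength = 0.3,
                                decay = 1, noise = 0.1, aWeakening = 1,
                                seed = 1L) {
  stopifnot(strength >= 0, nBins >= 2)
  blockOf <- ((seq_len(nBins) - 1) %/% blockSize) %% 2
  labels <- ifelse(blockOf == 0, "A", "B")
  w <- sqrt(strength) * ifelse(labels == "A", aWeakening, -1)
  s <- abs(outer(seq_len(nBins), seq_len(nBins), `-`))
  m <- (1 + s)^(-decay) * (1 + outer(w, w))
  withSeed(seed, {
    m <- m * matrix(lognormNoise(nBins * nBins, noise), nBins)
  })
  m <- symmetrizeCap(m)
  list(map = new("ContactMap", map = m, binBp = 1e5, threshold = NA_real_,
                 nConformations = 0L),
       labels = labels, e1 = ifelse(labels == "A", 1, -1))
}

#' Synthetic locus map from a planted binding profile
#'
#' Composites the mean-field forward model of a binding profile (see
#' [predictedMap()]) with corner peaks at consecutive anchor pairs
#' (Gaussian bumps of width `peakWidth` bins, amplitude `loopStrength`
#' scaled by the two engagement probabilities) and multiplicative
#' log-normal noise.
#'
#' @param profile a [BindingProfile-class]
#' @param anchors an [AnchorSet-class] on the profile grid.
#' @param beta,gamma forward-model constants.
#' @param loopStrength corner-peak amplitude (default 0.3).
#' @param peakWidth Gaussian peak width in bins (default 2).
#' @param noise log-normal noise level (default 0.1).
#' @param seed RNG seed.
#' @return a [ContactMap-class]
#' @export
synthLocusMap <- function(profile, anchors = anchorSet(), beta = 0.3,
                          gamma = 1, loopStrength = 0.3, peakWidth = 2,
                          noise = 0.1, seed = 1L) {
  n <- ncol(profile@counts)
  if (length(anchors@bead) && max(anchors@bead) >= n)
    stop("anchors fall outside the profile grid")
  m <- predictedMap(profile, beta = beta, gamma = gamma)@map
  ab <- anchors@bead
  if (length(ab) >= 2) {
    ord <- order(ab)
    ab <- ab[ord]; ap <- anchors@prob[ord]
    ii <- matrix(rep(seq_len(n), n), n)
    for (q in seq_len(length(ab) - 1)) {
      a <- ab[q] + 1; b <- ab[q + 1] + 1
      amp <- loopStrength * ap[q] * ap[q + 1]
      bump <- amp * exp(-((ii - a)^2 + (t(ii) - b)^2) / (2 * peakWidth^2))
      m <- m + bump + t(bump)
    }
  }
  withSeed(seed, {
    m <- m * matrix(lognormNoise(n * n, noise), n)
  })
  new("ContactMap", map = symmetrizeCap(m), binBp = profile@binBp,
      threshold = NA_real_, nConformations = 0L)
}

#' Synthetic epigenetic tracks with planted correlations
#'
#' Each track is built as `rho * z(profile row) + sqrt(1 - rho^2) * z`
#' (standardised row plus independent standard-normal noise), shifted to
#' be nonnegative, so its Pearson correlation with the chosen binding-site
#' type is `rho` up to sampling error (within about 0.1 for 200+ bins).
#'
#' @param profile a [BindingProfile-class]
#' @param rho named vector of planted correlations in `[-1, 1]`, one per
#'   mark.
#' @param typeOf profile row index used per mark (recycled; default 1).
#' @param condition condition label for the tracks.
#' @param seed RNG seed.
#' @return list of [EpiTrack-class], one per entry of `rho`.
#' @export
synthTracks <- function(profile, rho, typeOf = 1L, condition = "",
                        seed = 1L) {
  if (any(abs(rho) > 1)) stop("rho must lie in [-1, 1]")
  P <- profile@counts
  n <- ncol(P)
  typeOf <- rep_len(as.integer(typeOf), length(rho))
  marks <- names(rho)
  if (is.null(marks)) marks <- paste0("mark", seq_along(rho))
  withSeed(seed, {
    tracks <- lapply(seq_along(rho), function(k) {
      row <- P[typeOf[k], ]
      z <- if (stats::sd(row) > 0) (row - mean(row)) / stats::sd(row) else
        rep(0, n)
      raw <- rho[k] * z + sqrt(1 - rho[k]^2) * stats::rnorm(n)
      epiTrack(raw - min(raw), binBp = profile@binBp, mark = marks[k],
               condition = condition)
    })
  })
  names(tracks) <- marks
  tracks
}

#' Planted block binding profile
#'
#' A convenience generator: `nTypes` types laid out as contiguous blocks
#' of sites separated by empty spacers, the planted truth for inference
#' and correlation tests.
#'
#' @param nBeads profile length.
#' @param nTypes number of types.
#' @param siteFraction fraction of each type block occupied by sites.
#' @param binBp bin size annotation.
#' @param seed RNG seed.
#' @return a [BindingProfile-class]
#' @export
plantedProfile <- function(nBeads = 400, nTypes = 2, siteFraction = 0.8,
                           binBp = 500, seed = 1L) {
  P <- matrix(0L, nTypes, nBeads)
  span <- nBeads %/% nTypes
  withSeed(seed, {
    for (t in seq_len(nTypes)) {
      lo <- (t - 1) * span + 1
      hi <- min(t * span, nBeads)
      block <- lo:hi
      on <- sample(block, round(siteFraction * length(block)))
      P[t, on] <- 1L
    }
  })
  new("BindingProfile", counts = P, binBp = binBp,
      typeLabels = paste0("type", seq_len(nTypes)))
}
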