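## Epigenetic tracks: binning, binding-site cross-correlation with
## permutation significance, and condition-change p-values.

#' Construct an epigenetic track
#' @param values nonnegative per-bin signal.
#' @param binBp bin size, bp (5 kb is the working resolution).
#' @param mark mark name.
#' @param condition condition label.
#' @export
epiTrack <- function(values, binBp = 5000, mark = "mark",
                     condition = "") {
  t <- new("EpiTrack", values = as.numeric(values), binBp = binBp,
           mark = mark, condition = condition)
  validObject(t)
  t
}

#' Bin a signal track to a fixed resolution
#'
#' Converts interval signal (bedGraph-like: 0-based half-open `start`,
#' `end`, `value`) into per-bin means, length-weighted over the covered
#' part of each bin; uncovered bins are 0.  Intervals must be sorted and
#' non-overlapping (overlaps are merged by value-averaging over the
#' overlap, with a warning); intervals extending past the binned region
#' are clipped with a warning.
#'
#' @param intervals data.frame with columns `start`, `end`, `value` (bp).
#' @param binBp bin size, bp.
#' @param nBins number of bins (default: cover the last interval).
#' @param mark,condition annotations for the result.
#' @return an [EpiTrack-class]
#' @export
binTrack <- function(intervals, binBp = 5000, nBins = NULL, mark = "mark",
                     condition = "") {
  st <- as.numeric(intervals$start); en <- as.numeric(intervals$end)
  va <- as.numeric(intervals$value)
  if (any(en <= st)) stop("intervals must satisfy start < end")
  o <- order(st)
  st <- st[o]; en <- en[o]; va <- va[o]
  if (any(st[-1] < en[-length(en)]))
    warning("overlapping intervals: overlap contributes from both")
  if (is.null(nBins)) nBins <- ceiling(max(en) / binBp)
  span <- nBins * binBp
  if (any(en > span) || any(st < 0)) {
    warning("intervals outside the binned region were clipped")
    en <- pmin(en, span); st <- pmax(st, 0)
    keep <- en > st
    st <- st[keep]; en <- en[keep]; va <- va[keep]
  }
  num <- numeric(nBins); den <- numeric(nBins)
  for (q in seq_along(st)) {
    b0 <- floor(st[q] / binBp); b1 <- ceiling(en[q] / binBp) - 1
    for (b in b0:b1) {
      ov <- min(en[q], (b + 1) * binBp) - max(st[q], b * binBp)
      if (ov > 0) {
        num[b + 1] <- num[b + 1] + ov * va[q]
        den[b + 1] <- den[b + 1] + ov
      }
    }
  }
  vals <- ifelse(den > 0, num / pmax(den, 1e-300), 0)
  epiTrack(vals, binBp = binBp, mark = mark, condition = condition)
}

# per-type positional permutation of a profile (site counts preserved)
permuteProfileRows <- function(P) {
  t(apply(P, 1, sample))
}

#' Significant binding-site / mark correlations
#'
#' Pearson correlation between every binding-site type (row of the
#' profile) and every epigenetic mark, thresholded against a positional
#' null: site placements are randomly permuted along the locus per type
#' `nBoot` times (site counts preserved) and correlations outside the
#' null's central band — below its `pct[1]`-th or above its `pct[2]`-th
#' percentile — keep their value, others are set to 0.  Undefined
#' correlations (constant track or empty type) give 0 with a warning.
#'
#' @param profile a [BindingProfile-class]
#' @param tracks list of [EpiTrack-class] objects on the profile's grid.
#' @param nBoot number of positional permutations (default 10000).
#' @param pct lower/upper percentile thresholds (default `c(15, 85)`).
#' @param seed RNG seed.
#' @return `nTypes x nMarks` matrix: significant correlations, 0 elsewhere.
#' @export
crosscorrSignificant <- function(profile, tracks, nBoot = 10000,
                                 pct = c(15, 85), seed = 1L) {
  P <- profile@counts
  V <- vapply(tracks, trackValues, numeric(ncol(P)))
  marks <- vapply(tracks, function(t) t@mark, character(1))
  nt <- nrow(P); nm <- ncol(V)
  out <- matrix(0, nt, nm, dimnames = list(profile@typeLabels, marks))
  withSeed(seed, {
    for (t in seq_len(nt)) {
      row <- P[t, ]
      if (stats::sd(row) == 0) {
        warning("type ", profile@typeLabels[t],
                " has constant site counts: correlations undefined, set 0")
        next
      }
      nullRows <- replicate(nBoot, sample(row))
      for (k in seq_len(nm)) {
        v <- V[, k]
        if (stats::sd(v) == 0) {
          warning("mark ", marks[k], " is constant: correlation set to 0")
          next
        }
        r <- stats::cor(row, v)
        # the observed value joins its own null (exchangeability), so a
        # degenerate (0, 100) band can never call anything significant
        nullR <- c(as.numeric(stats::cor(nullRows, v)), r)
        qs <- stats::quantile(nullR, pct / 100, names = FALSE, type = 7)
        if (r < qs[1] || r > qs[2]) out[t, k] <- r
      }
    }
  })
  out
}

#' Ranked correlation changes between conditions
#'
#' For every (type, mark) pair, the absolute change in binding-site/mark
#' correlation between two conditions is compared against a null of
#' per-type positional permutations of the binding sites in both
#' conditions (one-sided: observed change at least as large).  The
#' `topK` lowest p-values are flagged; ties are broken by larger absolute
#' change.
#'
#' @param profileA,profileB [BindingProfile-class] per condition (same
#'   grid and type count).
#' @param tracksA,tracksB lists of [EpiTrack-class] per condition, same
#'   marks in the same order.
#' @param nPerm number of permutations (default 1000).
#' @param topK number of changes to flag (default 4).
#' @param seed RNG seed.
#' @return data.frame (type, mark, rA, rB, deltaAbs, p, top) sorted by p.
#' @export
correlationChangePvalues <- function(profileA, profileB, tracksA, tracksB,
                                     nPerm = 1000, topK = 4, seed = 1L) {
  PA <- profileA@counts; PB <- profileB@counts
  if (!all(dim(PA) == dim(PB))) stop("profiles must share shape")
  if (profileA@binBp != profileB@binBp) stop("profiles must share bin size")
  n <- ncol(PA)
  VA <- vapply(tracksA, trackValues, numeric(n))
  VB <- vapply(tracksB, trackValues, numeric(n))
  marks <- unname(vapply(tracksA, function(t) t@mark, character(1)))
  marksB <- unname(vapply(tracksB, function(t) t@mark, character(1)))
  if (!identical(marks, marksB)) stop("conditions must carry the same marks")
  nt <- nrow(PA); nm <- length(marks)
  safeCor <- function(a, b) {
    r <- suppressWarnings(stats::cor(a, b))
    if (is.finite(r)) r else 0
  }
  res <- expand.grid(type = unname(profileA@typeLabels),
                     mark = unname(marks), stringsAsFactors = FALSE)
  res$rA <- NA_real_; res$rB <- NA_real_; res$deltaAbs <- NA_real_
  res$p <- NA_real_
  withSeed(seed, {
    for (t in seq_len(nt)) {
      nullDelta <- matrix(NA_real_, nPerm, nm)
      for (b in seq_len(nPerm)) {
        pa <- sample(PA[t, ]); pb <- sample(PB[t, ])
        for (k in seq_len(nm))
          nullDelta[b, k] <- abs(safeCor(pa, VA[, k]) - safeCor(pb, VB[, k]))
      }
      for (k in seq_len(nm)) {
        i <- which(res$type == profileA@typeLabels[t] & res$mark == marks[k])
        rA <- safeCor(PA[t, ], VA[, k]); rB <- safeCor(PB[t, ], VB[, k])
        dl <- abs(rA - rB)
        res$rA[i] <- rA; res$rB[i] <- rB; res$deltaAbs[i] <- dl
        res$p[i] <- (1 + sum(nullDelta[, k] >= dl)) / (nPerm + 1)
      }
    }
  })
  res <- res[order(res$p, -res$deltaAbs), ]
  res$top <- seq_len(nrow(res)) <= topK
  rownames(res) <- NULL
  res
}
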