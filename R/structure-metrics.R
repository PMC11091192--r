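## Shape descriptors, volumes, physical-unit mapping, distance dynamics.

#' Gyration tensor and shape descriptors
#'
#' Computes the gyration tensor `G[a,b] = 1/N sum_i (x[i,a] - xCM[a]) *
#' (x[i,b] - xCM[b])` of a conformation, its ascending-ordered eigenvalues
#' and two standard shape descriptors: anisotropy
#' `1 - 3 (l1 l2 + l2 l3 + l3 l1) / (l1 + l2 + l3)^2` (0 for a sphere, 1
#' for a rod) and asphericity `l3 - (l1 + l2) / 2`, taken against the
#' largest eigenvalue so that a sphere gives 0 and a rod a positive value.
#' `trace(G)` equals the squared radius of gyration.
#'
#' @param x a [Conformation-class], [Trajectory-class] frame or `n x 3`
#'   matrix of unwrapped coordinates (>= 2 beads).
#' @return list with `tensor`, `eigenvalues` (ascending), `anisotropy`,
#'   `asphericity`, `rg` (radius of gyration).
#' @export
gyrationShape <- function(x) {
  p <- if (is(x, "Conformation")) x@beadPos else as.matrix(x)
  if (nrow(p) < 2) stop("shape descriptors need at least 2 beads")
  cm <- colMeans(p)
  d <- sweep(p, 2, cm)
  G <- crossprod(d) / nrow(p)
  ev <- sort(eigen(G, symmetric = TRUE, only.values = TRUE)$values)
  ev <- pmax(ev, 0)
  tr <- sum(ev)
  if (tr == 0) stop("degenerate conformation: zero gyration tensor")
  ani <- 1 - 3 * (ev[1] * ev[2] + ev[2] * ev[3] + ev[3] * ev[1]) / tr^2
  asp <- ev[3] - (ev[1] + ev[2]) / 2
  list(tensor = G, eigenvalues = ev, anisotropy = ani, asphericity = asp,
       rg = sqrt(tr))
}

#' Convex-hull volume of a conformation
#'
#' Numerically computes the convex hull of the 3D bead coordinates
#' (incremental insertion) and returns its volume, in sigma^3 or, when
#' `sigmaNm` is given, in nm^3.  Degenerate inputs (fewer than 4 points,
#' collinear or coplanar clouds) raise an error naming the degeneracy.
#'
#' @param x conformation or `n x 3` matrix.
#' @param sigmaNm physical bead diameter in nm (1 keeps sigma^3 units).
#' @return hull volume.
#' @export
hullVolume <- function(x, sigmaNm = 1) {
  p <- if (is(x, "Conformation")) x@beadPos else as.matrix(x)
  .cpp_hull_volume(p) * sigmaNm^3
}

#' Physical length of one bead diameter
#'
#' `sigma = (g / G)^(1/3) * D`: the bead diameter follows from requiring
#' that the fraction of nuclear volume occupied per bead matches its
#' fraction `g / G` of the nuclear genomic content `G` inside a nucleus of
#' diameter `D`.  With the defaults (G = 6.6 Gbp, D = 7 um) a 500 bp bead
#' maps to about 30 nm.
#'
#' @param g genomic content per bead, bp.
#' @param G_bp nuclear genomic content, bp.
#' @param D_nm nuclear diameter, nm.
#' @return sigma in nm.
#' @examples
#' mapLengthScale(500)  # ~30 nm
#' @export
mapLengthScale <- function(g, G_bp = 6.6e9, D_nm = 7000) {
  if (any(g <= 0)) stop("g must be positive")
  if (any(g > G_bp)) stop("g cannot exceed the nuclear genomic content")
  (g / G_bp)^(1 / 3) * D_nm
}

#' Physical duration of one MD time unit
#'
#' Evaluates `tau = eta * 6 * pi * sigma^3 / epsilon` with
#' `epsilon = kB * T`, the Brownian time of a sphere of diameter `sigma`
#' in a medium of viscosity `eta`.  The relation is evaluated exactly as
#' stated; see the package vignette for the known ambiguity in the
#' constant factor when comparing with coarse literature estimates.  Used
#' only to label time axes.
#'
#' @param eta viscosity in centipoise (default 0.2 cP).
#' @param sigmaNm bead diameter in nm.
#' @param T_K absolute temperature (default 300 K).
#' @return tau in milliseconds.
#' @export
mapTimeScale <- function(eta = 0.2, sigmaNm = 30, T_K = 300) {
  if (eta <= 0 || sigmaNm <= 0) stop("eta and sigmaNm must be positive")
  kB <- 1.380649e-23                       # J/K
  etaSI <- eta * 1e-3                      # cP -> Pa s
  sigmaM <- sigmaNm * 1e-9
  tauS <- etaSI * 6 * pi * sigmaM^3 / (kB * T_K)
  tauS * 1e3                               # ms
}

#' Distance time series between two beads
#'
#' Per-frame Euclidean 3D distance between `beadI` and `beadJ` in nm, with
#' the frame spacing in MD steps and (through the time mapping) in ms.
#' Identical indices give an all-zero series with a warning.
#'
#' @param trajectory a [Trajectory-class]
#' @param beadI,beadJ 0-based bead indices.
#' @param sigmaNm physical bead diameter, nm.
#' @param tauMs physical duration of one MD time unit, ms (for frame
#'   spacing in ms; `NA` to skip).
#' @return a [ContactTimeSeries-class]
#' @export
distanceSeries <- function(trajectory, beadI, beadJ,
                           sigmaNm = mapLengthScale(trajectory@g),
                           tauMs = NA_real_) {
  fr <- trajectory@frames
  n <- dim(fr)[1]
  if (beadI < 0 || beadI >= n || beadJ < 0 || beadJ >= n)
    stop("bead indices outside the polymer (0-based)")
  if (beadI == beadJ) warning("identical beads: all-zero distance series")
  d <- sqrt(colSums((fr[beadI + 1, , ] - fr[beadJ + 1, , ])^2))
  if (dim(fr)[3] == 1) d <- sqrt(sum((fr[beadI + 1, , 1] - fr[beadJ + 1, , 1])^2))
  spacing <- if (length(trajectory@times) > 1) diff(trajectory@times)[1] else
    NA_real_
  new("ContactTimeSeries", distanceNm = as.numeric(d) * sigmaNm,
      spacingSteps = spacing,
      spacingMs = if (is.na(tauMs)) NA_real_ else spacing * 0.01 * tauMs,
      beads = as.integer(c(beadI, beadJ)), sigmaNm = sigmaNm)
}

#' Moving least-squares smoothing of a series
#'
#' Local first-order polynomial smoothing over an odd window: at each
#' point a degree-`order` polynomial is fitted to the window by least
#' squares and evaluated at the centre.  Near the edges the window
#' shrinks symmetrically (documented endpoint rule), so constant series
#' are returned unchanged and linear ramps are reproduced exactly.
#'
#' @param series numeric vector or [ContactTimeSeries-class]
#' @param window odd window length >= 3.
#' @param order polynomial order (< window; default 1).
#' @return smoothed object of the input's kind.
#' @export
smoothSeries <- function(series, window = 5, order = 1) {
  x <- if (is(series, "ContactTimeSeries")) series@distanceNm else
    as.numeric(series)
  n <- length(x)
  if (window > n) stop("window longer than the series")
  if (window %% 2 != 1 || window < 3) stop("window must be odd and >= 3")
  if (order >= window) stop("order must be below the window length")
  half <- (window - 1) / 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    h <- min(half, i - 1, n - i)            # shrink symmetrically at edges
    idx <- (i - h):(i + h)
    if (length(idx) <= order) { out[i] <- x[i]; next }
    t <- idx - i
    fit <- stats::lm.fit(outer(t, 0:order, `^`), x[idx])
    out[i] <- fit$coefficients[1]
  }
  if (is(series, "ContactTimeSeries")) {
    series@distanceNm <- out
    series
  } else out
}

#' Contact durations and inter-contact gaps
#'
#' Splits a distance series at the contact threshold (default 150 nm) into
#' maximal below-threshold runs (contact durations tau) and above-threshold
#' runs (gaps).  Runs touching the series edges are right/left-censored;
#' they are flagged and excluded from the means by default.  Durations are
#' reported in frames and, when known, in ms.
#'
#' @param series a [ContactTimeSeries-class] or numeric vector (nm).
#' @param thresholdNm contact threshold, nm.
#' @param dropEdgeRuns censor runs touching the series edges (default).
#' @return list with `durations`, `gaps` (frames), `meanContact`,
#'   `meanGap` (frames; `NA` when empty), `edgeRuns` count, and ms
#'   equivalents when the frame spacing in ms is known.
#' @export
contactTimes <- function(series, thresholdNm = 150, dropEdgeRuns = TRUE) {
  x <- if (is(series, "ContactTimeSeries")) series@distanceNm else
    as.numeric(series)
  if (!length(x)) stop("empty series")
  below <- x < thresholdNm
  r <- rle(below)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  isEdge <- starts == 1 | ends == length(x)
  keep <- if (dropEdgeRuns) !isEdge else rep(TRUE, length(r$lengths))
  durations <- r$lengths[r$values & keep]
  gaps <- r$lengths[!r$values & keep]
  spacingMs <- if (is(series, "ContactTimeSeries")) series@spacingMs else
    NA_real_
  list(durations = durations, gaps = gaps,
       meanContact = if (length(durations)) mean(durations) else NA_real_,
       meanGap = if (length(gaps)) mean(gaps) else NA_real_,
       edgeRuns = sum(isEdge),
       durationsMs = if (!is.na(spacingMs)) durations * spacingMs else NULL,
       meanContactMs = if (!is.na(spacingMs) && length(durations))
         mean(durations) * spacingMs else NA_real_)
}

#' Fraction of frames with full co-localisation
#'
#' The fraction of trajectory frames in which all pairwise distances among
#' the given beads (a regulatory hub of three or more elements) fall below
#' the threshold.
#'
#' @param trajectory a [Trajectory-class]
#' @param elements distinct 0-based bead indices (>= 2).
#' @param thresholdNm distance threshold in nm.
#' @param sigmaNm physical bead diameter, nm.
#' @return fraction of frames in `[0, 1]`.
#' @export
cooccurrenceFraction <- function(trajectory, elements, thresholdNm = 150,
                                 sigmaNm = mapLengthScale(trajectory@g)) {
  elements <- as.integer(elements)
  if (length(elements) < 2) stop("at least 2 elements are required")
  if (anyDuplicated(elements)) stop("elements must be distinct")
  ind <- .cpp_all_close_indicator(trajectory@frames, elements,
                                  thresholdNm / sigmaNm)
  mean(ind)
}

#' Per-trajectory summary metrics table
#'
#' One row per replica: mean and standard deviation of the distance
#' between two loci, shape descriptors and hull volume averaged over
#' frames, and censored mean contact time and gap at the threshold.
#'
#' @param ensemble an [Ensemble-class]
#' @param beadI,beadJ 0-based beads of the distance pair.
#' @param thresholdNm contact threshold, nm.
#' @param sigmaNm physical bead diameter, nm.
#' @return data.frame with columns replica, meanDistNm, sdDistNm,
#'   anisotropy, asphericity, volumeNm3, meanContactFrames,
#'   meanGapFrames.
#' @export
trajectoryMetricsTable <- function(ensemble, beadI, beadJ,
                                   thresholdNm = 150,
                                   sigmaNm = mapLengthScale(
                                     ensemble@model@g)) {
  rows <- lapply(trajectories(ensemble), function(tr) {
    ser <- distanceSeries(tr, beadI, beadJ, sigmaNm = sigmaNm)
    ct <- contactTimes(ser, thresholdNm = thresholdNm)
    nf <- dim(tr@frames)[3]
    sh <- vapply(seq_len(nf), function(f) {
      g <- gyrationShape(tr@frames[, , f])
      v <- tryCatch(hullVolume(tr@frames[, , f], sigmaNm),
                    error = function(e) NA_real_)
      c(g$anisotropy, g$asphericity, v)
    }, numeric(3))
    data.frame(replica = tr@replicaId,
               meanDistNm = mean(ser@distanceNm),
               sdDistNm = stats::sd(ser@distanceNm),
               anisotropy = mean(sh[1, ]),
               asphericity = mean(sh[2, ]),
               volumeNm3 = mean(sh[3, ], na.rm = TRUE),
               meanContactFrames = ct$meanContact,
               meanGapFrames = ct$meanGap)
  })
  do.call(rbind, rows)
}
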