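## Contact maps, contact probability, fold changes, triplet contacts.

framesOf <- function(x) {
  if (is(x, "Trajectory")) return(list(x@frames))
  if (is(x, "Ensemble")) return(lapply(x@trajectories, function(t) t@frames))
  if (is.array(x) && length(dim(x)) == 3) return(list(x))
  stop("expected a Trajectory, an Ensemble or an nBeads x 3 x nFrames array")
}

gOf <- function(x, binBp) {
  if (!is.null(binBp)) return(binBp)
  if (is(x, "Trajectory")) return(x@g)
  if (is(x, "Ensemble")) return(x@model@g)
  NA_real_
}

#' Ensemble contact map
#'
#' Marks beads `i`, `j` in contact in a conformation when their Euclidean
#' distance is below `A` sigma, and averages the boolean maps over all
#' conformations.  Replicas are weighted equally regardless of their frame
#' counts.  The default threshold `A = 3` sigma is the midpoint of the
#' 2-3.5 sigma working range for compartment/TAD-scale models.
#'
#' @param x an [Ensemble-class], [Trajectory-class] or a
#'   `nBeads x 3 x nFrames` array of unwrapped coordinates.
#' @param A contact distance threshold, sigma.
#' @param binBp bin size recorded in the map (taken from the input when
#'   available).
#' @return a [ContactMap-class]
#' @export
contactMap <- function(x, A = 3, binBp = NULL) {
  if (A <= 0) stop("contact threshold A must be positive")
  fl <- framesOf(x)
  maps <- lapply(fl, function(fr) {
    nf <- dim(fr)[3]
    .cpp_contact_counts(fr, A) / nf
  })
  m <- Reduce(`+`, maps) / length(maps)
  nConf <- sum(vapply(fl, function(fr) dim(fr)[3], numeric(1)))
  new("ContactMap", map = m, binBp = as.numeric(gOf(x, binBp)),
      threshold = A, nConformations = as.integer(nConf))
}

#' Contact probability versus genomic separation
#'
#' `P(s)` for `s = 0 .. n-1`, the average of each diagonal of the contact
#' map, optionally multiplied by a global scale coefficient (the same
#' coefficient must be applied to every condition being compared).
#'
#' @param map a [ContactMap-class] or square matrix.
#' @param scale global multiplicative coefficient.
#' @return numeric vector of length `n` (`P(0) = scale`).
#' @export
contactProbability <- function(map, scale = 1) {
  m <- if (is(map, "ContactMap")) map@map else map
  n <- nrow(m)
  ps <- vapply(0:(n - 1), function(s)
    mean(m[cbind(seq_len(n - s), seq_len(n - s) + s)]), numeric(1))
  ps * scale
}

#' Average consecutive diagonal sub-matrices
#'
#' Splits the map into `k` equal consecutive diagonal blocks and returns
#' their element-wise mean (the presentation average over repeating
#' blocks).  A remainder of rows that does not fit is dropped with a
#' warning.
#'
#' @param map a [ContactMap-class] or square matrix.
#' @param k number of consecutive blocks.
#' @return a [ContactMap-class] of the block size.
#' @export
averageSubmatrices <- function(map, k) {
  if (k < 1) stop("k must be >= 1")
  cm <- if (is(map, "ContactMap")) map else
    new("ContactMap", map = map, binBp = NA_real_, threshold = NA_real_,
        nConformations = 0L)
  m <- cm@map
  b <- nrow(m) %/% k
  if (nrow(m) %% k != 0)
    warning("dropping ", nrow(m) %% k, " trailing bins that do not fit ",
            k, " equal blocks")
  acc <- matrix(0, b, b)
  for (q in seq_len(k)) {
    idx <- ((q - 1) * b + 1):(q * b)
    acc <- acc + m[idx, idx]
  }
  new("ContactMap", map = acc / k, binBp = cm@binBp,
      threshold = cm@threshold, nConformations = cm@nConformations)
}

#' Log2 fold change between two maps
#'
#' `log2((a + pc) / (b + pc))` entry-wise.  The default pseudocount is the
#' smallest nonzero entry of either map times 1e-2, which keeps zero cells
#' finite without dominating measured values.
#'
#' @param mapA,mapB [ContactMap-class] objects or matrices of equal shape.
#' @param pseudocount override for the pseudocount.
#' @return matrix of log2 fold changes.
#' @export
log2FoldChange <- function(mapA, mapB, pseudocount = NULL) {
  a <- if (is(mapA, "ContactMap")) mapA@map else mapA
  b <- if (is(mapB, "ContactMap")) mapB@map else mapB
  if (!all(dim(a) == dim(b))) stop("maps must have the same shape")
  if (is(mapA, "ContactMap") && is(mapB, "ContactMap") &&
      !is.na(mapA@binBp) && !is.na(mapB@binBp) && mapA@binBp != mapB@binBp)
    stop("maps must share a bin size")
  if (is.null(pseudocount)) {
    nz <- c(a[a > 0], b[b > 0])
    pseudocount <- if (length(nz)) min(nz) * 1e-2 else 1e-6
  }
  log2((a + pseudocount) / (b + pseudocount))
}

#' Triplet-contact matrix for a viewpoint
#'
#' For a fixed viewpoint bead `i`, marks cell `(j, k)` in a conformation
#' when all three mutual distances `d_ij`, `d_jk`, `d_ki` are below the
#' threshold (default 5 sigma), and averages over the ensemble.  The
#' result is symmetric in `(j, k)`.
#'
#' @param x ensemble, trajectory or frames array.
#' @param viewpoint 0-based bead index.
#' @param threshold distance threshold, sigma.
#' @param binBp optional bin size annotation.
#' @return a [TripletMatrix-class]
#' @export
tripletMatrix <- function(x, viewpoint, threshold = 5, binBp = NULL) {
  fl <- framesOf(x)
  n <- dim(fl[[1]])[1]
  if (viewpoint < 0 || viewpoint >= n)
    stop("viewpoint outside the polymer (0-based)")
  maps <- lapply(fl, function(fr) .cpp_triplet_counts(fr, as.integer(viewpoint),
                                                      threshold) / dim(fr)[3])
  m <- Reduce(`+`, maps) / length(maps)
  nConf <- sum(vapply(fl, function(fr) dim(fr)[3], numeric(1)))
  new("TripletMatrix", map = m, viewpoint = as.integer(viewpoint),
      threshold = threshold, nConformations = as.integer(nConf))
}

#' Significance of a specific triple contact
#'
#' Compares the per-conformation indicator of a target triple `(i, j, k)`
#' (all three mutual distances below the threshold) against a control
#' triple shifted `controlOffsetBp` downstream while preserving the
#' relative genomic distances, with a one-sided Mann-Whitney rank test
#' (target greater).  Indicators are binary per conformation.
#'
#' @param x ensemble, trajectory or frames array.
#' @param triple integer vector of three 0-based bead indices.
#' @param controlOffsetBp genomic offset of the control triple (default
#'   100 kb).
#' @param g bp per bead (taken from the input when available).
#' @param threshold distance threshold, sigma (default 5).
#' @return list with `p.value`, `targetFrequency`, `controlFrequency`.
#' @export
tripletSignificance <- function(x, triple, controlOffsetBp = 1e5, g = NULL,
                                threshold = 5) {
  fl <- framesOf(x)
  if (!length(fl) || dim(fl[[1]])[3] == 0) stop("empty ensemble")
  n <- dim(fl[[1]])[1]
  g <- gOf(x, g)
  if (is.na(g)) stop("g (bp per bead) is required to place the control")
  offBeads <- as.integer(round(controlOffsetBp / g))
  control <- as.integer(triple) + offBeads
  if (any(control >= n) || any(control < 0))
    stop("control triple falls outside the polymer")
  ind <- function(beads) unlist(lapply(fl, function(fr)
    .cpp_all_close_indicator(fr, as.integer(beads), threshold)))
  ti <- as.numeric(ind(triple)); ci <- as.numeric(ind(control))
  wt <- suppressWarnings(stats::wilcox.test(ti, ci, alternative = "greater",
                                            exact = FALSE, correct = TRUE))
  list(p.value = wt$p.value, targetFrequency = mean(ti),
       controlFrequency = mean(ci))
}
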