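## Convex fitting of ensemble mixtures: simplex-constrained least squares
## for saddle plots / E1 profiles, and nonnegative fitting with a shared
## scale for contact-probability curves.
##
## Both problems are convex with few basis elements, so the global optimum
## is found exactly by enumerating active sets (faces of the simplex or the
## nonnegative cone) and solving the equality-constrained least-squares
## problem on each face; the best feasible face solution is the global
## minimiser.  Enumeration order (smaller supports first, earlier indices
## first) makes the documented tie-break — mass on the first of duplicated
## basis elements — automatic.

flattenSummary <- function(x) {
  if (is(x, "SaddlePlot")) return(as.vector(x@saddle))
  if (is(x, "ContactMap")) return(as.vector(x@map))
  as.vector(as.numeric(x))
}

subsetsBySize <- function(m, maxSize = m) {
  out <- list()
  for (size in seq_len(maxSize))
    out <- c(out, utils::combn(m, size, simplify = FALSE))
  out
}

#' Best convex combination of basis summaries
#'
#' Finds coefficients `c >= 0`, `sum(c) = 1`, minimising the (optionally
#' weighted) sum of squared entry-by-entry differences between
#' `sum_m c_m basis_m` and the target.  The problem is convex and the
#' solver is exact (active-set enumeration), so the result is the global
#' minimiser; with duplicated basis elements the mass lands on the first
#' duplicate and the objective is unchanged.
#'
#' @param target a [SaddlePlot-class], [ContactMap-class], matrix or
#'   vector.
#' @param basis list of same-shape summaries.
#' @param weights optional per-entry weights (1/variance for a chi-square
#'   objective); unit by default.
#' @return a [FitResult-class]
#' @export
fitSimplexCombination <- function(target, basis, weights = NULL) {
  b <- flattenSummary(target)
  if (!length(basis)) stop("at least one basis element is required")
  cols <- lapply(basis, flattenSummary)
  if (any(vapply(cols, length, integer(1)) != length(b)))
    stop("target and basis shapes differ")
  A <- do.call(cbind, cols)
  m <- ncol(A)
  if (m > 16) stop("active-set enumeration supports at most 16 basis elements")
  w <- if (is.null(weights)) rep(1, length(b)) else as.numeric(weights)
  sw <- sqrt(w)
  Aw <- A * sw; bw <- b * sw
  ids <- names(basis)
  if (is.null(ids)) ids <- paste0("basis", seq_len(m))
  # drop exact duplicates, keep the first occurrence
  keep <- !duplicated(lapply(seq_len(m), function(j) round(A[, j], 12)))
  map <- which(keep)
  Ad <- Aw[, keep, drop = FALSE]
  md <- ncol(Ad)
  best <- NULL
  for (S in subsetsBySize(md)) {
    As <- Ad[, S, drop = FALSE]
    k <- length(S)
    G <- crossprod(As)
    kkt <- rbind(cbind(2 * G, rep(1, k)), c(rep(1, k), 0))
    rhs <- c(2 * crossprod(As, bw), 1)
    sol <- tryCatch(solve(kkt, rhs), error = function(e) NULL)
    if (is.null(sol)) next
    cS <- sol[seq_len(k)]
    if (any(cS < -1e-9)) next
    cS <- pmax(cS, 0); cS <- cS / sum(cS)
    obj <- sum((As %*% cS - bw)^2)
    if (is.null(best) || obj < best$obj - 1e-12) {
      best <- list(obj = obj, S = S, c = cS)
    }
  }
  if (is.null(best)) stop("no feasible face found (degenerate basis)")
  cf <- numeric(m)
  cf[map[best$S]] <- best$c
  new("FitResult", coefficients = cf, objective = best$obj,
      basisIds = ids, scale = NA_real_,
      fitRange = c(NA_real_, NA_real_))
}

#' Fit contact-probability curves with a shared scale
#'
#' Finds simplex coefficients and one positive multiplicative scale (the
#' same scale must be reused across conditions being compared) so that
#' `scale * sum_m c_m basis_m` matches the target `P(s)` curve in the
#' fitted genomic range, minimising the chi-square with unit weights
#' unless a variance vector is supplied.  Internally the product
#' `d = scale * c` is fitted over the nonnegative cone (convex, exact
#' active-set solution), then split into `scale = sum(d)` and
#' `c = d / sum(d)`.
#'
#' @param targetPs target `P(s)` curve (index s = 0, 1, ...).
#' @param basisPs list of basis `P(s)` curves on the same s-grid.
#' @param g bp per bin, to express the fit range in bp.
#' @param fitRangeBp genomic fit range, bp (default 15 kb - 2.5 Mb).
#' @param variance optional per-point variance for chi-square weighting.
#' @return a [FitResult-class] with the shared `scale` filled in.
#' @export
fitContactProbability <- function(targetPs, basisPs, g,
                                  fitRangeBp = c(15e3, 2.5e6),
                                  variance = NULL) {
  n <- length(targetPs)
  cols <- lapply(basisPs, as.numeric)
  if (any(vapply(cols, length, integer(1)) != n))
    stop("basis curves must share the target s-grid")
  sBp <- (seq_len(n) - 1) * g
  inRange <- sBp >= fitRangeBp[1] & sBp <= fitRangeBp[2] & targetPs > 0
  if (!any(inRange)) stop("fit range excludes every point of the s-grid")
  A <- do.call(cbind, cols)[inRange, , drop = FALSE]
  b <- targetPs[inRange]
  w <- if (is.null(variance)) rep(1, length(b)) else 1 / variance[inRange]
  sw <- sqrt(w)
  Aw <- A * sw; bw <- b * sw
  m <- ncol(A)
  if (m > 16) stop("active-set enumeration supports at most 16 basis elements")
  ids <- names(basisPs)
  if (is.null(ids)) ids <- paste0("basis", seq_len(m))
  best <- NULL
  for (S in subsetsBySize(m)) {
    As <- Aw[, S, drop = FALSE]
    sol <- tryCatch(solve(crossprod(As), crossprod(As, bw)),
                    error = function(e) NULL)
    if (is.null(sol)) next
    d <- as.numeric(sol)
    if (any(d < -1e-9)) next
    d <- pmax(d, 0)
    obj <- sum((As %*% d - bw)^2)
    if (is.null(best) || obj < best$obj - 1e-12) best <- list(obj = obj,
                                                             S = S, d = d)
  }
  if (is.null(best) || sum(best$d) <= 0)
    stop("no positive fit found (target orthogonal to the basis?)")
  d <- numeric(m)
  d[best$S] <- best$d
  scale <- sum(d)
  new("FitResult", coefficients = d / scale, objective = best$obj,
      basisIds = ids, scale = scale, fitRange = as.numeric(fitRangeBp))
}
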