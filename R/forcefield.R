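## Pair potentials and the affinity <-> epsilon mapping.

#' Truncated-and-shifted Lennard-Jones pair potential
#'
#' The binder-bead attraction: `4 eps [ (1/r)^12 - (1/r)^6 - (1/rInt)^12 +
#' (1/rInt)^6 ]` for `r < rInt` and exactly 0 otherwise, in kBT with
#' distances in sigma.  The shift makes the potential continuous (value 0)
#' at the cutoff.
#'
#' @param r distance(s) between particle centres, sigma; must be positive.
#' @param epsilon interaction strength in kBT (>= 0).
#' @param rInt attraction cutoff in sigma (1.3 for compartment/TAD models,
#'   2.5 for locus models).
#' @return energy in kBT, vectorised over `r`.
#' @examples
#' pairPotential(2^(1/6), 10, 1.3)   # near the well minimum, about -3.43
#' pairPotential(1.3, 10, 1.3)       # exactly 0 at the cutoff
#' @export
pairPotential <- function(r, epsilon, rInt) {
  if (any(r <= 0)) stop("pair potential undefined for r <= 0")
  if (epsilon < 0) stop("epsilon must be >= 0")
  if (rInt <= 1) stop("rInt must exceed 1 sigma")
  s6 <- (1 / r)^6
  c6 <- (1 / rInt)^6
  v <- 4 * epsilon * (s6^2 - s6 - c6^2 + c6)
  v[r >= rInt] <- 0
  v
}

#' FENE bond energy
#'
#' `-1/2 K R0^2 log(1 - (r/R0)^2)` for `0 <= r < R0`; diverges as `r`
#' approaches `R0` and errors at or beyond it (a broken bond means the
#' integration step was too large).
#'
#' @param r bond length(s), sigma.
#' @param ff a [ForceField-class] supplying `R0` and `kFene`.
#' @return energy in kBT.
#' @export
feneEnergy <- function(r, ff = ForceField()) {
  if (any(r < 0)) stop("bond length must be >= 0")
  if (any(r >= ff@R0))
    stop("FENE bond at or beyond R0 = ", ff@R0,
         " sigma: bond broken (integration must never reach this)")
  -0.5 * ff@kFene * ff@R0^2 * log(1 - (r / ff@R0)^2)
}

#' @rdname ForceField-class
#' @param R0,kFene,kSpring,rEq,epsRep force-field constants, see slots.
#' @export
ForceField <- function(R0 = 1.6, kFene = 30, kSpring = 10, rEq = 1.1,
                       epsRep = 1) {
  new("ForceField", R0 = R0, kFene = kFene, kSpring = kSpring, rEq = rEq,
      epsRep = epsRep)
}

#' Binding affinity of a truncated-shifted LJ well
#'
#' The binding affinity reported for an interaction strength `epsilon` is
#' the depth of the pair potential, `|min_r V(r)|`.  The minimum is located
#' numerically (golden-section refinement of a fine grid); it sits at
#' `r = 2^(1/6)` sigma whenever the cutoff exceeds that distance.
#'
#' @param epsilon interaction strength in kBT.
#' @param rInt attraction cutoff, sigma.
#' @return affinity in kBT (0 for `epsilon = 0`); monotone in `epsilon`.
#' @examples
#' epsilonToAffinity(10, 1.3)  # about 3.43 kBT
#' @export
epsilonToAffinity <- function(epsilon, rInt = 1.3) {
  if (any(epsilon < 0)) stop("epsilon must be >= 0")
  vapply(epsilon, function(e) {
    if (e == 0) return(0)
    o <- stats::optimize(function(r) pairPotential(r, e, rInt),
                         interval = c(0.8, rInt), tol = 1e-10)
    abs(o$objective)
  }, numeric(1))
}

#' Interaction strength for a requested binding affinity
#'
#' Inverse of [epsilonToAffinity()]: the `epsilon` whose truncated-shifted
#' LJ well has depth `affinity` at cutoff `rInt`.  The well depth is linear
#' in `epsilon`, so the inverse is exact.
#'
#' @param affinity desired well depth, kBT.
#' @param rInt attraction cutoff, sigma.
#' @export
affinityToEpsilon <- function(affinity, rInt = 1.3) {
  if (any(affinity < 0)) stop("affinity must be >= 0")
  unit <- epsilonToAffinity(1, rInt)
  affinity / unit
}
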