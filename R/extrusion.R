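## Loop extrusion: anchors, parameters, stochastic extruder dynamics.
##
## Orientation convention (used everywhere): a "forward" anchor blocks legs
## travelling leftward into it, a "reverse" anchor blocks rightward travel,
## so convergent forward/reverse pairs enclose a domain.  Engagement of an
## anchor is drawn once per extruder-anchor encounter (with the anchor's
## probability) and remembered until that extruder detaches.

#' Construct an oriented anchor set
#'
#' @param bead 0-based bead indices.
#' @param orientation `"forward"`, `"reverse"` or `"bidirectional"` per
#'   anchor (recycled).
#' @param prob engagement probability per anchor (recycled).
#' @return an [AnchorSet-class]
#' @export
anchorSet <- function(bead = integer(0), orientation = character(0),
                      prob = numeric(0)) {
  n <- length(bead)
  a <- new("AnchorSet", bead = as.integer(bead),
           orientation = rep_len(as.character(orientation), n),
           prob = rep_len(as.numeric(prob), n))
  validObject(a)
  a
}

#' Regularly spaced bidirectional anchors
#'
#' @param nBeads polymer length; anchors at beads `0, spacing, 2*spacing, ...`
#' @param spacing beads between anchors.
#' @param prob engagement probability.
#' @export
anchorsEvery <- function(nBeads, spacing, prob = 0.5) {
  anchorSet(seq(0L, nBeads - 1L, by = spacing), "bidirectional", prob)
}

#' Loop-extrusion parameter set
#'
#' Either give `nExtruders` directly or a mean genomic `separationKb`
#' between extruders, converted through `nExtruders = N * g / separation`.
#' The detachment rate comes from the processivity (mean extruded loop
#' length) via `proc = 2 g / kOff`, `kOff` per extrusion update.
#'
#' @param nExtruders number of extruders (overrides `separationKb`).
#' @param separationKb mean genomic distance between extruders, kb.
#' @param processivityKb mean extruded loop at detachment, kb (`Inf` or
#'   `NULL` for no detachment).
#' @param nBeads,g polymer size and bp per bead (needed for conversions).
#' @param stepInterval MD steps between extrusion updates.
#' @param oneSided free-leg continuation after the partner halts.
#' @return an [ExtrusionParams-class]
#' @export
extrusionParams <- function(nExtruders = NULL, separationKb = NULL,
                            processivityKb = NULL, nBeads = NULL, g = NULL,
                            stepInterval = 500, oneSided = TRUE) {
  if (is.null(nExtruders)) {
    if (is.null(separationKb)) nExtruders <- 0L
    else {
      if (is.null(nBeads) || is.null(g))
        stop("separationKb needs nBeads and g to convert to a count")
      nExtruders <- as.integer(round(nBeads * g / 1000 / separationKb))
    }
  }
  kOff <- 0
  if (!is.null(processivityKb) && is.finite(processivityKb)) {
    if (is.null(g)) stop("processivityKb needs g to convert to a rate")
    kOff <- 2 * (g / 1000) / processivityKb
  }
  p <- new("ExtrusionParams", nExtruders = as.integer(nExtruders),
           stepInterval = as.integer(stepInterval), kOff = kOff,
           oneSided = oneSided)
  validObject(p)
  p
}

#' Mean extruder separation implied by a parameter set
#' @param params an [ExtrusionParams-class]
#' @param nBeads,g polymer size and bp per bead.
#' @return separation in kb (Inf when no extruders).
#' @export
extruderSeparationKb <- function(params, nBeads, g) {
  if (params@nExtruders == 0) return(Inf)
  nBeads * g / 1000 / params@nExtruders
}

asLegsMatrix <- function(extruders) {
  cbind(as.integer(extruders$i), as.integer(extruders$j))
}
asHaltedMatrix <- function(extruders) {
  cbind(as.logical(extruders$haltedLeft), as.logical(extruders$haltedRight))
}
asExtruderFrame <- function(legs, halted) {
  data.frame(i = legs[, 1], j = legs[, 2],
             haltedLeft = halted[, 1], haltedRight = halted[, 2])
}

anchorArrays <- function(anchors, nBeads) {
  orient <- integer(nBeads); prob <- numeric(nBeads)
  if (length(anchors@bead)) {
    code <- c(forward = 1L, reverse = 2L, bidirectional = 3L)
    orient[anchors@bead + 1L] <- code[anchors@orientation]
    prob[anchors@bead + 1L] <- anchors@prob
  }
  list(orient = orient, prob = prob)
}

#' Seed extruders at random non-overlapping positions
#'
#' Places `params@nExtruders` extruders with legs on adjacent bead pairs
#' `(k, k+1)`, uniformly at random without overlap.
#'
#' @param params an [ExtrusionParams-class]
#' @param nBeads polymer length (>= 2).
#' @param seed integer seed.
#' @return a data.frame with columns `i`, `j`, `haltedLeft`, `haltedRight`.
#' @export
seedExtruders <- function(params, nBeads, seed = 1L) {
  stopifnot(nBeads >= 2)
  n <- params@nExtruders
  if (n > nBeads / 2)
    stop("cannot place ", n, " extruders on ", nBeads,
         " beads without overlap")
  if (n == 0)
    return(data.frame(i = integer(0), j = integer(0),
                      haltedLeft = logical(0), haltedRight = logical(0)))
  legs <- .cpp_seed_extruders(n, as.integer(nBeads), as.integer(seed))
  asExtruderFrame(legs, matrix(FALSE, n, 2))
}

#' One extrusion update (sliding only)
#'
#' Advances every non-halted leg one bead outward in randomized order.  A
#' leg entering a bead occupied by another extruder's leg waits (extruders
#' never cross); a leg stepping onto an engaged anchor of opposing
#' orientation moves onto it and halts permanently; legs at the polymer
#' ends wait.  Engagement draws use the anchor probability, once per
#' encounter within this call.
#'
#' @param extruders data.frame as returned by [seedExtruders()].
#' @param anchors an [AnchorSet-class]
#' @param nBeads polymer length.
#' @param nUpdates number of updates to apply.
#' @param seed integer seed.
#' @param oneSided free-leg continuation flag.
#' @return updated extruder data.frame.
#' @export
extrusionStep <- function(extruders, anchors = anchorSet(), nBeads,
                          nUpdates = 1L, seed = 1L, oneSided = TRUE) {
  aa <- anchorArrays(anchors, nBeads)
  res <- .cpp_extrusion_update(asLegsMatrix(extruders),
                               asHaltedMatrix(extruders),
                               as.integer(nBeads), aa$orient, aa$prob,
                               0, oneSided, as.integer(nUpdates),
                               as.integer(seed), TRUE)
  asExtruderFrame(res$legs, res$halted)
}

#' Stochastic detachment and rebinding
#'
#' Each extruder detaches with per-update probability `1 - exp(-kOff)` and
#' is immediately re-seeded at a random free position with halted flags
#' reset, so the extruder count is conserved exactly.
#'
#' @param extruders data.frame of extruders.
#' @param params an [ExtrusionParams-class] supplying `kOff`.
#' @param nBeads polymer length.
#' @param nUpdates number of detachment rounds.
#' @param seed integer seed.
#' @return list with the updated `extruders` and the genomic-independent
#'   `loopLengths` (beads extruded) recorded at each detachment event.
#' @export
detachRebind <- function(extruders, params, nBeads, nUpdates = 1L,
                         seed = 1L) {
  aa <- anchorArrays(anchorSet(), nBeads)
  res <- .cpp_extrusion_update(asLegsMatrix(extruders),
                               asHaltedMatrix(extruders),
                               as.integer(nBeads), aa$orient, aa$prob,
                               params@kOff, params@oneSided,
                               as.integer(nUpdates), as.integer(seed), FALSE)
  list(extruders = asExtruderFrame(res$legs, res$halted),
       loopLengths = res$loop_lengths)
}

#' Lattice-level extrusion dynamics without MD
#'
#' Runs the extrusion process alone (sliding + detachment/rebinding) for
#' `nUpdates` updates, which is how loop-length statistics against the
#' processivity relation `proc = 2 g / kOff` are collected cheaply.
#'
#' @inheritParams extrusionStep
#' @param params an [ExtrusionParams-class]
#' @return list of final `extruders` and `loopLengths` (in beads) at every
#'   detachment event.
#' @export
simulateExtrusion <- function(params, nBeads, anchors = anchorSet(),
                              nUpdates = 1000L, seed = 1L) {
  ex <- seedExtruders(params, nBeads, seed = deriveSeed(seed, 1L))
  aa <- anchorArrays(anchors, nBeads)
  res <- .cpp_extrusion_update(asLegsMatrix(ex), asHaltedMatrix(ex),
                               as.integer(nBeads), aa$orient, aa$prob,
                               params@kOff, params@oneSided,
                               as.integer(nUpdates), deriveSeed(seed, 2L),
                               TRUE)
  list(extruders = asExtruderFrame(res$legs, res$halted),
       loopLengths = res$loop_lengths)
}

#' Anchors from a binned signal track
#'
#' Converts a binned occupancy signal (e.g., CTCF) into anchor engagement
#' probabilities `p_k = signal_k / max(signal)` (proportionality with
#' max-normalisation), with orientations passed through from the per-bin
#' strand: `"+"` gives a forward anchor, `"-"` reverse, `"."` (or `"*"`)
#' bidirectional.  Zero-signal bins produce no anchor; an all-zero track
#' yields an empty set with a warning.
#'
#' @param signal nonnegative per-bin values, one bin per bead.
#' @param strand character per bin.
#' @param normalize `"max"` (default) or a positive number to divide by.
#' @return an [AnchorSet-class]
#' @export
anchorsFromSignal <- function(signal, strand = rep(".", length(signal)),
                              normalize = "max") {
  if (any(signal < 0)) stop("signal must be nonnegative")
  if (all(signal == 0)) {
    warning("all-zero signal: empty anchor set")
    return(anchorSet())
  }
  denom <- if (identical(normalize, "max")) max(signal) else {
    if (!is.numeric(normalize) || normalize <= 0)
      stop("normalize must be \"max\" or a positive number")
    normalize
  }
  p <- pmin(1, signal / denom)
  keep <- which(signal > 0)
  orient <- c("+" = "forward", "-" = "reverse", "." = "bidirectional",
              "*" = "bidirectional")[strand[keep]]
  if (any(is.na(orient))) stop("strand must be one of '+', '-', '.', '*'")
  anchorSet(keep - 1L, unname(orient), p[keep])
}
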