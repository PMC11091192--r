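## Model builders: compartment-, TAD- and locus-scale polymer models.

newPolymerModel <- function(beadTypes, binderTypes, affinity, g, rInt,
                            anchors = anchorSet(),
                            extrusion = extrusionParams(), inertTail = 0L) {
  m <- new("PolymerModel", nBeads = length(beadTypes),
           beadTypes = beadTypes, binderTypes = binderTypes,
           affinity = affinity, g = g, rInt = rInt, anchors = anchors,
           extrusion = extrusion, inertTail = as.integer(inertTail))
  validObject(m)
  m
}

compartmentAffinity <- function(beadTypes, eAA, eBB, eAB) {
  aff <- matrix(0, 2, length(beadTypes),
                dimnames = list(c("A", "B"), NULL))
  isA <- beadTypes == "A"; isB <- beadTypes == "B"
  aff["A", isA] <- eAA; aff["A", isB] <- eAB
  aff["B", isB] <- eBB; aff["B", isA] <- eAB
  aff
}

#' Block-copolymer model of A/B compartments
#'
#' Alternating A/B blocks of `blockSize` beads with homo-typic binding
#' affinities `eAA`, `eBB` and a hetero-typic background `eAB`
#' (micro-phase separation requires `eAA > eAB` and `eBB > eAB`, which is
#' enforced).  Default affinities sit in the 3.2-3.4 kBT homo-typic range
#' over a 3.1 kBT hetero-typic background.  If `blockSize` does not divide
#' `nBeads` the final block is left incomplete, with a warning.
#'
#' @param nBeads polymer length (default 1000).
#' @param blockSize beads per compartment block (default 75, i.e., 7.5 Mb
#'   blocks at 100 kb per bead).
#' @param eAA,eBB homo-typic affinities, kBT.
#' @param eAB hetero-typic affinity, kBT.
#' @param g genomic content per bead, bp (default 1e5).
#' @param extrusion optional [ExtrusionParams-class]
#' @param anchors optional [AnchorSet-class]
#' @return a [PolymerModel-class]
#' @examples
#' m <- buildCompartmentModel(900, 75)
#' genomicContent(m) / 1e6   # 90 Mb
#' @export
buildCompartmentModel <- function(nBeads = 1000, blockSize = 75, eAA = 3.3,
                                  eBB = 3.3, eAB = 3.1, g = 1e5,
                                  extrusion = extrusionParams(),
                                  anchors = anchorSet()) {
  if (eAA <= eAB || eBB <= eAB)
    stop("micro-phase separation requires homo-typic affinities above the ",
         "hetero-typic background (eAA > eAB and eBB > eAB)")
  if (nBeads %% blockSize != 0)
    warning("blockSize does not divide nBeads: final block is incomplete")
  blockOf <- ((seq_len(nBeads) - 1) %/% blockSize) %% 2
  beadTypes <- ifelse(blockOf == 0, "A", "B")
  newPolymerModel(beadTypes, c("A", "B"),
                  compartmentAffinity(beadTypes, eAA, eBB, eAB),
                  g = g, rInt = 1.3, anchors = anchors,
                  extrusion = extrusion)
}

#' A/B model from a compartment eigenvector
#'
#' Assigns bead types from the sign of the first compartment eigenvector
#' (A where positive, assuming the sign convention is already oriented so
#' that A is positive).  Undefined bins (`NA`) are filled by linear
#' interpolation of the eigenvector around them and then thresholded at
#' zero; the tie at exactly 0 is assigned to A (documented choice).
#'
#' @param e1 per-bin eigenvector values, `NA` where undefined.
#' @param g bp per bin (default 1e5).
#' @param eAA,eBB,eAB affinities as in [buildCompartmentModel()].
#' @return a [PolymerModel-class] with one bead per bin.
#' @export
buildFromEigenvector <- function(e1, g = 1e5, eAA = 3.3, eBB = 3.3,
                                 eAB = 3.1) {
  if (all(is.na(e1))) stop("eigenvector undefined everywhere")
  if (eAA <= eAB || eBB <= eAB)
    stop("micro-phase separation requires homo-typic affinities above the ",
         "hetero-typic background (eAA > eAB and eBB > eAB)")
  n <- length(e1)
  if (anyNA(e1)) {
    known <- which(!is.na(e1))
    e1 <- stats::approx(known, e1[known], xout = seq_len(n), rule = 2)$y
  }
  beadTypes <- ifelse(e1 >= 0, "A", "B")
  newPolymerModel(beadTypes, c("A", "B"),
                  compartmentAffinity(beadTypes, eAA, eBB, eAB),
                  g = g, rInt = 1.3)
}

#' TAD-scale polymer templates
#'
#' `kind = "plain"`: a homopolymer (default N = 1000, 5 kb per bead) with
#' one binder type, bidirectional anchors every 120 beads at engagement
#' probability 0.5 (600 kb mean TAD size), affinity in the 3.1-3.8 kBT
#' range, processivity 500 kb and extruder separation in the 60-500 kb
#' range.  `kind = "with_compartments"`: four equal A-B-A-B compartment
#' blocks (default N = 1000, 10 kb per bead) with five TADs per block and
#' separation in the 100-1000 kb range.  Parameters outside the declared
#' ranges are allowed for exploration but warned about.
#'
#' @param kind `"plain"` or `"with_compartments"`.
#' @param nBeads polymer length (scaled-down variants keep proportions).
#' @param affinity bead-binder affinity for the plain template, kBT.
#' @param eAA,eBB,eAB compartment affinities for `with_compartments`.
#' @param separationKb mean extruder separation, kb.
#' @param processivityKb extruder processivity, kb.
#' @param anchorProb anchor engagement probability.
#' @param anchorSpacing beads between anchors (plain template).
#' @return a [PolymerModel-class]
#' @export
buildTadModel <- function(kind = c("plain", "with_compartments"),
                          nBeads = 1000, affinity = 3.5, eAA = 3.3,
                          eBB = 3.3, eAB = 3.1, separationKb = NULL,
                          processivityKb = 500, anchorProb = 0.5,
                          anchorSpacing = 120) {
  kind <- match.arg(kind)
  if (kind == "plain") {
    g <- 5000
    if (is.null(separationKb)) separationKb <- 120
    if (affinity < 3.1 || affinity > 3.8)
      warning("affinity outside the declared 3.1-3.8 kBT range")
    if (separationKb < 60 || separationKb > 500)
      warning("separation outside the declared 60-500 kb range")
    anch <- anchorsEvery(nBeads, anchorSpacing, anchorProb)
    ex <- extrusionParams(separationKb = separationKb,
                          processivityKb = processivityKb,
                          nBeads = nBeads, g = g)
    aff <- matrix(affinity, 1, nBeads, dimnames = list("B1", NULL))
    newPolymerModel(rep("U", nBeads), "B1", aff, g = g, rInt = 1.3,
                    anchors = anch, extrusion = ex)
  } else {
    g <- 1e4
    if (is.null(separationKb)) separationKb <- 200
    if (eAA <= eAB || eBB <= eAB)
      stop("micro-phase separation requires homo-typic affinities above ",
           "the hetero-typic background")
    if (separationKb < 100 || separationKb > 1000)
      warning("separation outside the declared 100-1000 kb range")
    if (nBeads %% 20 != 0)
      stop("with_compartments template needs nBeads divisible by 20 ",
           "(4 blocks x 5 TADs)")
    blockSize <- nBeads %/% 4
    tadSize <- blockSize %/% 5
    blockOf <- ((seq_len(nBeads) - 1) %/% blockSize) %% 2
    beadTypes <- ifelse(blockOf == 0, "A", "B")
    anch <- anchorsEvery(nBeads, tadSize, anchorProb)
    ex <- extrusionParams(separationKb = separationKb,
                          processivityKb = processivityKb,
                          nBeads = nBeads, g = g)
    newPolymerModel(beadTypes, c("A", "B"),
                    compartmentAffinity(beadTypes, eAA, eBB, eAB),
                    g = g, rInt = 1.3, anchors = anch, extrusion = ex)
  }
}

#' Locus-scale model from a binding-site profile
#'
#' Builds a locus model (500 bp per bead, attraction cutoff 2.5 sigma)
#' from a [BindingProfile-class]: each bead is labelled with its dominant
#' binding-site type (`"inert"` when unoccupied), every binder type gains
#' its homo-typic affinity for beads carrying its sites plus a weak
#' constant hetero-typic affinity for any other occupied bead, and inert
#' tails are added at both ends to control boundary effects.  Anchor
#' indices are given on the profile grid and shifted past the left tail.
#'
#' @param profile a [BindingProfile-class] (`nTypes x nBeads` site counts).
#' @param anchors an [AnchorSet-class] on the profile grid.
#' @param g bp per bead (default 500).
#' @param tails inert beads added at each end (default 50).
#' @param affinity homo-typic affinity per type, kBT (recycled over types;
#'   declared range 2.3-2.9, the infected variant sits at the lower end).
#' @param heteroAffinity weak constant affinity of every binder for any
#'   occupied non-cognate bead, kBT.
#' @param separationKb,processivityKb extrusion parameters (declared
#'   ranges 50-100 kb and 150-400 kb).
#' @return a [PolymerModel-class]
#' @export
buildLocusModel <- function(profile, anchors = anchorSet(), g = 500,
                            tails = 50, affinity = 2.7,
                            heteroAffinity = 1.5, separationKb = 75,
                            processivityKb = 300) {
  stopifnot(is(profile, "BindingProfile"))
  P <- profile@counts
  nTypes <- nrow(P); nCore <- ncol(P)
  if (length(anchors@bead) && max(anchors@bead) >= nCore)
    stop("anchor indices exceed the profile length")
  if (any(affinity < 2.3) || any(affinity > 2.9))
    warning("affinity outside the declared 2.3-2.9 kBT range")
  if (separationKb < 50 || separationKb > 100)
    warning("separation outside the declared 50-100 kb range")
  if (processivityKb < 150 || processivityKb > 400)
    warning("processivity outside the declared 150-400 kb range")
  affinity <- rep_len(affinity, nTypes)
  typeLabels <- profile@typeLabels
  dominant <- apply(P, 2, function(col)
    if (all(col == 0)) "inert" else typeLabels[which.max(col)])
  occupied <- colSums(P) > 0
  core <- matrix(0, nTypes, nCore, dimnames = list(typeLabels, NULL))
  for (t in seq_len(nTypes)) {
    core[t, P[t, ] > 0] <- affinity[t]
    weak <- occupied & P[t, ] == 0
    core[t, weak] <- heteroAffinity
  }
  n <- nCore + 2L * tails
  beadTypes <- c(rep("inert", tails), dominant, rep("inert", tails))
  aff <- cbind(matrix(0, nTypes, tails), core, matrix(0, nTypes, tails))
  anch <- if (length(anchors@bead))
    anchorSet(anchors@bead + tails, anchors@orientation, anchors@prob)
  else anchors
  ex <- extrusionParams(separationKb = separationKb,
                        processivityKb = processivityKb, nBeads = n, g = g)
  newPolymerModel(beadTypes, typeLabels, aff, g = g, rInt = 2.5,
                  anchors = anch, extrusion = ex, inertTail = tails)
}

#' Infected-condition transform of a control model
#'
#' Applies the virally infected re-parameterisation to a control (mock)
#' model as one documented constructor: extruder density is halved
#' (doubled separation) and every attractive affinity is reduced by
#' `affinityReduction` (15-20%, default 17.5%).
#'
#' @param model the control [PolymerModel-class]
#' @param affinityReduction fractional reduction of attractive affinities.
#' @param extruderFactor multiplier on the extruder count (default 0.5).
#' @return the transformed [PolymerModel-class]
#' @export
infectedVariant <- function(model, affinityReduction = 0.175,
                            extruderFactor = 0.5) {
  if (affinityReduction < 0 || affinityReduction >= 1)
    stop("affinityReduction must lie in [0, 1)")
  m <- model
  m@affinity <- model@affinity * (1 - affinityReduction)
  ex <- model@extrusion
  ex@nExtruders <- as.integer(round(ex@nExtruders * extruderFactor))
  m@extrusion <- ex
  validObject(m)
  m
}
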