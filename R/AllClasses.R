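## S4 classes for the simulation and analysis layer.

#' Force-field constants
#'
#' Bonded and non-bonded constants of the bead-spring force field, in
#' dimensionless units (bead diameter sigma = 1, mass m = 1, energies in
#' kBT).  Defaults follow the standard chromatin bead-spring setup: FENE
#' bonds with maximum extension `R0` = 1.6 sigma and spring constant
#' `kFene` = 30 kBT/sigma^2, extruder springs with `kSpring` = 10
#' kBT/sigma^2 and rest length `rEq` = 1.1 sigma, and a purely repulsive
#' truncated Lennard-Jones core of unit strength between all particle
#' pairs (bonded pairs included).
#'
#' @slot R0 maximum FENE bond length (sigma).
#' @slot kFene FENE spring constant (kBT/sigma^2).
#' @slot kSpring extruder spring constant (kBT/sigma^2).
#' @slot rEq extruder spring rest length (sigma).
#' @slot epsRep repulsive-core strength (kBT).
#' @export
setClass("ForceField",
  representation(R0 = "numeric", kFene = "numeric", kSpring = "numeric",
                 rEq = "numeric", epsRep = "numeric"),
  prototype(R0 = 1.6, kFene = 30, kSpring = 10, rEq = 1.1, epsRep = 1))

setValidity("ForceField", function(object) {
  if (object@R0 <= 1) return("R0 must exceed the bead diameter (1 sigma)")
  if (object@kFene <= 0) return("kFene must be positive")
  if (object@kSpring < 0) return("kSpring must be nonnegative")
  TRUE
})

#' Oriented extrusion anchors
#'
#' A set of loop-extrusion anchor points: bead index (0-based), orientation
#' and engagement probability.  A `"forward"` anchor blocks legs travelling
#' leftward into it, a `"reverse"` anchor blocks rightward travel, so a
#' convergent forward/reverse pair encloses a domain; `"bidirectional"`
#' anchors block both directions.
#'
#' @slot bead integer bead indices, 0-based.
#' @slot orientation character, one of `"forward"`, `"reverse"`,
#'   `"bidirectional"` per anchor.
#' @slot prob engagement probability in `[0, 1]` per anchor.
#' @export
setClass("AnchorSet",
  representation(bead = "integer", orientation = "character",
                 prob = "numeric"))

setValidity("AnchorSet", function(object) {
  n <- length(object@bead)
  if (length(object@orientation) != n || length(object@prob) != n)
    return("bead, orientation and prob must have equal length")
  if (n && any(object@bead < 0)) return("bead indices must be >= 0")
  if (!all(object@orientation %in% c("forward", "reverse", "bidirectional")))
    return("orientation must be forward, reverse or bidirectional")
  if (n && (any(object@prob < 0) || any(object@prob > 1)))
    return("probabilities must lie in [0, 1]")
  TRUE
})

#' Loop-extrusion parameters
#'
#' @slot nExtruders number of concurrently bound extruding factors.
#' @slot stepInterval MD steps between extrusion updates (default 500).
#' @slot kOff detachment rate per extrusion update; the mean extruded loop
#'   (processivity) is `2 * g / kOff` bp for a polymer with `g` bp per bead.
#' @slot oneSided if `TRUE` (default) the free leg keeps extruding after its
#'   partner is halted at an anchor.
#' @export
setClass("ExtrusionParams",
  representation(nExtruders = "integer", stepInterval = "integer",
                 kOff = "numeric", oneSided = "logical"),
  prototype(nExtruders = 0L, stepInterval = 500L, kOff = 0, oneSided = TRUE))

setValidity("ExtrusionParams", function(object) {
  if (object@nExtruders < 0) return("nExtruders must be >= 0")
  if (object@stepInterval < 1) return("stepInterval must be >= 1")
  if (object@kOff < 0) return("kOff must be >= 0")
  TRUE
})

#' Polymer model with typed binding sites
#'
#' A chromatin polymer of `nBeads` beads with a genomic content `g` bp per
#' bead, a label per bead (compartment or binding-site type, `"inert"` for
#' tails), an affinity matrix giving the binding affinity (kBT, the depth of
#' the truncated-shifted LJ well) of every binder type for every bead, an
#' oriented anchor set and extrusion parameters.
#'
#' @slot nBeads number of polymer beads.
#' @slot beadTypes character label per bead.
#' @slot binderTypes names of the binder types.
#' @slot affinity matrix `length(binderTypes) x nBeads` of binding
#'   affinities in kBT (0 = purely repulsive pair).
#' @slot g genomic content per bead (bp).
#' @slot rInt attraction cutoff (sigma): 1.3 for compartment/TAD-class
#'   models, 2.5 for locus-class models.
#' @slot anchors an [AnchorSet-class].
#' @slot extrusion an [ExtrusionParams-class].
#' @slot inertTail number of inert tail beads at each end.
#' @export
setClass("PolymerModel",
  representation(nBeads = "integer", beadTypes = "character",
                 binderTypes = "character", affinity = "matrix",
                 g = "numeric", rInt = "numeric", anchors = "AnchorSet",
                 extrusion = "ExtrusionParams", inertTail = "integer"),
  prototype(inertTail = 0L, rInt = 1.3))

setValidity("PolymerModel", function(object) {
  N <- object@nBeads
  if (length(object@beadTypes) != N)
    return("beadTypes must have one label per bead")
  if (nrow(object@affinity) != length(object@binderTypes) ||
      ncol(object@affinity) != N)
    return("affinity must be length(binderTypes) x nBeads")
  if (any(object@affinity < 0)) return("affinities must be >= 0")
  if (object@g <= 0) return("g (bp per bead) must be positive")
  if (object@rInt <= 1) return("rInt must exceed 1 sigma")
  if (length(object@anchors@bead) && max(object@anchors@bead) >= N)
    return("anchor bead indices must be within the polymer")
  inert <- object@beadTypes == "inert"
  if (any(inert) && any(object@affinity[, inert, drop = FALSE] > 0))
    return("inert beads must have zero affinity for every binder type")
  TRUE
})

#' Simulation configuration
#'
#' Langevin-dynamics schedule and environment: timestep, friction,
#' temperature, periodic box, equilibration/production lengths, sampling
#' interval, replicate seeds and binder counts per type.
#'
#' @slot dt integration timestep (default 0.01).
#' @slot zeta friction coefficient (default 0.5).
#' @slot temperature thermostat temperature in kB units (default 1).
#' @slot boxL cubic box edge in sigma (default 50).
#' @slot nEquilSteps MD steps of equilibration before sampling.
#' @slot nProductionSteps MD steps of sampled production.
#' @slot sampleInterval steps between sampled frames (default 5e4;
#'   fine-dynamics runs use 1e3).
#' @slot nReplicas number of independent replicas (up to 30).
#' @slot seeds one RNG seed per replica (distinct).
#' @slot binderCounts named integer vector, binders per type.
#' @slot storeBinders keep binder coordinates in sampled frames.
#' @export
setClass("SimulationConfig",
  representation(dt = "numeric", zeta = "numeric", temperature = "numeric",
                 boxL = "numeric", nEquilSteps = "numeric",
                 nProductionSteps = "numeric", sampleInterval = "numeric",
                 nReplicas = "integer", seeds = "integer",
                 binderCounts = "numeric", storeBinders = "logical"),
  prototype(dt = 0.01, zeta = 0.5, temperature = 1, boxL = 50,
            nEquilSteps = 1e4, nProductionSteps = 5e4, sampleInterval = 5e4,
            nReplicas = 1L, seeds = 1L, binderCounts = numeric(0),
            storeBinders = FALSE))

setValidity("SimulationConfig", function(object) {
  if (object@dt <= 0) return("dt must be positive")
  if (object@boxL <= 2 * 1.6) return("boxL must exceed twice the FENE R0")
  if (object@sampleInterval < 1) return("sampleInterval must be >= 1")
  if (length(object@seeds) != object@nReplicas)
    return("one seed per replica is required")
  if (anyDuplicated(object@seeds)) return("replica seeds must be distinct")
  if (object@nReplicas > 30L) return("at most 30 replicas are supported")
  TRUE
})

#' A single system conformation
#'
#' Unwrapped bead coordinates plus binder coordinates and velocities, in
#' sigma units, with the periodic box edge and an MD time stamp.  Polymer
#' coordinates are stored unwrapped (shape and volume analysis needs them);
#' the minimum-image convention is applied when forces are computed.
#'
#' @export
setClass("Conformation",
  representation(beadPos = "matrix", beadVel = "matrix",
                 binderPos = "matrix", binderVel = "matrix",
                 binderTypes = "character", boxL = "numeric",
                 time = "numeric"))

setValidity("Conformation", function(object) {
  if (ncol(object@beadPos) != 3) return("beadPos must be an n x 3 matrix")
  if (!all(dim(object@beadVel) == dim(object@beadPos)))
    return("beadVel must match beadPos")
  if (nrow(object@binderPos) != length(object@binderTypes))
    return("one binder type per binder is required")
  if (object@boxL <= 0) return("boxL must be positive")
  TRUE
})

#' A time-ordered trajectory of one replica
#'
#' @slot frames array `nBeads x 3 x nFrames` of unwrapped bead coordinates.
#' @slot binderFrames optional array of binder coordinates (or `NULL`).
#' @slot times MD-step time stamps, strictly increasing, equally spaced.
#' @export
setClass("Trajectory",
  representation(frames = "array", binderFrames = "ANY", times = "numeric",
                 replicaId = "integer", boxL = "numeric", g = "numeric",
                 kinetic = "numeric", potential = "numeric",
                 nBinders = "integer", extrusionLog = "list",
                 finalState = "ANY"),
  prototype(binderFrames = NULL, kinetic = numeric(0),
            potential = numeric(0), nBinders = 0L, extrusionLog = list(),
            finalState = NULL))

setValidity("Trajectory", function(object) {
  d <- dim(object@frames)
  if (length(d) != 3 || d[2] != 3)
    return("frames must be an nBeads x 3 x nFrames array")
  if (length(object@times) != d[3])
    return("one time stamp per frame is required")
  if (d[3] > 1) {
    dt <- diff(object@times)
    if (any(dt <= 0)) return("time stamps must be strictly increasing")
    if (max(dt) - min(dt) > 1e-9 * max(dt))
      return("frame spacing must be constant")
  }
  TRUE
})

#' An ensemble of replica trajectories
#' @export
setClass("Ensemble",
  representation(trajectories = "list", model = "PolymerModel",
                 config = "SimulationConfig"))

#' Contact-frequency map
#'
#' Symmetric bead-by-bead contact frequencies in `[0, 1]` (unit diagonal),
#' with the genomic bin size, the distance threshold used (sigma) and the
#' number of conformations aggregated.
#' @export
setClass("ContactMap",
  representation(map = "matrix", binBp = "numeric", threshold = "numeric",
                 nConformations = "integer"))

setValidity("ContactMap", function(object) {
  m <- object@map
  if (nrow(m) != ncol(m)) return("contact map must be square")
  if (max(abs(m - t(m))) > 1e-8) return("contact map must be symmetric")
  if (min(m) < -1e-12 || max(m) > 1 + 1e-12)
    return("contact frequencies must lie in [0, 1]")
  if (max(abs(diag(m) - 1)) > 1e-8) return("diagonal must equal 1")
  TRUE
})

#' Triplet-contact matrix for a fixed viewpoint
#' @export
setClass("TripletMatrix",
  representation(map = "matrix", viewpoint = "integer", threshold = "numeric",
                 nConformations = "integer"))

setValidity("TripletMatrix", function(object) {
  m <- object@map
  if (nrow(m) != ncol(m)) return("triplet matrix must be square")
  if (max(abs(m - t(m))) > 1e-8) return("triplet matrix must be (j,k)-symmetric")
  if (min(m) < -1e-12 || max(m) > 1 + 1e-12)
    return("triplet frequencies must lie in [0, 1]")
  TRUE
})

#' Saddle plot over ranked compartment eigenvector
#'
#' Observed/expected contact averages between quantile bins of the ranked
#' first eigenvector (ascending: most-B first, most-A last).
#' @export
setClass("SaddlePlot",
  representation(saddle = "matrix", nBins = "integer", e1 = "numeric"))

setValidity("SaddlePlot", function(object) {
  if (object@nBins < 2) return("a saddle needs at least 2 bins")
  if (any(!is.finite(object@saddle))) return("saddle entries must be finite")
  TRUE
})

#' Simplex-fit result
#'
#' Convex-combination coefficients (nonnegative, summing to 1), the attained
#' objective, basis identifiers, an optional shared multiplicative scale and
#' the fitted range.
#' @export
setClass("FitResult",
  representation(coefficients = "numeric", objective = "numeric",
                 basisIds = "character", scale = "numeric",
                 fitRange = "numeric"),
  prototype(scale = NA_real_, fitRange = c(NA_real_, NA_real_)))

setValidity("FitResult", function(object) {
  cf <- object@coefficients
  if (any(cf < -1e-6)) return("coefficients must be nonnegative")
  if (abs(sum(cf) - 1) > 1e-6) return("coefficients must sum to 1")
  if (object@objective < -1e-12) return("objective must be >= 0")
  TRUE
})

#' Binding-site profile
#'
#' Nonnegative integer site counts, one row per binding-site type and one
#' column per bead/bin.
#' @export
setClass("BindingProfile",
  representation(counts = "matrix", binBp = "numeric",
                 typeLabels = "character"))

setValidity("BindingProfile", function(object) {
  if (any(object@counts < 0)) return("site counts must be nonnegative")
  if (any(object@counts != round(object@counts)))
    return("site counts must be integers")
  if (length(object@typeLabels) != nrow(object@counts))
    return("one label per type row is required")
  TRUE
})

#' Binned epigenetic signal track
#' @export
setClass("EpiTrack",
  representation(values = "numeric", binBp = "numeric", mark = "character",
                 condition = "character"),
  prototype(condition = ""))

setValidity("EpiTrack", function(object) {
  if (any(object@values < 0)) return("signal values must be nonnegative")
  if (object@binBp <= 0) return("binBp must be positive")
  TRUE
})

#' Distance time series between two loci
#'
#' Per-frame 3D distance in nm between two beads, with frame spacing in MD
#' steps and (via the time mapping) in ms.
#' @export
setClass("ContactTimeSeries",
  representation(distanceNm = "numeric", spacingSteps = "numeric",
                 spacingMs = "numeric", beads = "integer",
                 sigmaNm = "numeric"),
  prototype(spacingMs = NA_real_))

#' Simulated-annealing configuration for binding-site inference
#'
#' @slot nTypesRange candidate numbers of binding-site types.
#' @slot t0 initial temperature of the cost-space Metropolis walk.
#' @slot cooling geometric cooling factor in (0, 1).
#' @slot nTemps number of temperature stages.
#' @slot movesPerBead inner Metropolis moves per temperature, per bead.
#' @slot lambda site-count penalty weight.
#' @slot seed RNG seed.
#' @export
setClass("SAConfig",
  representation(nTypesRange = "integer", t0 = "numeric", cooling = "numeric",
                 nTemps = "integer", movesPerBead = "numeric",
                 lambda = "numeric", seed = "integer"),
  prototype(nTypesRange = 1:4, t0 = 1, cooling = 0.9, nTemps = 60L,
            movesPerBead = 20, lambda = 1e-3, seed = 1L))

setValidity("SAConfig", function(object) {
  if (object@t0 <= 0) return("t0 must be positive")
  if (object@cooling <= 0 || object@cooling >= 1)
    return("cooling must lie in (0, 1)")
  if (object@lambda < 0) return("lambda must be >= 0")
  if (any(object@nTypesRange < 1)) return("nTypesRange must be >= 1")
  TRUE
})
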