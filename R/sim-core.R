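## Langevin MD driver: initial states, single steps, replicas.

# evaluate expr with R's RNG temporarily seeded, restoring the global state
withSeed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

# deterministic stream of derived 31-bit seeds
deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 48271 + k * 65537) %% 2147483647)
}

#' Simulation configuration constructor
#'
#' @param nEquilSteps,nProductionSteps,sampleInterval MD schedule.
#' @param nReplicas number of replicas; `seeds` defaults to a derived
#'   distinct seed per replica.
#' @param seeds integer seeds, one per replica.
#' @param binderCounts named vector of binder counts per binder type.
#' @param dt,zeta,temperature,boxL Langevin parameters and box edge.
#' @param storeBinders keep binder coordinates in sampled frames.
#' @return a [SimulationConfig-class]
#' @export
simulationConfig <- function(nEquilSteps = 1e4, nProductionSteps = 5e4,
                             sampleInterval = 5e4, nReplicas = 1,
                             seeds = NULL, binderCounts = numeric(0),
                             dt = 0.01, zeta = 0.5, temperature = 1,
                             boxL = 50, storeBinders = FALSE) {
  if (is.null(seeds)) seeds <- vapply(seq_len(nReplicas), function(k)
    deriveSeed(7777L, k), integer(1))
  cfg <- new("SimulationConfig", dt = dt, zeta = zeta,
             temperature = temperature, boxL = boxL,
             nEquilSteps = nEquilSteps, nProductionSteps = nProductionSteps,
             sampleInterval = sampleInterval, nReplicas = as.integer(nReplicas),
             seeds = as.integer(seeds), binderCounts = binderCounts,
             storeBinders = storeBinders)
  validObject(cfg)
  cfg
}

#' Default binder counts for a model
#'
#' One binder per two cognate beads of each type (fraction 0.5), the
#' working point of the coil-globule calibration: enough binders that a
#' cognate homopolymer at affinity above ~3.1 kBT collapses, kept constant
#' across conditions.
#'
#' @param model a [PolymerModel-class]
#' @param fraction binders per cognate bead.
#' @export
defaultBinderCounts <- function(model, fraction = 0.5) {
  counts <- vapply(seq_along(model@binderTypes), function(t) {
    cognate <- sum(model@affinity[t, ] > 0)
    max(0L, as.integer(round(fraction * cognate)))
  }, integer(1))
  stats::setNames(counts, model@binderTypes)
}

#' Self-avoiding-walk initial conformation
#'
#' Places the polymer as a random walk with unit steps and a hard pairwise
#' clearance of 1 sigma (all-pairs checked), starting at the box centre,
#' and scatters binders uniformly in the box.  Velocities are drawn from
#' the Maxwell-Boltzmann distribution at `temperature`.  Fully
#' reproducible given `seed`; fails with a clear message if the walk
#' cannot be placed (box too small) after `maxRestarts` restarts.
#'
#' @param nBeads polymer length (>= 1).
#' @param boxL cubic box edge, sigma.
#' @param seed integer seed.
#' @param binderCounts named binder counts per type (may be empty).
#' @param temperature for the initial velocities.
#' @param maxRestarts bounded number of whole-walk restarts.
#' @return a [Conformation-class]
#' @export
initSawConformation <- function(nBeads, boxL, seed, binderCounts = numeric(0),
                                temperature = 1, maxRestarts = 200) {
  stopifnot(nBeads >= 1, boxL > 0)
  pos <- .cpp_init_saw(as.integer(nBeads), boxL, as.integer(seed),
                       as.integer(maxRestarts))
  nm <- sum(binderCounts)
  if (nm > 0 && is.null(names(binderCounts)))
    stop("binderCounts must be named by binder type")
  btypes <- rep(names(binderCounts), times = binderCounts)
  withSeed(deriveSeed(seed, 11L), {
    # binders uniform in the box, but with a hard clearance from every
    # already-placed particle so the stiff cores never start overlapped
    bpos <- matrix(NA_real_, nm, 3)
    if (nm > 0) {
      minImg <- function(d) d - boxL * round(d / boxL)
      for (q in seq_len(nm)) {
        placed <- FALSE
        for (try in seq_len(5000)) {
          cand <- stats::runif(3, 0, boxL)
          dxb <- minImg(sweep(pos, 2, cand))
          ok <- min(rowSums(dxb^2)) >= 1.21   # clearance 1.1 sigma
          if (ok && q > 1) {
            dxm <- minImg(sweep(bpos[seq_len(q - 1), , drop = FALSE], 2, cand))
            ok <- min(rowSums(dxm^2)) >= 1.21
          }
          if (ok) { bpos[q, ] <- cand; placed <- TRUE; break }
        }
        if (!placed)
          stop("could not place binder ", q, " with clearance: box too full")
      }
    }
    vel <- matrix(stats::rnorm(3 * nBeads, 0, sqrt(temperature)), ncol = 3)
    bvel <- matrix(stats::rnorm(3 * nm, 0, sqrt(temperature)), ncol = 3)
  })
  new("Conformation", beadPos = pos, beadVel = vel, binderPos = bpos,
      binderVel = bvel, binderTypes = as.character(btypes), boxL = boxL,
      time = 0)
}

# engine plumbing: expand a model + config into the .cpp_run_engine args
engineArgs <- function(model, config, conformation) {
  eps <- affinityToEpsilon(model@affinity, rInt = model@rInt)
  eps <- matrix(eps, nrow = length(model@binderTypes))
  typeIdx <- match(conformation@binderTypes, model@binderTypes) - 1L
  if (any(is.na(typeIdx)))
    stop("conformation contains binder types unknown to the model")
  orient <- integer(model@nBeads)
  prob <- numeric(model@nBeads)
  a <- model@anchors
  if (length(a@bead)) {
    code <- c(forward = 1L, reverse = 2L, bidirectional = 3L)
    orient[a@bead + 1L] <- code[a@orientation]
    prob[a@bead + 1L] <- a@prob
  }
  list(eps = eps, typeIdx = typeIdx, orient = orient, prob = prob)
}

emptyLegs <- function() matrix(integer(0), 0, 2)
emptyHalted <- function() matrix(logical(0), 0, 2)

#' Advance a conformation by Langevin dynamics
#'
#' Runs `nSteps` BAOAB Langevin steps (velocity Verlet when `zeta = 0`) of
#' beads and binders under the model's force field.  Deterministic given
#' `seed`; aborts with a diagnostic on non-finite positions or a broken
#' FENE bond.
#'
#' @param conformation a [Conformation-class]
#' @param model a [PolymerModel-class]
#' @param config a [SimulationConfig-class] (dt, zeta, temperature, box).
#' @param nSteps number of timesteps.
#' @param seed integer seed for the thermostat noise.
#' @return the advanced [Conformation-class]
#' @export
langevinStep <- function(conformation, model, config, nSteps = 1L, seed = 1L) {
  ea <- engineArgs(model, config, conformation)
  res <- .cpp_run_engine(conformation@beadPos, conformation@beadVel,
                         conformation@binderPos, conformation@binderVel,
                         ea$typeIdx, ea$eps, model@rInt, config@boxL,
                         config@dt, config@zeta, config@temperature,
                         as.integer(nSteps), 0L, as.integer(seed), FALSE,
                         emptyLegs(), emptyHalted(), ea$orient, ea$prob,
                         0, TRUE, 0L, 1.6, 30, 10, 1.1)
  new("Conformation", beadPos = res$bead_pos, beadVel = res$bead_vel,
      binderPos = res$binder_pos, binderVel = res$binder_vel,
      binderTypes = conformation@binderTypes, boxL = config@boxL,
      time = conformation@time + nSteps)
}

#' Run one replica: equilibrate, then sample a trajectory
#'
#' Initialises a self-avoiding walk plus uniform binders, seeds extruders
#' if the model carries them, equilibrates for `nEquilSteps`, then samples
#' every `sampleInterval` steps for `nProductionSteps`.  The per-frame
#' kinetic energy is retained for thermostat diagnostics.
#'
#' @param model a [PolymerModel-class]
#' @param config a [SimulationConfig-class]
#' @param replicaId integer id recorded in the trajectory.
#' @param seed replica seed (defaults to `config@seeds[replicaId]`).
#' @param initialState optional [Conformation-class] to continue from
#'   instead of a fresh self-avoiding walk (in-silico perturbation
#'   experiments branch a shared equilibrated state this way); extruders
#'   are re-seeded at random positions.
#' @return a [Trajectory-class]; its `finalState` slot carries the full
#'   end-of-run [Conformation-class] for continuation.
#' @export
runSimulation <- function(model, config, replicaId = 1L, seed = NULL,
                          initialState = NULL) {
  if (is.null(seed)) seed <- config@seeds[replicaId]
  counts <- config@binderCounts
  if (!length(counts) && length(model@binderTypes))
    counts <- defaultBinderCounts(model)
  conf <- if (is.null(initialState))
    initSawConformation(model@nBeads, config@boxL, deriveSeed(seed, 1L),
                        counts, config@temperature)
  else initialState
  ea <- engineArgs(model, config, conf)
  nx <- model@extrusion@nExtruders
  if (nx > 0) {
    if (nx > model@nBeads / 2) stop("more extruders than bead pairs")
    legs <- .cpp_seed_extruders(nx, model@nBeads, deriveSeed(seed, 2L))
    halted <- matrix(FALSE, nx, 2)
  } else {
    legs <- emptyLegs(); halted <- emptyHalted()
  }
  run <- function(cf, nSteps, sampleEvery, sd2, legs, halted) {
    .cpp_run_engine(cf$beadPos, cf$beadVel, cf$binderPos, cf$binderVel,
                    ea$typeIdx, ea$eps, model@rInt, config@boxL, config@dt,
                    config@zeta, config@temperature, as.integer(nSteps),
                    as.integer(sampleEvery), sd2, config@storeBinders,
                    legs, halted, ea$orient, ea$prob,
                    model@extrusion@kOff, model@extrusion@oneSided,
                    model@extrusion@stepInterval, 1.6, 30, 10, 1.1)
  }
  state <- list(beadPos = conf@beadPos, beadVel = conf@beadVel,
                binderPos = conf@binderPos, binderVel = conf@binderVel)
  if (config@nEquilSteps > 0) {
    eq <- run(state, config@nEquilSteps, 0L, deriveSeed(seed, 3L), legs,
              halted)
    state <- list(beadPos = eq$bead_pos, beadVel = eq$bead_vel,
                  binderPos = eq$binder_pos, binderVel = eq$binder_vel)
    if (nx > 0) { legs <- eq$extrusion$legs; halted <- eq$extrusion$halted }
  }
  pr <- run(state, config@nProductionSteps, config@sampleInterval,
            deriveSeed(seed, 4L), legs, halted)
  frames <- pr$frames
  if (length(frames) == 0)
    stop("no frames sampled: production shorter than the sampling interval")
  exLog <- if (nx > 0) list(legs = pr$extrusion$legs,
                            halted = pr$extrusion$halted,
                            loopLengths = pr$extrusion$loop_lengths)
           else list()
  fin <- new("Conformation", beadPos = pr$bead_pos, beadVel = pr$bead_vel,
             binderPos = pr$binder_pos, binderVel = pr$binder_vel,
             binderTypes = conf@binderTypes, boxL = config@boxL,
             time = conf@time + config@nEquilSteps + config@nProductionSteps)
  new("Trajectory", frames = frames,
      binderFrames = if (config@storeBinders) pr$binder_frames else NULL,
      times = config@nEquilSteps + pr$times,
      replicaId = as.integer(replicaId), boxL = config@boxL, g = model@g,
      kinetic = pr$ke, potential = pr$pe,
      nBinders = as.integer(sum(counts)), extrusionLog = exLog,
      finalState = fin)
}

#' Run independent replicas into an ensemble
#'
#' Runs `config@nReplicas` independent simulations with the per-replica
#' seeds.  A replica failure is isolated: the error is reported, the
#' remaining trajectories are returned and the partial ensemble is
#' flagged with a warning rather than silently truncated.
#'
#' @param model a [PolymerModel-class]
#' @param config a [SimulationConfig-class]
#' @param verbose print one line per replica.
#' @return an [Ensemble-class]
#' @export
runReplicas <- function(model, config, verbose = FALSE) {
  validObject(model); validObject(config)
  used <- rownames(model@affinity)
  trajs <- vector("list", config@nReplicas)
  failed <- character(0)
  for (r in seq_len(config@nReplicas)) {
    trajs[[r]] <- tryCatch(
      runSimulation(model, config, replicaId = r, seed = config@seeds[r]),
      error = function(e) {
        failed <<- c(failed, sprintf("replica %d: %s", r, conditionMessage(e)))
        NULL
      })
    if (verbose)
      message(sprintf("replica %d/%d done (seed %d)", r, config@nReplicas,
                      config@seeds[r]))
  }
  keep <- !vapply(trajs, is.null, logical(1))
  if (!any(keep))
    stop("every replica failed: ", paste(failed, collapse = "; "))
  if (any(!keep))
    warning("partial ensemble: ", paste(failed, collapse = "; "))
  new("Ensemble", trajectories = trajs[keep], model = model, config = config)
}

#' Kinetic temperature of a trajectory
#'
#' `2 <KE> / (3 N)` per sampled frame, where `N` counts beads plus binders;
#' equals the thermostat temperature in equilibrium (equipartition).
#'
#' @param trajectory a [Trajectory-class]
#' @export
kineticTemperature <- function(trajectory) {
  n <- dim(trajectory@frames)[1] + trajectory@nBinders
  2 * trajectory@kinetic / (3 * n)
}
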