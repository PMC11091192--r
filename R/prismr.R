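## Binding-site inference from a contact map: mean-field forward model and
## simulated-annealing optimisation with an overfitting penalty.

#' Mean-field predicted contact map of a binding profile
#'
#' Forward model: predicted contact between beads `u` and `v` is a fixed
#' power-law distance-decay background plus a term proportional to the
#' type-wise co-occupancy of the two beads,
#' `M[u,v] = min(1, (1 + |u-v|)^-gamma + beta * sum_t p[t,u] p[t,v])`,
#' with a unit diagonal.  This is the simplest forward model consistent
#' with binder-mediated bridging: beads sharing binding-site types are
#' predicted to contact in proportion to their co-occupancy.
#'
#' @param profile a [BindingProfile-class] or `nTypes x nBeads` matrix.
#' @param beta co-occupancy enrichment coefficient (default 0.3).
#' @param gamma distance-decay exponent (default 1).
#' @param binBp bin size annotation for the result.
#' @return a [ContactMap-class]
#' @export
predictedMap <- function(profile, beta = 0.3, gamma = 1, binBp = 500) {
  P <- if (is(profile, "BindingProfile")) profile@counts else as.matrix(profile)
  n <- ncol(P)
  s <- abs(outer(seq_len(n), seq_len(n), `-`))
  B <- (1 + s)^(-gamma)
  E <- crossprod(P)
  m <- pmin(B + beta * E, 1)   # matrix first so attributes survive pmin
  diag(m) <- 1
  if (is(profile, "BindingProfile")) binBp <- profile@binBp
  new("ContactMap", map = m, binBp = binBp, threshold = NA_real_,
      nConformations = 0L)
}

#' Annealing cost of a profile against a target map
#'
#' Two terms: the sum of squared differences between the forward-model map
#' and the target over off-diagonal unordered bead pairs, plus
#' `lambda * (total site count)`, penalising profiles with too many sites
#' (overfitting control).
#'
#' @param profile a [BindingProfile-class] or matrix.
#' @param targetMap a [ContactMap-class] or square matrix.
#' @param lambda penalty weight per site.
#' @param beta,gamma forward-model constants (see [predictedMap()]).
#' @return scalar cost (>= 0 when lambda >= 0).
#' @export
saCost <- function(profile, targetMap, lambda = 1e-3, beta = 0.3,
                   gamma = 1) {
  P <- if (is(profile, "BindingProfile")) profile@counts else as.matrix(profile)
  T <- if (is(targetMap, "ContactMap")) targetMap@map else targetMap
  if (ncol(P) != nrow(T)) stop("profile and map sizes differ")
  M <- predictedMap(P, beta = beta, gamma = gamma)@map
  dif <- (M - T)^2
  sse <- sum(dif[upper.tri(dif)])
  sse + lambda * sum(P)
}

#' Infer binding sites from a contact map by simulated annealing
#'
#' For each candidate number of types, anneals a binding profile against
#' the target map under [saCost()] (Metropolis acceptance on add/remove,
#' relocate and type-switch moves, geometric cooling) and then selects the
#' smallest number of types whose penalised cost is within `parsimonyTol`
#' of the best (parsimony rule).  Deterministic given the seed; runs whose
#' cost is still decreasing over the final stages are flagged as not
#' converged.
#'
#' @param targetMap a [ContactMap-class] or square matrix in `[0, 1]`.
#' @param config a [SAConfig-class]
#' @param beta,gamma forward-model constants.
#' @param parsimonyTol relative tolerance of the parsimony rule (default
#'   0.01).
#' @return list with `profile` (a [BindingProfile-class]), `cost`,
#'   `nTypes`, `trace` (per-temperature cost of the selected run),
#'   `converged`, and `byTypes` (cost and convergence per candidate).
#' @export
inferBindingSites <- function(targetMap, config = new("SAConfig"),
                              beta = 0.3, gamma = 1, parsimonyTol = 0.01) {
  T <- if (is(targetMap, "ContactMap")) targetMap@map else targetMap
  if (nrow(T) != ncol(T)) stop("target map must be square")
  validObject(config)
  binBp <- if (is(targetMap, "ContactMap")) targetMap@binBp else NA_real_
  n <- ncol(T)
  runs <- list()
  for (k in seq_along(config@nTypesRange)) {
    nt <- config@nTypesRange[k]
    inner <- as.integer(ceiling(config@movesPerBead * n))
    runs[[k]] <- .cpp_sa_anneal(T, as.integer(nt), config@lambda, beta,
                                gamma, config@t0, config@cooling,
                                config@nTemps, inner, 1L, 0.05,
                                deriveSeed(config@seed, k))
  }
  costs <- vapply(runs, function(r) r$cost, numeric(1))
  bestCost <- min(costs)
  okWithin <- costs <= bestCost * (1 + parsimonyTol) + 1e-12
  sel <- which(okWithin)[1]          # smallest nTypes within tolerance
  run <- runs[[sel]]
  nt <- config@nTypesRange[sel]
  prof <- new("BindingProfile", counts = run$profile,
              binBp = if (is.na(binBp)) 0 else binBp,
              typeLabels = paste0("type", seq_len(nt)))
  if (!run$converged)
    warning("annealing not converged for the selected run ",
            "(cost still decreasing at schedule end)")
  list(profile = prof, cost = run$cost, nTypes = nt, trace = run$trace,
       converged = run$converged,
       byTypes = data.frame(nTypes = config@nTypesRange, cost = costs,
                            converged = vapply(runs, function(r)
                              isTRUE(r$converged), logical(1))))
}

#' Match inferred type rows to reference type rows
#'
#' Binding-site types are identifiable only up to a permutation of type
#' labels; this evaluates all row permutations (small type counts) and
#' returns the one maximising the summed per-type Pearson correlation
#' with the reference profile.
#'
#' @param estimated,reference [BindingProfile-class] objects or matrices
#'   with equal column counts.
#' @return list with `order` (permutation of estimated rows), `perType`
#'   correlations after matching, and `mean` correlation.
#' @export
matchProfileTypes <- function(estimated, reference) {
  E <- if (is(estimated, "BindingProfile")) estimated@counts else
    as.matrix(estimated)
  R <- if (is(reference, "BindingProfile")) reference@counts else
    as.matrix(reference)
  if (ncol(E) != ncol(R)) stop("profiles must share the bead grid")
  nt <- nrow(R)
  if (nrow(E) != nt) stop("profiles must have the same number of types")
  if (nt > 6) stop("permutation matching supports at most 6 types")
  cors <- matrix(NA_real_, nt, nt)
  for (i in seq_len(nt))
    for (j in seq_len(nt))
      cors[i, j] <- suppressWarnings(stats::cor(E[i, ], R[j, ]))
  cors[!is.finite(cors)] <- -1
  perms <- permutationsOf(nt)
  scores <- vapply(seq_len(nrow(perms)), function(p)
    sum(cors[cbind(perms[p, ], seq_len(nt))]), numeric(1))
  bestP <- perms[which.max(scores), ]
  list(order = bestP, perType = cors[cbind(bestP, seq_len(nt))],
       mean = max(scores) / nt)
}

permutationsOf <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- permutationsOf(n - 1)
  out <- matrix(0L, 0, n)
  for (k in seq_len(n)) {
    rest <- setdiff(seq_len(n), k)
    out <- rbind(out, cbind(k, matrix(rest[sub], nrow(sub))))
  }
  unname(out)
}
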