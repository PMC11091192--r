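## Generics, accessors and show methods.

#' @export
setGeneric("nBeads", function(x) standardGeneric("nBeads"))
#' @export
setGeneric("beadTypes", function(x) standardGeneric("beadTypes"))
#' @export
setGeneric("genomicContent", function(x) standardGeneric("genomicContent"))
#' @export
setGeneric("anchors", function(x) standardGeneric("anchors"))
#' @export
setGeneric("contactMatrix", function(x) standardGeneric("contactMatrix"))
#' @export
setGeneric("binSize", function(x) standardGeneric("binSize"))
#' @export
setGeneric("trajectories", function(x) standardGeneric("trajectories"))
#' @export
setGeneric("profileMatrix", function(x) standardGeneric("profileMatrix"))
#' @export
setGeneric("trackValues", function(x) standardGeneric("trackValues"))
#' @export
setGeneric("saddleMatrix", function(x) standardGeneric("saddleMatrix"))

#' Number of beads of a polymer model
#' @param x a [PolymerModel-class]
#' @export
setMethod("nBeads", "PolymerModel", function(x) x@nBeads)
#' @export
setMethod("nBeads", "Trajectory", function(x) dim(x@frames)[1])
#' @export
setMethod("beadTypes", "PolymerModel", function(x) x@beadTypes)
#' Genomic span in bp (`nBeads * g`)
#' @param x a [PolymerModel-class]
#' @export
setMethod("genomicContent", "PolymerModel", function(x) x@nBeads * x@g)
#' @export
setMethod("anchors", "PolymerModel", function(x) x@anchors)
#' @export
setMethod("contactMatrix", "ContactMap", function(x) x@map)
#' @export
setMethod("contactMatrix", "TripletMatrix", function(x) x@map)
#' @export
setMethod("binSize", "ContactMap", function(x) x@binBp)
#' @export
setMethod("binSize", "BindingProfile", function(x) x@binBp)
#' @export
setMethod("binSize", "EpiTrack", function(x) x@binBp)
#' @export
setMethod("trajectories", "Ensemble", function(x) x@trajectories)
#' @export
setMethod("profileMatrix", "BindingProfile", function(x) x@counts)
#' @export
setMethod("trackValues", "EpiTrack", function(x) x@values)
#' @export
setMethod("saddleMatrix", "SaddlePlot", function(x) x@saddle)

#' @export
setMethod("length", "AnchorSet", function(x) length(x@bead))

#' Fitted simplex coefficients
#' @param object a [FitResult-class]
#' @param ... ignored
#' @export
setMethod("coef", "FitResult", function(object, ...) {
  stats::setNames(object@coefficients, object@basisIds)
})

setMethod("show", "PolymerModel", function(object) {
  tab <- table(object@beadTypes)
  cat("PolymerModel:", object@nBeads, "beads x", object@g, "bp =",
      format(object@nBeads * object@g / 1e6, digits = 4), "Mb\n")
  cat("  bead types:",
      paste(sprintf("%s(%d)", names(tab), as.integer(tab)), collapse = " "),
      "\n")
  cat("  binder types:", paste(object@binderTypes, collapse = ", "),
      "| rInt =", object@rInt, "sigma\n")
  cat("  anchors:", length(object@anchors@bead),
      "| extruders:", object@extrusion@nExtruders, "\n")
})

setMethod("show", "SimulationConfig", function(object) {
  cat("SimulationConfig: dt =", object@dt, "zeta =", object@zeta,
      "T =", object@temperature, "box L =", object@boxL, "\n")
  cat("  equil", format(object@nEquilSteps, big.mark = ","),
      "+ production", format(object@nProductionSteps, big.mark = ","),
      "steps, sampled every", format(object@sampleInterval, big.mark = ","),
      "\n")
  cat("  replicas:", object@nReplicas, "| binders:",
      if (length(object@binderCounts))
        paste(sprintf("%s=%d", names(object@binderCounts),
                      as.integer(object@binderCounts)), collapse = " ")
      else "none", "\n")
})

setMethod("show", "Ensemble", function(object) {
  nf <- vapply(object@trajectories, function(t) dim(t@frames)[3], integer(1))
  cat("Ensemble of", length(object@trajectories), "trajectories (",
      sum(nf), "frames ) for a", object@model@nBeads, "bead model\n")
})

setMethod("show", "ContactMap", function(object) {
  cat("ContactMap:", nrow(object@map), "x", ncol(object@map), "bins of",
      object@binBp, "bp | threshold", object@threshold, "sigma |",
      object@nConformations, "conformations\n")
})

setMethod("show", "BindingProfile", function(object) {
  cat("BindingProfile:", nrow(object@counts), "types x", ncol(object@counts),
      "beads (", sum(object@counts), "sites ), bin", object@binBp, "bp\n")
})

setMethod("show", "FitResult", function(object) {
  cat("FitResult: objective =", format(object@objective, digits = 6), "\n")
  print(round(coef(object), 4))
  if (!is.na(object@scale)) cat("  shared scale =",
                                format(object@scale, digits = 6), "\n")
})

setMethod("show", "SaddlePlot", function(object) {
  cat("SaddlePlot:", object@nBins, "x", object@nBins,
      "quantile bins of ranked E1\n")
})
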