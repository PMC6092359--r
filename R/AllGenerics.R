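#' Accessors for model objects
#'
#' Accessor generics for the scrambling-assay and trajectory classes.
#' Slot access by users is discouraged; these are the supported interface.
#'
#' @param object a \pkg{scramblr} object
#' @return the requested component
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("alphaRate", function(object) standardGeneric("alphaRate"))
#' @rdname accessors
#' @export
setGeneric("betaRate", function(object) standardGeneric("betaRate"))
#' @rdname accessors
#' @export
setGeneric("gammaRate", function(object) standardGeneric("gammaRate"))
#' @rdname accessors
#' @export
setGeneric("emptyFraction", function(object) standardGeneric("emptyFraction"))
#' @rdname accessors
#' @export
setGeneric("innerFraction", function(object) standardGeneric("innerFraction"))
#' @rdname accessors
#' @export
setGeneric("leakRate", function(object) standardGeneric("leakRate"))
#' @rdname accessors
#' @export
setGeneric("params", function(object) standardGeneric("params"))
#' @rdname accessors
#' @export
setGeneric("fitMode", function(object) standardGeneric("fitMode"))
#' @rdname accessors
#' @export
setGeneric("isLowerBound", function(object) standardGeneric("isLowerBound"))
#' @rdname accessors
#' @export
setGeneric("traceTime", function(object) standardGeneric("traceTime"))
#' @rdname accessors
#' @export
setGeneric("fluorescence", function(object) standardGeneric("fluorescence"))
#' @rdname accessors
#' @export
setGeneric("condition", function(object) standardGeneric("condition"))
#' @rdname accessors
#' @export
setGeneric("atoms", function(object) standardGeneric("atoms"))
#' @rdname accessors
#' @export
setGeneric("nFrames", function(object) standardGeneric("nFrames"))
#' @rdname accessors
#' @export
setGeneric("frameCoords", function(object, frame) standardGeneric("frameCoords"))
#' @rdname accessors
#' @export
setGeneric("boxDims", function(object, frame) standardGeneric("boxDims"))
#' @rdname accessors
#' @export
setGeneric("frameTimes", function(object) standardGeneric("frameTimes"))
#' @rdname accessors
#' @export
setGeneric("protomers", function(object) standardGeneric("protomers"))
#' @rdname accessors
#' @export
setGeneric("eigenvalues", function(object) standardGeneric("eigenvalues"))
#' @rdname accessors
#' @export
setGeneric("eigenvectors", function(object) standardGeneric("eigenvectors"))
#' @rdname accessors
#' @export
setGeneric("ticaLag", function(object) standardGeneric("ticaLag"))
#' @rdname accessors
#' @export
setGeneric("stateLabels", function(object) standardGeneric("stateLabels"))
#' @rdname accessors
#' @export
setGeneric("stateCenters", function(object) standardGeneric("stateCenters"))

#' @rdname accessors
setMethod("alphaRate", "KineticParams", function(object) object@alpha)
#' @rdname accessors
setMethod("betaRate", "KineticParams", function(object) object@beta)
#' @rdname accessors
setMethod("gammaRate", "KineticParams", function(object) object@gamma)
#' @rdname accessors
setMethod("emptyFraction", "KineticParams", function(object) object@f0)
#' @rdname accessors
setMethod("innerFraction", "KineticParams", function(object) object@liPF)
#' @rdname accessors
setMethod("leakRate", "KineticParams", function(object) object@leak)

#' @rdname accessors
setMethod("params", "FitResult", function(object) object@params)
#' @rdname accessors
setMethod("alphaRate", "FitResult", function(object) object@params@alpha)
#' @rdname accessors
setMethod("betaRate", "FitResult", function(object) object@params@beta)
#' @rdname accessors
setMethod("gammaRate", "FitResult", function(object) object@params@gamma)
#' @rdname accessors
setMethod("fitMode", "FitResult", function(object) object@mode)
#' @rdname accessors
setMethod("isLowerBound", "FitResult", function(object) object@lowerBoundOnly)

#' @rdname accessors
setMethod("traceTime", "FluorescenceTrace", function(object) object@time)
#' @rdname accessors
setMethod("fluorescence", "FluorescenceTrace", function(object) object@fluorescence)
#' @rdname accessors
setMethod("condition", "FluorescenceTrace", function(object) object@condition)
#' @rdname accessors
setMethod("length", "FluorescenceTrace", function(x) length(x@time))

#' @rdname accessors
setMethod("atoms", "Trajectory", function(object) object@atoms)
#' @rdname accessors
setMethod("nFrames", "Trajectory", function(object) dim(object@xyz)[3])
#' @rdname accessors
setMethod("frameCoords", "Trajectory", function(object, frame) {
  stopifnot(frame >= 1, frame <= dim(object@xyz)[3])
  object@xyz[, , frame, drop = TRUE]
})
#' @rdname accessors
setMethod("boxDims", "Trajectory", function(object, frame) object@box[frame, ])
#' @rdname accessors
setMethod("frameTimes", "Trajectory", function(object) object@times)
#' @rdname accessors
setMethod("protomers", "Trajectory", function(object)
  sort(unique(object@atoms$chain[object@atoms$type == "protein"])))

#' @rdname accessors
setMethod("eigenvalues", "TICAModel", function(object) object@evals)
#' @rdname accessors
setMethod("eigenvectors", "TICAModel", function(object) object@evecs)
#' @rdname accessors
setMethod("ticaLag", "TICAModel", function(object) object@lag)

#' @rdname accessors
setMethod("stateLabels", "MicrostateMap", function(object) object@labels)
#' @rdname accessors
setMethod("stateCenters", "MicrostateMap", function(object) object@centers)

setMethod("show", "KineticParams", function(object) {
  cat("KineticParams\n")
  cat(sprintf("  alpha = %.4g /s, beta = %.4g /s, gamma = %.4g /s\n",
              object@alpha, object@beta, object@gamma))
  cat(sprintf("  f0 = %.3f, Li^PF = %.3f, leak = %.3g /s\n",
              object@f0, object@liPF, object@leak))
})

setMethod("show", "FluorescenceTrace", function(object) {
  cc <- object@condition
  cat(sprintf("FluorescenceTrace: %s (%s Ca2+), replicate %s, batch %s\n",
              cc$construct, if (isTRUE(cc$ca)) "+" else "0",
              cc$replicate, cc$batch))
  cat(sprintf("  %d samples over %.1f s; F range [%.3f, %.3f]\n",
              length(object@time), diff(range(object@time)),
              min(object@fluorescence), max(object@fluorescence)))
})

setMethod("show", "FitResult", function(object) {
  cat(sprintf("FitResult (mode = %s, converged = %s)\n",
              object@mode, object@converged))
  p <- object@params
  if (object@lowerBoundOnly)
    cat(sprintf("  rate-limited: alpha = beta > %.3g /s (lower bound)\n",
                object@bound))
  else
    cat(sprintf("  alpha = %.4g /s, beta = %.4g /s\n", p@alpha, p@beta))
  cat(sprintf("  gamma = %.4g /s, f0 = %.3f, Li^PF = %.3f, leak = %.3g /s\n",
              p@gamma, p@f0, p@liPF, p@leak))
  if (length(object@stderr))
    cat("  stderr:", paste(sprintf("%s = %.3g", names(object@stderr),
                                   object@stderr), collapse = ", "), "\n")
  cat(sprintf("  residual RMS = %.4g\n", object@residualRMS))
})

setMethod("show", "GrooveDefinition", function(object) {
  cat("GrooveDefinition\n")
  cat(sprintf("  %d groove residues; cutoffs (A): water %.1f, lipid %.1f, contact %.1f, gate %.1f, near %.1f\n",
              length(object@grooveResidues), object@waterCutoff,
              object@lipidCutoff, object@contactCutoff, object@gateCutoff,
              object@nearCutoff))
  cat(sprintf("  compartment planes: Calpha of residues %d / %d\n",
              object@boundaryResidues[1], object@boundaryResidues[2]))
})

setMethod("show", "Trajectory", function(object) {
  tab <- table(object@atoms$type)
  cat(sprintf("Trajectory: %d frames, %d atoms (%s)\n",
              dim(object@xyz)[3], nrow(object@atoms),
              paste(sprintf("%s: %d", names(tab), tab), collapse = ", ")))
  cat(sprintf("  protomers: %s\n",
              paste(protomers(object), collapse = ", ")))
})

setMethod("show", "TICAModel", function(object) {
  cat(sprintf("TICAModel: lag %d frames, %d components\n",
              object@lag, length(object@evals)))
  cat("  eigenvalues:", paste(sprintf("%.3f", object@evals), collapse = " "),
      "\n")
})

setMethod("show", "MicrostateMap", function(object) {
  cat(sprintf("MicrostateMap: %d microstates over %d frames\n",
              object@k, length(object@labels)))
})
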