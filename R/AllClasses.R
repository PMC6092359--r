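#' @import methods
NULL

#' Kinetic parameters of the three-state scrambling/bleaching model
#'
#' Container for the rate constants and population parameters of the
#' dithionite bleaching assay model. A liposome preparation is a mixture of
#' protein-free vesicles (fraction \code{f0}) and vesicles carrying at least
#' one active scramblase. Fluorescent reporter lipids on the outer leaflet
#' are bleached by dithionite at rate \code{gamma}; scramblases exchange
#' lipids between leaflets with forward rate \code{alpha} (inner to outer)
#' and reverse rate \code{beta}. A slow background decay \code{leak}
#' (dithionite permeation / spontaneous flipping) multiplies the protected
#' inner-leaflet fluorescence by \code{exp(-leak * t)}.
#'
#' @slot alpha forward scrambling rate constant (1/s)
#' @slot beta reverse scrambling rate constant (1/s)
#' @slot gamma dithionite reduction rate (1/s)
#' @slot f0 fraction of protein-free (empty) vesicles, in [0, 1]
#' @slot liPF inner-leaflet fluorescent-lipid fraction of protein-free
#'   vesicles, in [0, 1]
#' @slot leak background decay rate L (1/s)
#' @seealso [kineticParams()], [fTot()], [simulateTrace()]
#' @exportClass KineticParams
setClass("KineticParams",
  representation(alpha = "numeric", beta = "numeric", gamma = "numeric",
                 f0 = "numeric", liPF = "numeric", leak = "numeric"),
  prototype(alpha = 0, beta = 0, gamma = 2, f0 = 1, liPF = 0.5, leak = 5.4e-5))

setValidity("KineticParams", function(object) {
  msg <- character()
  for (s in c("alpha", "beta", "gamma", "f0", "liPF", "leak")) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, sprintf("'%s' must be a single finite number", s))
  }
  if (!length(msg)) {
    if (object@alpha < 0) msg <- c(msg, "alpha must be >= 0")
    if (object@beta < 0) msg <- c(msg, "beta must be >= 0")
    if (object@gamma < 0) msg <- c(msg, "gamma must be >= 0")
    if (object@f0 < 0 || object@f0 > 1) msg <- c(msg, "f0 must be in [0, 1]")
    if (object@liPF < 0 || object@liPF > 1)
      msg <- c(msg, "liPF must be in [0, 1]")
    if (object@leak < 0) msg <- c(msg, "leak must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Normalized dithionite-bleaching fluorescence time course
#'
#' One fluorescence decay trace, normalized so that the mean pre-addition
#' signal is 1 and time zero is the moment of dithionite addition.
#'
#' @slot time time points in seconds, strictly increasing, \code{time[1] >= 0}
#' @slot fluorescence normalized fluorescence values
#' @slot condition list with elements \code{construct}, \code{ca}
#'   (logical, Ca2+ present), \code{replicate}, \code{batch}
#' @seealso [normalizeTrace()], [simulateTrace()]
#' @exportClass FluorescenceTrace
setClass("FluorescenceTrace",
  representation(time = "numeric", fluorescence = "numeric",
                 condition = "list"))

setValidity("FluorescenceTrace", function(object) {
  msg <- character()
  n <- length(object@time)
  if (n < 50L) msg <- c(msg, "a trace needs at least 50 samples")
  if (length(object@fluorescence) != n)
    msg <- c(msg, "time and fluorescence lengths differ")
  if (n && (any(!is.finite(object@time)) || object@time[1] < 0 ||
            any(diff(object@time) <= 0)))
    msg <- c(msg, "time must be finite, start at >= 0 and strictly increase")
  if (any(!is.finite(object@fluorescence)))
    msg <- c(msg, "fluorescence must be finite")
  need <- c("construct", "ca", "replicate", "batch")
  if (!all(need %in% names(object@condition)))
    msg <- c(msg, paste("condition must contain:", paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Result of fitting the bleaching model to a trace
#'
#' @slot params fitted [KineticParams-class] (free parameters updated, fixed
#'   parameters unchanged)
#' @slot free names of the parameters that were free in the fit
#' @slot mode one of \code{"full"}, \code{"linear"}, \code{"protein_free"}
#' @slot lowerBoundOnly \code{TRUE} when detection was rate-limited by the
#'   dithionite chemistry so the reported alpha is only a lower bound
#' @slot bound the lower bound on alpha when \code{lowerBoundOnly} (1/s)
#' @slot residualRMS root-mean-square residual (normalized units)
#' @slot converged did the optimizer converge
#' @slot stderr named numeric vector of standard errors for free parameters
#' @seealso [fitFull()], [fitProteinFree()], [fitLinear()]
#' @exportClass FitResult
setClass("FitResult",
  representation(params = "KineticParams", free = "character",
                 mode = "character", lowerBoundOnly = "logical",
                 bound = "numeric", residualRMS = "numeric",
                 converged = "logical", stderr = "numeric"))

setValidity("FitResult", function(object) {
  msg <- character()
  if (!object@mode %in% c("full", "linear", "protein_free"))
    msg <- c(msg, "mode must be 'full', 'linear' or 'protein_free'")
  if (length(object@lowerBoundOnly) != 1L)
    msg <- c(msg, "lowerBoundOnly must be a single logical")
  if (length(msg)) msg else TRUE
})

#' Definition of the hydrophilic groove and all analysis cutoffs
#'
#' Residue lists (4WIS numbering) and distance cutoffs used by every
#' trajectory observable. Defaults follow the published analysis protocol:
#' a water belongs to the groove if any of its atoms is within 3 A of the
#' sidechains of the groove-lining residues; a lipid if its phosphorus atom
#' is within 5 A of those sidechains; a residue-lipid contact uses 7 A to
#' any residue atom; an extracellular gate salt bridge counts as formed at
#' a minimum distance of 3 A or shorter; lipid headgroups are "near" the
#' E313/R432 pair within 5 A.
#'
#' @slot grooveResidues residue ids lining the groove
#' @slot waterCutoff groove-water cutoff (A)
#' @slot lipidCutoff groove-lipid (phosphorus) cutoff (A)
#' @slot contactCutoff residue-lipid contact cutoff (A)
#' @slot gateCutoff gate bond cutoff (A)
#' @slot nearCutoff near-pair cutoff for lipid counting at E313/R432 (A)
#' @slot boundaryResidues the two residues (T381, Q436) whose C-alpha planes
#'   delimit the central compartment
#' @slot tm3Span,tm6Span residue spans whose C-alpha centers of mass define
#'   the TM3-TM6 opening distance
#' @slot gateResidues named integer vector: \code{e313}, \code{e318},
#'   \code{t333}, \code{r432}, \code{q436}, \code{y439}
#' @seealso [grooveDefinition()]
#' @exportClass GrooveDefinition
setClass("GrooveDefinition",
  representation(grooveResidues = "integer", waterCutoff = "numeric",
                 lipidCutoff = "numeric", contactCutoff = "numeric",
                 gateCutoff = "numeric", nearCutoff = "numeric",
                 boundaryResidues = "integer", tm3Span = "integer",
                 tm6Span = "integer", gateResidues = "integer"))

setValidity("GrooveDefinition", function(object) {
  msg <- character()
  cuts <- c(object@waterCutoff, object@lipidCutoff, object@contactCutoff,
            object@gateCutoff, object@nearCutoff)
  if (any(!is.finite(cuts)) || any(cuts <= 0))
    msg <- c(msg, "all cutoffs must be positive")
  if (length(object@boundaryResidues) != 2L)
    msg <- c(msg, "boundaryResidues must contain exactly two residue ids")
  need <- c("e313", "e318", "t333", "r432", "q436", "y439")
  if (!all(need %in% names(object@gateResidues)))
    msg <- c(msg, paste("gateResidues must name:", paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Labeled molecular trajectory
#'
#' Frames of coordinates for a labeled system: protein residues (4WIS
#' numbering, one chain per protomer), lipids (each with a phosphorus atom
#' and tail carbons) and waters. The membrane normal is z and, after
#' centering, the membrane mid-point (mean z of all lipid phosphorus atoms)
#' sits at z = 0 in every frame.
#'
#' @slot atoms data.frame with columns \code{eleno}, \code{elety} (atom
#'   name), \code{resid} (residue number), \code{resname}, \code{chain},
#'   \code{type} (\code{"protein"}, \code{"lipid"} or \code{"water"}) and
#'   \code{molid} (molecule id, unique per lipid/water molecule)
#' @slot xyz numeric array \code{c(nAtoms, 3, nFrames)} in Angstrom
#' @slot box numeric matrix \code{nFrames x 3} of orthorhombic box lengths
#'   (A); \code{NA} rows disable periodic wrapping for that frame
#' @slot times frame times (ns)
#' @seealso [readTrajectory()], [renderToyTrajectory()]
#' @exportClass Trajectory
setClass("Trajectory",
  representation(atoms = "data.frame", xyz = "array", box = "matrix",
                 times = "numeric"))

setValidity("Trajectory", function(object) {
  msg <- character()
  need <- c("eleno", "elety", "resid", "resname", "chain", "type", "molid")
  if (!all(need %in% names(object@atoms)))
    msg <- c(msg, paste("atoms must contain columns:",
                        paste(need, collapse = ", ")))
  d <- dim(object@xyz)
  if (length(d) != 3L || d[2] != 3L)
    msg <- c(msg, "xyz must be an nAtoms x 3 x nFrames array")
  else {
    if (d[1] != nrow(object@atoms))
      msg <- c(msg, "xyz first dimension must match nrow(atoms)")
    if (d[3] < 1L) msg <- c(msg, "at least one frame is required")
    if (nrow(object@box) != d[3] || ncol(object@box) != 3L)
      msg <- c(msg, "box must be an nFrames x 3 matrix")
    if (length(object@times) != d[3])
      msg <- c(msg, "times must have one entry per frame")
  }
  if (!length(msg)) {
    pro <- object@atoms[object@atoms$type == "protein", ]
    if (!nrow(pro)) msg <- c(msg, "at least one protein protomer is required")
    if (!all(object@atoms$type %in% c("protein", "lipid", "water")))
      msg <- c(msg, "atom type must be protein, lipid or water")
  }
  if (length(msg)) msg else TRUE
})

#' Scripted toy trajectory
#'
#' A declarative script for [renderToyTrajectory()]: per-frame extracellular
#' gate states, central-constriction states, lipid paths (groove membership,
#' z position, tilt, proximity to the gate pair) and groove water counts,
#' all per protomer, plus decoy molecules and coordinate jitter.
#'
#' @slot nFrames number of frames
#' @slot gate data.frame(frame, protomer, ecState, centralOpen) where
#'   \code{ecState} is \code{"closed"} (E313-R432 bonded),
#'   \code{"intermediate"} (E318-R432 bonded) or \code{"open"} (neither)
#' @slot lipids data.frame(lipid, protomer, frame, inGroove, z, tiltDeg,
#'   nearGate) describing each scripted lipid's path
#' @slot waters data.frame(frame, protomer, nInGroove)
#' @slot nDecoysPerLeaflet bulk lipids per leaflet per protomer
#' @slot box orthorhombic box lengths (A)
#' @slot jitter Gaussian coordinate jitter SD (A), truncated at 2 SD so the
#'   scripted cutoff margins are preserved
#' @slot seed RNG seed for the jitter
#' @seealso [trajScript()], [renderToyTrajectory()]
#' @exportClass TrajScript
setClass("TrajScript",
  representation(nFrames = "integer", gate = "data.frame",
                 lipids = "data.frame", waters = "data.frame",
                 nDecoysPerLeaflet = "integer", box = "numeric",
                 jitter = "numeric", seed = "integer"))

#' Fitted tICA model
#'
#' Time-lagged independent component analysis of a multivariate feature
#' series: the generalized eigen-decomposition of the symmetrized lagged
#' covariance against the instantaneous covariance. Components are ordered
#' by decreasing eigenvalue (autocorrelation at the chosen lag).
#'
#' @slot lag lag time in frames
#' @slot means feature means used for centering
#' @slot evecs matrix of eigenvectors (columns), normalized to unit variance
#'   in the C(0) metric
#' @slot evals eigenvalues, descending
#' @slot ridge ridge added to the diagonal of C(0)
#' @seealso [fitTICA()], [projectTICA()], [explainedFraction()]
#' @exportClass TICAModel
setClass("TICAModel",
  representation(lag = "integer", means = "numeric", evecs = "matrix",
                 evals = "numeric", ridge = "numeric"))

setValidity("TICAModel", function(object) {
  msg <- character()
  if (is.unsorted(rev(object@evals)))
    msg <- c(msg, "eigenvalues must be sorted in decreasing order")
  if (ncol(object@evecs) != length(object@evals))
    msg <- c(msg, "one eigenvalue per eigenvector column is required")
  if (length(msg)) msg else TRUE
})

#' k-means microstate discretization of a tICA plane
#'
#' @slot k number of microstates
#' @slot centers k x d matrix of cluster centers in tICA space
#' @slot labels per-frame microstate assignment, in 1..k
#' @slot sizes frames per microstate
#' @seealso [kmeansMicrostates()], [microstateProfiles()]
#' @exportClass MicrostateMap
setClass("MicrostateMap",
  representation(k = "integer", centers = "matrix", labels = "integer",
                 sizes = "integer"))

setValidity("MicrostateMap", function(object) {
  msg <- character()
  if (any(object@labels < 1L | object@labels > object@k))
    msg <- c(msg, "labels must lie in 1..k")
  if (nrow(object@centers) != object@k)
    msg <- c(msg, "centers must have k rows")
  if (length(msg)) msg else TRUE
})
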