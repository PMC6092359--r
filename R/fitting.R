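#' Build a normalized fluorescence trace
#'
#' Normalizes a raw fluorimeter recording: the fluorescence is divided by
#' the mean signal over the pre-addition window, time is shifted so that
#' dithionite addition is t = 0, and pre-addition samples are dropped.
#'
#' @param time raw time (s)
#' @param fluor raw fluorescence (arbitrary units)
#' @param additionTime time of dithionite addition (s); must lie inside the
#'   recorded range with at least 5 samples before it
#' @param construct construct label (e.g. "WT", "E313W", "protein-free")
#' @param ca logical, Ca2+ present
#' @param replicate replicate id
#' @param batch reconstitution batch id
#' @return a [FluorescenceTrace-class]
#' @examples
#' tt <- seq(0, 430, by = 1)
#' f <- ifelse(tt < 30, 1000, 1000 * (0.5 + 0.5 * exp(-2 * (tt - 30))))
#' normalizeTrace(tt, f, additionTime = 30, construct = "protein-free")
#' @export
normalizeTrace <- function(time, fluor, additionTime, construct = "WT",
                           ca = TRUE, replicate = 1L, batch = "B1") {
  stopifnot(length(time) == length(fluor))
  if (additionTime <= min(time) || additionTime > max(time))
    stop("additionTime must lie inside the recorded time range")
  pre <- time < additionTime
  if (sum(pre) < 5L)
    stop("at least 5 pre-addition samples are required for normalization")
  ref <- mean(fluor[pre])
  if (!is.finite(ref) || ref <= 0)
    stop("cannot normalize: nonpositive pre-addition mean")
  keep <- !pre
  new("FluorescenceTrace",
      time = time[keep] - additionTime,
      fluorescence = fluor[keep] / ref,
      condition = list(construct = construct, ca = isTRUE(ca),
                       replicate = replicate, batch = batch))
}

# ---- internal optimizer plumbing ----------------------------------------

# bounds in natural units; rates are optimized in log10 space
.FIT_BOUNDS <- list(alpha = c(1e-7, 50), beta = c(1e-7, 50),
                    gamma = c(0.01, 20), f0 = c(0, 1), liPF = c(0, 1))

.isRate <- function(nm) nm %in% c("alpha", "beta", "gamma")

.toOpt <- function(v, nm) ifelse(.isRate(nm), log10(v), v)
.fromOpt <- function(v, nm) ifelse(.isRate(nm), 10^v, v)

# run bounded Levenberg-Marquardt on the named free parameters of `fn`,
# possibly from several starts; returns the best solution
.lmFit <- function(residFun, starts, lower, upper) {
  best <- NULL
  for (i in seq_len(nrow(starts))) {
    fit <- try(minpack.lm::nls.lm(
      par = as.numeric(starts[i, ]), fn = residFun,
      lower = lower, upper = upper,
      control = minpack.lm::nls.lm.control(maxiter = 200, ftol = 1e-12,
                                           ptol = 1e-12)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$deviance < best$deviance) best <- fit
  }
  best
}

# standard errors of free parameters (natural units) from an nls.lm fit in
# the transformed space, by the delta method
.lmStderr <- function(fit, freeNames) {
  se <- rep(NA_real_, length(freeNames))
  names(se) <- freeNames
  n <- length(fit$fvec)
  p <- length(fit$par)
  if (n <= p) return(se)
  s2 <- fit$deviance / (n - p)
  cv <- try(solve(fit$hessian) * 2 * s2, silent = TRUE)
  if (inherits(cv, "try-error")) return(se)
  d <- sqrt(pmax(diag(cv), 0))
  # delta method for log10-parametrized rates: se(x) = x * ln(10) * se(log10 x)
  val <- .fromOpt(fit$par, freeNames)
  se[] <- ifelse(.isRate(freeNames), val * log(10) * d, d)
  se
}

.updateParams <- function(p, values) {
  for (nm in names(values)) slot(p, nm) <- unname(values[nm])
  validObject(p)
  p
}

#' Fit the protein-free bleaching model to a trace
#'
#' Two-stage protocol for protein-free liposome traces. First gamma and
#' Li^PF are estimated by nonlinear least squares on the single-exponential
#' protein-free model over the exponential phase (t <= 7/gamma, iterated
#' once). Then, if the trace extends well beyond the exponential phase, the
#' slow leak rate L is estimated from a linear fit to the tail
#' (t > tCutFactor/gamma): the tail is Li^PF * exp(-Lt), so
#' L = -slope / (Li^PF * exp(-L tbar)), solved by fixed-point iteration.
#'
#' @param trace a [FluorescenceTrace-class] from protein-free vesicles
#' @param tCutFactor the tail used for the leak fit starts at
#'   \code{tCutFactor / gamma} (default 5, i.e. >99.3\% of the exponential
#'   transient has decayed)
#' @param minTail minimum number of tail samples required to estimate the
#'   leak (default 100); with a shorter tail the leak is left at 0 and the
#'   fit is flagged
#' @return a [FitResult-class] with mode \code{"protein_free"}; alpha and
#'   beta are fixed at 0 and f0 at 1
#' @examples
#' p <- kineticParams(alpha = 0, gamma = 2, f0 = 1, liPF = 0.5, leak = 0)
#' tr <- simulateTrace(p, duration = 300, noiseSD = 0, seed = 1)
#' fitProteinFree(tr)
#' @export
fitProteinFree <- function(trace, tCutFactor = 5, minTail = 100L) {
  stopifnot(is(trace, "FluorescenceTrace"))
  tt <- trace@time
  ff <- trace@fluorescence
  # crude initial gamma from the 1/e point of the fast phase
  fmin <- stats::quantile(ff, 0.02, names = FALSE)
  target <- fmin + (ff[1] - fmin) * exp(-1)
  i0 <- which(ff <= target)[1]
  g0 <- if (is.na(i0) || tt[i0] <= 0) 1 else 1 / tt[i0]
  g0 <- min(max(g0, .FIT_BOUNDS$gamma[1]), .FIT_BOUNDS$gamma[2])

  freeNames <- c("gamma", "liPF")
  lower <- .toOpt(c(.FIT_BOUNDS$gamma[1], 0), freeNames)
  upper <- .toOpt(c(.FIT_BOUNDS$gamma[2], 1), freeNames)
  fitOnce <- function(gGuess) {
    win <- tt <= min(max(tt), 7 / gGuess)
    twin <- tt[win]; fwin <- ff[win]
    resid <- function(par) {
      v <- .fromOpt(par, freeNames)
      v[2] + (1 - v[2]) * exp(-v[1] * twin) - fwin
    }
    .lmFit(resid, starts = matrix(.toOpt(c(gGuess, 0.5), freeNames), 1),
           lower = lower, upper = upper)
  }
  fit <- fitOnce(g0)
  if (is.null(fit)) stop("protein-free fit failed to converge")
  gHat <- .fromOpt(fit$par, freeNames)[1]
  fit <- fitOnce(gHat)
  est <- .fromOpt(fit$par, freeNames)
  names(est) <- freeNames
  gHat <- est["gamma"]; liHat <- est["liPF"]
  if (gHat <= .FIT_BOUNDS$gamma[1] * 1.001)
    stop("protein-free fit rejected: gamma estimate at lower bound")

  # leak from the post-exponential tail
  leakHat <- 0
  tailIdx <- tt > tCutFactor / gHat
  leakKnown <- sum(tailIdx) >= minTail && liHat > 0.05
  if (leakKnown) {
    lmfit <- stats::lm(ff[tailIdx] ~ tt[tailIdx])
    slope <- -stats::coef(lmfit)[2]
    tbar <- mean(tt[tailIdx])
    L <- max(slope, 0) / liHat
    for (i in 1:8) L <- max(slope, 0) / (liHat * exp(-L * tbar))
    leakHat <- L
  }
  pp <- .updateParams(new("KineticParams"),
                      c(alpha = 0, beta = 0, gamma = unname(gHat),
                        f0 = 1, liPF = unname(liHat), leak = unname(leakHat)))
  rms <- sqrt(mean((fPF(tt, pp) - ff)^2))
  new("FitResult", params = pp, free = c("gamma", "liPF", "leak")[c(TRUE, TRUE, leakKnown)],
      mode = "protein_free", lowerBoundOnly = FALSE, bound = NA_real_,
      residualRMS = rms, converged = !is.null(fit) && fit$info %in% 1:4,
      stderr = .lmStderr(fit, freeNames))
}

#' Fit the full mixed-population bleaching model
#'
#' Constrained nonlinear least squares on the total-fluorescence model.
#' Li^PF must be supplied from the same-batch protein-free fit; for mutant
#' traces f0 is constrained to the value determined in WT(+Ca2+)
#' proteoliposomes of the same reconstitution and only alpha and beta are
#' free. Rates are optimized in log10 space within bounds
#' alpha, beta in [1e-7, 50] /s and gamma in [0.01, 20] /s, with three
#' log-spaced alpha starts to avoid the alpha/gamma exchange local minimum.
#'
#' @param trace a [FluorescenceTrace-class]
#' @param liPF inner-leaflet fraction from the same-batch protein-free fit
#'   (fixed)
#' @param f0 fraction of empty vesicles; \code{NULL} (WT+Ca traces) leaves
#'   it free
#' @param gamma dithionite reduction rate; \code{NULL} leaves it free
#'   (normally fixed to the same-batch protein-free calibration)
#' @param leak background decay rate, fixed (default the protein-free
#'   consensus 5.4e-5 /s)
#' @param symmetric constrain alpha = beta
#' @return a [FitResult-class] with mode \code{"full"}
#' @examples
#' p <- kineticParams(alpha = 0.01, gamma = 2, f0 = 0.55, liPF = 0.5, leak = 0)
#' tr <- simulateTrace(p, duration = 400, noiseSD = 0, seed = 1)
#' fitFull(tr, liPF = 0.5, f0 = 0.55, gamma = 2, leak = 0)
#' @export
fitFull <- function(trace, liPF, f0 = NULL, gamma = NULL, leak = 5.4e-5,
                    symmetric = FALSE) {
  stopifnot(is(trace, "FluorescenceTrace"))
  if (liPF < 0 || liPF > 1) stop("liPF must be in [0, 1]")
  tt <- trace@time
  ff <- trace@fluorescence

  freeNames <- c("alpha", if (!symmetric) "beta",
                 if (is.null(f0)) "f0", if (is.null(gamma)) "gamma")
  fixed <- c(liPF = liPF, leak = leak,
              if (!is.null(f0)) c(f0 = f0),
              if (!is.null(gamma)) c(gamma = gamma))

  model <- function(v) {
    p <- new("KineticParams")
    all <- c(v, fixed)
    if (symmetric) all["beta"] <- all["alpha"]
    .updateParams(p, all[c("alpha", "beta", "gamma", "f0", "liPF", "leak")])
  }
  resid <- function(par) {
    v <- .fromOpt(par, freeNames); names(v) <- freeNames
    fTot(tt, model(v)) - ff
  }
  lower <- .toOpt(vapply(freeNames, function(n) .FIT_BOUNDS[[n]][1], 0), freeNames)
  upper <- .toOpt(vapply(freeNames, function(n) .FIT_BOUNDS[[n]][2], 0), freeNames)
  aStarts <- c(1e-4, 1e-2, 1)
  starts <- do.call(rbind, lapply(aStarts, function(a0) {
    st <- c(alpha = a0, beta = a0, f0 = 0.5,
            gamma = if (is.null(gamma)) 2 else gamma)[freeNames]
    .toOpt(st, freeNames)
  }))
  fit <- .lmFit(resid, starts, lower, upper)
  if (is.null(fit)) stop("full fit failed to converge")
  v <- .fromOpt(fit$par, freeNames); names(v) <- freeNames
  pp <- model(v)
  atBound <- any(abs(fit$par - lower) < 1e-8) || any(abs(fit$par - upper) < 1e-8)
  if (atBound) warning("one or more parameters ended at a bound")
  new("FitResult", params = pp,
      free = c(freeNames, if (symmetric) "beta"),
      mode = "full", lowerBoundOnly = FALSE, bound = NA_real_,
      residualRMS = sqrt(fit$deviance / length(tt)),
      converged = fit$info %in% 1:4,
      stderr = .lmStderr(fit, freeNames))
}

#' Flag fits in the rate-limited detection regime
#'
#' When scrambling is faster than the dithionite chemistry the fluorescence
#' decay is limited by the chemical reduction step and alpha is no longer
#' identifiable; only a lower bound can be reported. A fitted alpha at or
#' above \code{kappa * gamma} (default kappa = 0.1) marks the fit as
#' rate-limited, with the reported bound
#' \code{max(alphaHat, alphaRef * gamma / gammaRef)} — i.e. the canonical
#' 0.2 /s bound at gamma = 2 /s, rescaled to the actual dithionite rate.
#'
#' @param fit a full-mode [FitResult-class]
#' @param gamma dithionite rate used (defaults to the fitted/fixed gamma)
#' @param kappa identifiability threshold on alpha/gamma; default 0.1
#' @param alphaRef,gammaRef reference bound: alpha > 0.2 /s at gamma = 2 /s
#' @return the (possibly updated) [FitResult-class]
#' @export
resolveRateLimited <- function(fit, gamma = gammaRate(fit), kappa = 0.1,
                               alphaRef = 0.2, gammaRef = 2) {
  stopifnot(is(fit, "FitResult"))
  if (fit@mode != "full") stop("resolveRateLimited expects a full-mode fit")
  aHat <- fit@params@alpha
  if (aHat >= kappa * gamma) {
    fit@lowerBoundOnly <- TRUE
    fit@bound <- max(aHat, alphaRef * gamma / gammaRef)
  }
  fit
}

#' Linear-regime fit for very slow scramblers
#'
#' For mutants with alpha = beta << gamma the total fluorescence after the
#' exponential transient is, to first order, linear in time:
#' F(t) = F0 - C(alpha + L) t. The linear tail (t > tCutFactor/gamma) is
#' fitted by least squares and the slope converted to a rate using
#' C = (1 - f0) * w (the slowly-decaying amplitude of the scramblase
#' population, w = beta/(alpha+beta), 0.5 under the symmetric constraint),
#' after subtracting the protein-free leak contribution f0 * Li^PF * L.
#' A fixed-point iteration corrects for the residual exponential curvature
#' of the tail, and the slow eigenvalue is converted back to alpha through
#' lambda1 = alpha * gamma / (alpha + beta + gamma) (symmetric case).
#'
#' @param trace a [FluorescenceTrace-class]
#' @param leak leak rate L from the same-batch protein-free fit (fixed)
#' @param gamma dithionite rate from the same-batch protein-free fit
#' @param f0 fraction of empty vesicles (from the same-batch WT+Ca fit)
#' @param liPF inner-leaflet fraction (protein-free fit)
#' @param w slow-amplitude weight beta/(alpha+beta); default 0.5
#' @param tCutFactor tail starts at \code{tCutFactor/gamma}; default 5
#' @return a [FitResult-class] with mode \code{"linear"}
#' @export
fitLinear <- function(trace, leak, gamma, f0, liPF, w = 0.5, tCutFactor = 5) {
  stopifnot(is(trace, "FluorescenceTrace"))
  tt <- trace@time
  ff <- trace@fluorescence
  tailIdx <- tt > tCutFactor / gamma
  if (sum(tailIdx) < 100L)
    stop("linear region shorter than 100 samples; cannot fit")
  tl <- tt[tailIdx]; fl <- ff[tailIdx]
  lmfit <- stats::lm(fl ~ tl)
  slope <- -stats::coef(lmfit)[[2]]
  slopeSE <- summary(lmfit)$coefficients[2, 2]
  tbar <- mean(tl)
  C <- (1 - f0) * w
  if (C <= 0) stop("f0 = 1 leaves no scramblase population to fit")
  lam <- 0
  for (i in 1:10)
    lam <- max((slope - f0 * liPF * leak * exp(-leak * tbar)) /
                 (C * exp(-(lam + leak) * tbar)) - leak, 0)
  # invert lambda1 = alpha*gamma/(alpha+beta+gamma) with alpha = beta
  aHat <- if (lam > 0) lam * (gamma - lam) / (gamma - 2 * lam) else 0
  aHat <- max(aHat, 0)
  seA <- slopeSE / (C * exp(-(lam + leak) * tbar))
  pp <- .updateParams(new("KineticParams"),
                      c(alpha = aHat, beta = aHat, gamma = gamma, f0 = f0,
                        liPF = liPF, leak = leak))
  rms <- sqrt(mean(stats::residuals(lmfit)^2))
  new("FitResult", params = pp, free = c("alpha", "beta"), mode = "linear",
      lowerBoundOnly = FALSE, bound = NA_real_, residualRMS = rms,
      converged = TRUE, stderr = c(alpha = seA))
}

#' Fit a scrambling trace with automatic mode selection
#'
#' Runs the full constrained fit, applies the rate-limited check, and falls
#' back to the linear slow-regime protocol when the fitted rate is so small
#' that less than ~30\% of the slow decay is observable within the trace
#' (alphaHat * tmax < 0.3) — the regime where the linear approximation is
#' both valid and better conditioned.
#'
#' @inheritParams fitFull
#' @param kappa rate-limited threshold passed to [resolveRateLimited()]
#' @param mode \code{"auto"}, \code{"full"} or \code{"linear"}
#' @return a [FitResult-class]
#' @export
fitScrambling <- function(trace, liPF, f0 = NULL, gamma = NULL, leak = 5.4e-5,
                          symmetric = FALSE, kappa = 0.1,
                          mode = c("auto", "full", "linear")) {
  mode <- match.arg(mode)
  if (mode == "linear") {
    if (is.null(f0) || is.null(gamma))
      stop("linear mode requires fixed f0 and gamma")
    return(fitLinear(trace, leak = leak, gamma = gamma, f0 = f0, liPF = liPF))
  }
  fit <- fitFull(trace, liPF = liPF, f0 = f0, gamma = gamma, leak = leak,
                 symmetric = symmetric)
  g <- gammaRate(fit)
  fit <- resolveRateLimited(fit, gamma = g, kappa = kappa)
  if (mode == "full" || fit@lowerBoundOnly) return(fit)
  tmax <- max(trace@time)
  if ((alphaRate(fit) * tmax < 0.3 || !fit@converged) && !is.null(f0)) {
    lin <- try(fitLinear(trace, leak = leak, gamma = g, f0 = f0, liPF = liPF),
               silent = TRUE)
    if (!inherits(lin, "try-error")) return(lin)
  }
  fit
}

#' Classify the impact of a mutation on scrambling
#'
#' Fold reduction of the scrambling rate constant relative to WT,
#' categorized as in mutagenesis scans: low (<10-fold reduction), medium
#' (10- to 100-fold), high (>100-fold). A fold of 0.5 or below (a two-fold or
#' greater rate increase) is labeled "enhanced". A mutant whose fit is only a lower
#' bound (rate-limited detection) is classified as low impact.
#'
#' @param alphaWT WT scrambling rate constant (1/s)
#' @param alphaMut mutant scrambling rate constant (1/s)
#' @param mutantLowerBound is the mutant estimate only a lower bound
#' @return list with \code{foldReduction} and \code{label}
#' @examples
#' classifyImpact(0.2, 0.002)   # 100-fold: medium
#' @export
classifyImpact <- function(alphaWT, alphaMut, mutantLowerBound = FALSE) {
  if (mutantLowerBound)
    return(list(foldReduction = NA_real_, label = "low"))
  if (!is.finite(alphaWT) || !is.finite(alphaMut) ||
      alphaWT <= 0 || alphaMut <= 0)
    stop("rate constants must be positive")
  fold <- alphaWT / alphaMut
  label <- if (fold <= 0.5) "enhanced"
    else if (fold < 10) "low"
    else if (fold <= 100) "medium"
    else "high"
  list(foldReduction = fold, label = label)
}
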