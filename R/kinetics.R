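#' Construct kinetic parameters for the bleaching assay model
#'
#' @param alpha forward scrambling rate constant (1/s)
#' @param beta reverse scrambling rate constant (1/s); defaults to
#'   \code{alpha} (scrambling is close to symmetric in practice)
#' @param gamma dithionite reduction rate (1/s), or \code{NULL} to derive it
#'   from \code{secondOrderRate * dithionite}
#' @param f0 fraction of protein-free vesicles
#' @param liPF inner-leaflet fluorescent-lipid fraction of protein-free
#'   vesicles
#' @param leak slow background decay rate L (1/s); default 5.4e-5
#' @param secondOrderRate second-order dithionite reduction rate constant
#'   gamma' (1/s/mM), used when \code{gamma} is \code{NULL}
#' @param dithionite dithionite concentration [D] (mM); default 40
#' @return a [KineticParams-class] object
#' @examples
#' kineticParams(alpha = 0.001, gamma = 2, f0 = 0.55, liPF = 0.5)
#' @export
kineticParams <- function(alpha, beta = alpha, gamma = 2, f0 = 0, liPF = 0.5,
                          leak = 5.4e-5, secondOrderRate = NULL,
                          dithionite = 40) {
  if (is.null(gamma)) {
    if (is.null(secondOrderRate) || secondOrderRate <= 0 || dithionite <= 0)
      stop("to derive gamma, supply secondOrderRate > 0 and dithionite > 0")
    gamma <- secondOrderRate * dithionite
  }
  new("KineticParams", alpha = as.numeric(alpha), beta = as.numeric(beta),
      gamma = as.numeric(gamma), f0 = as.numeric(f0), liPF = as.numeric(liPF),
      leak = as.numeric(leak))
}

#' Dithionite reduction rate from the second-order rate constant
#'
#' gamma = gamma' * [D]. The second-order constant gamma' is never assumed;
#' it is calibrated from a protein-free fit at known dithionite
#' concentration ([fitProteinFree()]).
#'
#' @param secondOrderRate gamma' (1/s/mM)
#' @param concentration dithionite concentration [D] (mM); default 40
#' @return gamma (1/s)
#' @export
dithioniteGamma <- function(secondOrderRate, concentration = 40) {
  if (secondOrderRate <= 0 || concentration <= 0)
    stop("secondOrderRate and concentration must be positive")
  secondOrderRate * concentration
}

# relative discriminant threshold under which the degenerate
# (coincident-eigenvalue) expansion is used
.DEGENERATE_TOL <- 1e-12

#' Eigenstructure of the three-state bleaching model
#'
#' The scrambling/bleaching scheme Li <-> Lo -> L* has rate matrix
#' \code{[[-alpha, beta], [alpha, -(beta+gamma)]]} on (Li, Lo). Its
#' eigenvalues are
#' \deqn{\lambda_{1,2} = -[(\alpha+\beta+\gamma) \mp
#'   \sqrt{(\alpha+\beta+\gamma)^2 - 4\alpha\gamma}]/2}
#' and the normalization constant of the closed-form decay is
#' \deqn{D = (\lambda_1+\alpha)(\lambda_2+\beta+\gamma) - \alpha\beta.}
#' The discriminant is nonnegative for nonnegative rates, so both
#' eigenvalues are real with \code{lambda2 <= lambda1 <= 0}.
#'
#' @param p a [KineticParams-class] object
#' @return list with \code{lambda1} (slow), \code{lambda2} (fast),
#'   \code{D}, and \code{degenerate} (TRUE when the eigenvalues coincide to
#'   within tolerance)
#' @examples
#' eigenstructure(kineticParams(alpha = 0, beta = 0.5, gamma = 2))
#' @export
eigenstructure <- function(p) {
  stopifnot(is(p, "KineticParams"))
  validObject(p)
  a <- p@alpha; b <- p@beta; g <- p@gamma
  s <- a + b + g
  disc <- s^2 - 4 * a * g
  degenerate <- s > 0 && disc < .DEGENERATE_TOL * s^2
  sq <- sqrt(max(disc, 0))
  l2 <- -(s + sq) / 2
  # stable form of -(s - sq)/2: avoids cancellation when alpha*gamma << s^2
  l1 <- if (s + sq > 0) -2 * a * g / (s + sq) else 0
  D <- (l1 + a) * (l2 + b + g) - a * b
  list(lambda1 = l1, lambda2 = l2, D = D, degenerate = degenerate)
}

# Closed-form inner/outer leaflet probabilities of the scramblase scheme,
# leak-free: solution of dLi/dt = -a*Li + b*Lo, dLo/dt = a*Li - (b+g)*Lo
# from the scramblase equilibrium Li(0) = b/(a+b), Lo(0) = a/(a+b).
# Returns list(li, lo) vectorized over t. Requires a + b > 0.
.scrComponents <- function(t, a, b, g) {
  if (a == 0)                       # inner pool never feeds the outer leaflet
    return(list(li = rep(1, length(t)), lo = rep(0, length(t))))
  if (b == 0)                       # no inner pool at equilibrium
    return(list(li = rep(0, length(t)), lo = exp(-g * t)))
  s <- a + b + g
  disc <- s^2 - 4 * a * g
  if (s > 0 && disc < .DEGENERATE_TOL * s^2) {
    # coincident eigenvalues: exp(At) x0 = exp(lt) (I + t(A - lI)) x0
    l <- -s / 2
    li0 <- b / (a + b); lo0 <- a / (a + b)
    dli <- (-a - l) * li0 + b * lo0
    dlo <- a * li0 + (-(b + g) - l) * lo0
    e <- exp(l * t)
    return(list(li = e * (li0 + t * dli), lo = e * (lo0 + t * dlo)))
  }
  sq <- sqrt(disc)
  l2 <- -(s + sq) / 2
  l1 <- -2 * a * g / (s + sq)
  c1 <- -l2 / ((a + b) * (l1 - l2))
  c2 <-  l1 / ((a + b) * (l1 - l2))
  e1 <- exp(l1 * t); e2 <- exp(l2 * t)
  list(li = b * (c1 * e1 + c2 * e2),
       lo = c1 * (a + l1) * e1 + c2 * (a + l2) * e2)
}

.checkTime <- function(t) {
  if (any(!is.finite(t)) || any(t < 0))
    stop("time must be finite and nonnegative")
}

#' Protein-free fluorescence decay
#'
#' In protein-free vesicles only outer-leaflet reporters are accessible to
#' dithionite:
#' \deqn{F_{PF}(t) = L_i^{PF} e^{-Lt} + (1 - L_i^{PF}) e^{-\gamma t}}
#' where the protected inner-leaflet plateau decays with the slow leak rate
#' L (exactly the textbook single-exponential form when L = 0).
#'
#' @param t time since dithionite addition (s), vectorized
#' @param p a [KineticParams-class] object
#' @return normalized fluorescence
#' @examples
#' p <- kineticParams(alpha = 0, gamma = 2, liPF = 0.5, leak = 0)
#' fPF(c(0, log(2) / 2, 1e6), p)   # 1, 0.75, plateau 0.5
#' @export
fPF <- function(t, p) {
  stopifnot(is(p, "KineticParams"))
  .checkTime(t)
  p@liPF * exp(-p@leak * t) + (1 - p@liPF) * exp(-p@gamma * t)
}

#' Scramblase-containing vesicle fluorescence decay
#'
#' Closed-form solution of the three-state Markov scheme
#' Li <-> Lo -> L* started from the scramblase-generated equilibrium
#' (Li(0) = beta/(alpha+beta), Lo(0) = alpha/(alpha+beta)):
#' \deqn{F_{Scr}(t) = \frac{\alpha(\lambda_2+\gamma)(\lambda_1+\alpha+\beta)
#'   e^{\lambda_1 t} + \lambda_1 \beta (\lambda_2+\alpha+\beta+\gamma)
#'   e^{\lambda_2 t}}{D(\alpha+\beta)}}
#' with the eigenstructure of [eigenstructure()]. With a nonzero leak the
#' protected inner-leaflet component is additionally multiplied by
#' \code{exp(-leak * t)}. Near-coincident eigenvalues (discriminant below
#' 1e-12 relative) are handled by a first-order degenerate expansion.
#'
#' @inheritParams fPF
#' @return normalized fluorescence
#' @examples
#' p <- kineticParams(alpha = 0.001, gamma = 2, leak = 0)
#' fScr(c(0, 100), p)
#' @export
fScr <- function(t, p) {
  stopifnot(is(p, "KineticParams"))
  .checkTime(t)
  a <- p@alpha; b <- p@beta; g <- p@gamma
  if (a + b == 0)
    stop("alpha + beta = 0: no scrambling equilibrium is defined ",
         "(use fPF for protein-free kinetics)")
  if (g == 0) return(rep(1, length(t)))
  if (p@leak > 0 || a == 0 || b == 0) {
    cmp <- .scrComponents(t, a, b, g)
    return(cmp$li * exp(-p@leak * t) + cmp$lo)
  }
  es <- eigenstructure(p)
  if (es$degenerate) {
    cmp <- .scrComponents(t, a, b, g)
    return(cmp$li + cmp$lo)
  }
  l1 <- es$lambda1; l2 <- es$lambda2
  (a * (l2 + g) * (l1 + a + b) * exp(l1 * t) +
     l1 * b * (l2 + a + b + g) * exp(l2 * t)) / (es$D * (a + b))
}

#' Total fluorescence of the mixed liposome population
#'
#' \deqn{F_{tot}(t) = f_0 F_{PF}(t) + (1 - f_0) F_{Scr}(t)}
#' With zero leak the plateau is \code{f0 * liPF}. The degenerate case
#' alpha + beta = 0 reduces to pure protein-free kinetics.
#'
#' @inheritParams fPF
#' @return normalized fluorescence
#' @examples
#' p <- kineticParams(alpha = 0.001, gamma = 2, f0 = 0.55, liPF = 0.5, leak = 0)
#' fTot(c(0, 10, 5000), p)
#' @export
fTot <- function(t, p) {
  stopifnot(is(p, "KineticParams"))
  .checkTime(t)
  if (p@alpha + p@beta == 0) return(fPF(t, p))
  if (p@f0 == 1) return(fPF(t, p))
  p@f0 * fPF(t, p) + (1 - p@f0) * fScr(t, p)
}

#' Convert a scrambling rate constant to a per-protein lipid transport rate
#'
#' Multiplies the macroscopic rate constant alpha by the number of lipids
#' per scramblase-containing vesicle (default 1e5), giving the transport
#' rate in lipids per second per active protein: alpha = 0.2 /s corresponds
#' to 2e4 lipid/s and alpha = 0.001 /s to ~100 lipid/s.
#'
#' @param alpha scrambling rate constant (1/s), vectorized
#' @param nLip lipids per scramblase; default 1e5
#' @return transport rate (lipid/s)
#' @export
transportRate <- function(alpha, nLip = 1e5) {
  if (any(!is.finite(alpha)) || any(alpha < 0) || nLip < 0)
    stop("alpha and nLip must be nonnegative")
  alpha * nLip
}
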