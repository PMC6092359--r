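#' Fit a time-lagged independent component analysis model
#'
#' Mean-free features are used to estimate the instantaneous covariance
#' C(0) and the symmetrized time-lagged covariance
#' C(tau) = (C'(tau) + C'(tau)^T)/2, pooling lag pairs within each input
#' series (never across series boundaries). The generalized eigenproblem
#' C(tau) v = lambda C(0) v is solved through a Cholesky whitening of
#' C(0); a small ridge (1e-8 of the mean diagonal) stabilizes degenerate
#' feature sets, with a warning when C(0) is ill-conditioned. Eigenvalues
#' are the autocorrelations of the components at the chosen lag, sorted
#' descending.
#'
#' @param features a numeric matrix (frames x variables) or a list of such
#'   matrices (independent trajectories/replicates)
#' @param lag lag time in frames (default 10)
#' @param ridge relative ridge added to diag(C(0)); default 1e-8
#' @return a [TICAModel-class]
#' @examples
#' set.seed(1)
#' x <- as.numeric(stats::arima.sim(list(ar = 0.99), 2000))
#' f <- cbind(x, rnorm(2000))
#' fitTICA(f, lag = 5)
#' @export
fitTICA <- function(features, lag = 10, ridge = 1e-8) {
  if (is.matrix(features)) features <- list(features)
  lag <- as.integer(lag)
  if (lag < 1L) stop("lag must be a positive number of frames")
  if (any(vapply(features, nrow, 0L) <= lag))
    stop("every feature series must be longer than the lag")
  d <- ncol(features[[1]])
  if (any(vapply(features, ncol, 0L) != d))
    stop("all series must have the same number of variables")
  mu <- colMeans(do.call(rbind, features))
  C0 <- matrix(0, d, d); Ct <- matrix(0, d, d)
  n0 <- 0L; nt <- 0L
  for (x in features) {
    X <- sweep(x, 2, mu)
    C0 <- C0 + crossprod(X)
    n0 <- n0 + nrow(X)
    n <- nrow(X) - lag
    A <- X[seq_len(n), , drop = FALSE]
    B <- X[seq_len(n) + lag, , drop = FALSE]
    Ct <- Ct + crossprod(A, B)
    nt <- nt + n
  }
  C0 <- C0 / n0
  Ct <- (Ct + t(Ct)) / (2 * nt)
  rr <- ridge * mean(diag(C0))
  ev0 <- eigen(C0, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev0) < 1e-10 * max(ev0))
    warning("C(0) is nearly singular (degenerate features); ",
            "ridge-regularized solution")
  C0r <- C0 + diag(rr, d)
  R <- chol(C0r)
  W <- backsolve(R, diag(d))           # C0r^{-1} = W W'
  M <- t(W) %*% Ct %*% W
  M <- (M + t(M)) / 2
  eg <- eigen(M, symmetric = TRUE)
  V <- W %*% eg$vectors
  new("TICAModel", lag = lag, means = mu, evecs = V, evals = eg$values,
      ridge = rr)
}

#' Project features onto tICA components
#'
#' @param features matrix (frames x variables) in the same variable order
#'   used to fit the model
#' @param model a [TICAModel-class]
#' @param n number of components (default 2)
#' @return matrix frames x n of component scores
#' @export
projectTICA <- function(features, model, n = 2) {
  if (ncol(features) != length(model@means))
    stop("feature dimensionality does not match the model")
  n <- min(n, ncol(model@evecs))
  sweep(features, 2, model@means) %*% model@evecs[, seq_len(n), drop = FALSE]
}

#' Fraction of slow dynamics captured by the leading components
#'
#' Ratio of the eigenvalue mass of the top n components to the total mass
#' of the positive eigenvalues (negative eigenvalues carry no slow
#' autocorrelation and are excluded from the normalization).
#'
#' @param model a [TICAModel-class]
#' @param n number of leading components (default 2)
#' @return fraction in [0, 1]
#' @export
explainedFraction <- function(model, n = 2) {
  ev <- pmax(model@evals, 0)
  if (sum(ev) == 0) return(0)
  sum(ev[seq_len(min(n, length(ev)))]) / sum(ev)
}

# k-means++ initial centers: D^2-weighted sequential sampling
.kmeansPP <- function(x, k) {
  n <- nrow(x)
  centers <- matrix(NA_real_, k, ncol(x))
  centers[1, ] <- x[sample.int(n, 1), ]
  d2 <- rowSums(sweep(x, 2, centers[1, ])^2)
  for (j in seq_len(k - 1) + 1) {
    p <- d2 / sum(d2)
    centers[j, ] <- x[sample.int(n, 1, prob = p), ]
    d2 <- pmin(d2, rowSums(sweep(x, 2, centers[j, ])^2))
  }
  centers
}

#' Discretize tICA scores into k-means microstates
#'
#' k-means with k-means++ seeding (uniform random initial centers
#' essentially never cover many well-separated basins) and several
#' restarts; the partition with the lowest within-cluster sum of squares
#' is kept. Deterministic given the seed.
#'
#' @param scores matrix (frames x d) of tICA scores
#' @param k number of microstates (default 50)
#' @param seed RNG seed (clustering is deterministic given the seed)
#' @param nstart restarts (default 10)
#' @param iterMax maximum Lloyd iterations
#' @return a [MicrostateMap-class]
#' @export
kmeansMicrostates <- function(scores, k = 50, seed = 1, nstart = 10,
                              iterMax = 100) {
  scores <- as.matrix(scores)
  if (nrow(scores) < k)
    stop("need at least k = ", k, " points to form k microstates")
  set.seed(seed)
  km <- NULL
  for (s in seq_len(nstart)) {
    init <- .kmeansPP(scores, k)
    init <- init[!duplicated(init), , drop = FALSE]
    cand <- suppressWarnings(stats::kmeans(scores, centers = init,
                                           iter.max = iterMax))
    if (is.null(km) || cand$tot.withinss < km$tot.withinss) km <- cand
  }
  new("MicrostateMap", k = as.integer(nrow(km$centers)),
      centers = km$centers, labels = as.integer(km$cluster),
      sizes = as.integer(km$size))
}

#' Structural profiles of microstates
#'
#' Per-microstate distributions of frame-aligned structural quantities
#' (e.g. the z-distance to the R432 C-alpha, lipid tilt, T333-Y439
#' distance and TM3-TM6 opening). Histograms share common breaks per
#' metric and are normalized to unit mass.
#'
#' @param map a [MicrostateMap-class]
#' @param metrics data.frame of numeric columns, one row per frame,
#'   aligned with the frames used for clustering
#' @param nbreaks number of histogram bins (default 20)
#' @return a list with one element per metric; each is a list of
#'   \code{breaks} and a \code{density} matrix (k x bins, rows normalized
#'   to sum to 1; all-NA rows for empty states), plus a \code{summary}
#'   data.frame of per-state means
#' @export
microstateProfiles <- function(map, metrics, nbreaks = 20) {
  metrics <- as.data.frame(metrics)
  if (nrow(metrics) != length(map@labels))
    stop("metrics rows (", nrow(metrics), ") must match labeled frames (",
         length(map@labels), ")")
  out <- list()
  for (nm in names(metrics)) {
    v <- metrics[[nm]]
    breaks <- seq(min(v), max(v), length.out = nbreaks + 1)
    if (breaks[1] == breaks[nbreaks + 1])
      breaks <- breaks[1] + seq(-0.5, 0.5, length.out = nbreaks + 1)
    dens <- matrix(NA_real_, map@k, nbreaks)
    for (s in seq_len(map@k)) {
      vs <- v[map@labels == s]
      if (!length(vs)) next
      h <- graphics::hist(vs, breaks = breaks, plot = FALSE,
                          include.lowest = TRUE)
      dens[s, ] <- h$counts / sum(h$counts)
    }
    out[[nm]] <- list(breaks = breaks, density = dens)
  }
  means <- stats::aggregate(metrics, by = list(state = map@labels), mean)
  out$summary <- means
  out
}
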