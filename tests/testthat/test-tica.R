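test_that("tICA isolates a slow AR(1) coordinate from white noise", {
  set.seed(21)
  n <- 1e5; rho <- 0.99; lag <- 10
  slow <- as.numeric(stats::arima.sim(list(ar = rho), n,
                                      sd = sqrt(1 - rho^2)))
  f <- cbind(slow, rnorm(n), rnorm(n))
  mod <- fitTICA(f, lag = lag)
  v1 <- eigenvectors(mod)[, 1]
  cosine <- abs(v1[1]) / sqrt(sum(v1^2))
  expect_gt(cosine, 0.99)
  # leading eigenvalue approaches the AR(1) autocorrelation rho^lag
  expect_equal(eigenvalues(mod)[1], rho^lag, tolerance = 0.03)
  # the noise directions carry no slow weight
  expect_lt(max(abs(eigenvalues(mod)[-1])), 0.05)
  expect_gt(explainedFraction(mod, 1), 0.9)
})

test_that("white noise alone yields eigenvalues near zero", {
  set.seed(22)
  f <- matrix(rnorm(4e4), ncol = 4)
  mod <- fitTICA(f, lag = 10)
  expect_lt(max(abs(eigenvalues(mod))), 0.05)
})

test_that("degenerate feature sets are regularized with a warning", {
  set.seed(23)
  x <- as.numeric(stats::arima.sim(list(ar = 0.9), 5000))
  f <- cbind(x, x, rnorm(5000))          # duplicated column
  expect_warning(mod <- fitTICA(f, lag = 5), "singular")
  expect_true(all(is.finite(eigenvalues(mod))))
})

test_that("projections reproduce training scores and are C(0)-orthogonal", {
  set.seed(24)
  n <- 2e4
  f <- cbind(as.numeric(stats::arima.sim(list(ar = 0.95), n)),
             as.numeric(stats::arima.sim(list(ar = 0.5), n)),
             rnorm(n))
  mod <- fitTICA(f, lag = 10)
  s1 <- projectTICA(f, mod, n = 3)
  expect_identical(projectTICA(f, mod, n = 3), s1)   # bitwise repeatable
  # decorrelated at lag 0 in the C(0) metric (unit variance, zero cross)
  cv <- crossprod(sweep(s1, 2, colMeans(s1))) / nrow(s1)
  offdiag <- cv[upper.tri(cv)]
  expect_lt(max(abs(offdiag)), 1e-2)
  expect_error(projectTICA(f[, 1:2], mod), "dimensionality")
})

test_that("fit preconditions are checked", {
  expect_error(fitTICA(matrix(rnorm(10), ncol = 2), lag = 10), "longer")
  expect_error(fitTICA(matrix(rnorm(100), ncol = 2), lag = 0), "positive")
})

test_that("explained fraction follows the eigenvalue mass", {
  mk <- function(ev) new("TICAModel", lag = 1L, means = numeric(length(ev)),
                         evecs = diag(length(ev)), evals = ev, ridge = 0)
  expect_equal(explainedFraction(mk(c(0.9, 0, 0, 0)), 1), 1)
  expect_equal(explainedFraction(mk(rep(0.5, 8)), 2), 0.25)
  # negative eigenvalues are excluded from the normalization
  expect_equal(explainedFraction(mk(c(0.8, 0.2, -0.5)), 1), 0.8)
})

test_that("k-means microstates recover well-separated blobs", {
  set.seed(2)
  centers <- cbind(rep(1:10, 5) * 20, rep(1:5, each = 10) * 20)
  pts <- centers[rep(1:50, each = 100), ] +
    matrix(rnorm(10000, sd = 0.5), ncol = 2)
  truth <- rep(1:50, each = 100)
  mm <- kmeansMicrostates(pts, k = 50, seed = 3)
  expect_equal(mm@k, 50)
  skip_if_not_installed("mclust")
  expect_gt(mclust::adjustedRandIndex(stateLabels(mm), truth), 0.99)
  # determinism and k = 1 degenerate case
  mm2 <- kmeansMicrostates(pts, k = 50, seed = 3)
  expect_identical(stateLabels(mm), stateLabels(mm2))
  one <- kmeansMicrostates(pts, k = 1, seed = 1)
  expect_true(all(stateLabels(one) == 1L))
  expect_error(kmeansMicrostates(pts[1:10, ], k = 50), "at least k")
})

test_that("microstate profiles summarize aligned structural metrics", {
  set.seed(25)
  sc <- matrix(rnorm(400), ncol = 2)
  mm <- kmeansMicrostates(sc, k = 1, seed = 1)
  met <- data.frame(m1 = rnorm(200), m2 = runif(200))
  pr <- microstateProfiles(mm, met)
  # single state: profile equals the global distribution
  gh <- graphics::hist(met$m1, breaks = pr$m1$breaks, plot = FALSE,
                       include.lowest = TRUE)
  expect_equal(pr$m1$density[1, ], gh$counts / sum(gh$counts))
  expect_equal(sum(pr$m1$density[1, ]), 1)
  expect_error(microstateProfiles(mm, met[1:10, , drop = FALSE]),
               "must match")
})

test_that("the toy translocation orders microstates along the groove axis", {
  r <- renderToyTrajectory(demoTrajScript())
  tr <- r$trajectory
  ft <- ticaFeatures(tr, protomer = "A")
  # piecewise-constant gate features make C(0) near-singular by design
  mod <- suppressWarnings(fitTICA(ft, lag = 3))
  sc <- projectTICA(ft, mod, n = 2)
  mm <- kmeansMicrostates(sc, k = 8, seed = 1)
  # mean scripted lipid z per microstate orders consistently with the mean
  # tICA-1 score ranking
  z <- ft[, "zP_R432CA"]
  zBar <- tapply(z, stateLabels(mm), mean)
  sBar <- tapply(sc[, 1], stateLabels(mm), mean)
  rho <- abs(cor(rank(zBar), rank(sBar), method = "spearman"))
  expect_gt(rho, 0.9)
  # states made purely of open-central-gate frames sit at T333-Y439 > 3 A
  pr <- microstateProfiles(mm, data.frame(d333 = ft[, "dmin_T333_Y439"]))
  lbl <- stateLabels(mm)
  pureOpen <- setdiff(unique(lbl[41:60]), unique(lbl[1:40]))
  expect_gt(length(pureOpen), 0)
  expect_gt(min(pr$summary$d333[pr$summary$state %in% pureOpen]), 3)
})
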