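test_that("eigenstructure matches limiting cases and a numeric eigensolver", {
  # gamma = 0: discriminant collapses to (alpha+beta)^2
  es <- eigenstructure(kineticParams(alpha = 0.001, beta = 0.001, gamma = 0))
  expect_equal(es$lambda1, 0)
  expect_equal(es$lambda2, -0.002)
  # alpha = 0: sqrt((beta+gamma)^2)
  es <- eigenstructure(kineticParams(alpha = 0, beta = 0.5, gamma = 2))
  expect_equal(es$lambda1, 0)
  expect_equal(es$lambda2, -2.5)
  # generic case against R's eigen() on the rate matrix
  for (p in list(c(0.001, 0.001, 2), c(0.3, 0.1, 2), c(5, 4, 0.5))) {
    A <- matrix(c(-p[1], p[1], p[2], -p[2] - p[3]), 2, 2)
    ev <- sort(eigen(A, only.values = TRUE)$values, decreasing = TRUE)
    es <- eigenstructure(kineticParams(alpha = p[1], beta = p[2],
                                       gamma = p[3]))
    expect_equal(es$lambda1, ev[1], tolerance = 1e-12)
    expect_equal(es$lambda2, ev[2], tolerance = 1e-12)
  }
})

test_that("eigenvalues obey the Vieta relations", {
  set.seed(42)
  for (i in 1:100) {
    a <- 10^runif(1, -5, 1); b <- 10^runif(1, -5, 1)
    g <- 10^runif(1, -2, 1)
    es <- eigenstructure(kineticParams(alpha = a, beta = b, gamma = g))
    expect_equal(es$lambda1 * es$lambda2, a * g, tolerance = 1e-10)
    expect_equal(es$lambda1 + es$lambda2, -(a + b + g), tolerance = 1e-10)
    expect_lte(es$lambda2, es$lambda1)
    expect_lte(es$lambda1, 1e-15)
  }
})

test_that("protein-free decay has the right normalization, half-life and plateau", {
  p <- kineticParams(alpha = 0, gamma = 2, f0 = 1, liPF = 0.5, leak = 0)
  expect_equal(fPF(0, p), 1)
  expect_equal(fPF(1e9, p), 0.5)              # plateau = Li^PF
  expect_equal(fPF(log(2) / 2, p), 0.75)      # one outer-leaflet half-life
  expect_error(fPF(-1, p), "nonnegative")
})

test_that("scramblase decay conserves probability without bleaching", {
  set.seed(7)
  for (i in 1:100) {
    p <- kineticParams(alpha = 10^runif(1, -5, 1), beta = 10^runif(1, -5, 1),
                       gamma = 0, f0 = runif(1), liPF = runif(1), leak = 0)
    tt <- 10^seq(-2, 4, length.out = 13)
    expect_equal(fScr(tt, p), rep(1, length(tt)))
    expect_equal(fTot(tt, p), rep(1, length(tt)))
  }
})

test_that("closed form agrees with adaptive ODE integration to 1e-8 relative", {
  skip_if_not_installed("deSolve")
  grid <- expand.grid(a = 10^seq(-4, 0.5, length.out = 5),
                      b = 10^seq(-4, 0.5, length.out = 5),
                      g = 10^seq(-1, 1, length.out = 4))
  for (i in seq_len(nrow(grid))) {
    a <- grid$a[i]; b <- grid$b[i]; g <- grid$g[i]
    tmax <- 10 / max(a, g)
    tt <- seq(0, tmax, length.out = 7)
    ours <- fScr(tt, kineticParams(alpha = a, beta = b, gamma = g, leak = 0))
    ode <- oracle_ode_fscr(tt, a, b, g)
    expect_lt(max(abs(ours - ode) / (abs(ode) + 1e-12)), 1e-8)
  }
  expect_equal(fScr(0, kineticParams(alpha = 0.1, beta = 0.1, gamma = 2,
                                     leak = 0)), 1)
})

test_that("fast dithionite reduces the scramblase decay to the alpha branch", {
  # gamma >> alpha + beta: F -> (beta/(alpha+beta)) exp(-alpha t)
  a <- 0.002; b <- 0.001
  g <- 1e4 * (a + b)
  p <- kineticParams(alpha = a, beta = b, gamma = g, leak = 0)
  tt <- seq(1 / g * 50, 3 / a, length.out = 20)  # past the fast transient
  lim <- (b / (a + b)) * exp(-a * tt)
  expect_lt(max(abs(fScr(tt, p) - lim) / lim), 0.01)
})

test_that("the near-degenerate eigenvalue branch stays finite and accurate", {
  skip_if_not_installed("deSolve")
  # beta ~ 0, alpha ~ gamma puts the discriminant at machine-epsilon scale
  a <- 1; g <- 1; b <- 1e-9
  p <- kineticParams(alpha = a, beta = b, gamma = g, leak = 0)
  tt <- seq(0, 10, length.out = 21)
  expect_true(all(is.finite(fScr(tt, p))))
  ode <- oracle_ode_fscr(tt, a, b, g)
  expect_lt(max(abs(fScr(tt, p) - ode) / (abs(ode) + 1e-12)), 1e-6)
})

test_that("total fluorescence mixes the populations and is monotone", {
  p <- pWTslow()
  expect_equal(fTot(1e7, p), 0.55 * 0.5, tolerance = 1e-6)  # f0 * Li^PF
  # f0 = 1 reduces to protein-free
  p1 <- kineticParams(alpha = 0.01, gamma = 2, f0 = 1, liPF = 0.4, leak = 0)
  tt <- seq(0, 100, by = 0.5)
  expect_equal(fTot(tt, p1), fPF(tt, p1))
  # monotone non-increasing on dense grids for random parameters
  set.seed(11)
  for (i in 1:25) {
    p <- kineticParams(alpha = 10^runif(1, -5, 0), beta = 10^runif(1, -5, 0),
                       gamma = 10^runif(1, -1, 1), f0 = runif(1),
                       liPF = runif(1), leak = runif(1, 0, 1e-4))
    tt <- seq(0, 5000, length.out = 2000)
    expect_true(all(diff(fTot(tt, p)) <= 1e-12))
  }
})

test_that("degenerate alpha + beta = 0 falls back to protein-free kinetics", {
  p <- kineticParams(alpha = 0, beta = 0, gamma = 2, f0 = 0.5, liPF = 0.5,
                     leak = 0)
  expect_error(fScr(1, p), "alpha \\+ beta")
  expect_equal(fTot(c(0, 1, 100), p), fPF(c(0, 1, 100), p))
})

test_that("mixture oracle: fTot equals the weighted ODE solution", {
  skip_if_not_installed("deSolve")
  p <- kineticParams(alpha = 0.001, beta = 0.001, gamma = 2, f0 = 0.55,
                     liPF = 0.5, leak = 0)
  tt <- c(0, 5, 50, 500, 3000)
  expected <- 0.55 * (0.5 + 0.5 * exp(-2 * tt)) +
    0.45 * oracle_ode_fscr(tt, 0.001, 0.001, 2)
  expect_equal(fTot(tt, p), expected, tolerance = 1e-8)
})

test_that("transport rate conversion uses 1e5 lipids per scramblase", {
  expect_equal(transportRate(0.2), 2e4)
  expect_equal(transportRate(0.001), 100)
  expect_equal(transportRate(0), 0)
  expect_error(transportRate(-1), "nonnegative")
})

test_that("gamma can be derived from the second-order dithionite rate", {
  expect_equal(dithioniteGamma(0.05, 40), 2)
  expect_equal(gammaRate(kineticParams(alpha = 0, gamma = NULL,
                                       secondOrderRate = 0.05)), 2)
  expect_error(dithioniteGamma(-1, 40), "positive")
})

test_that("parameter validation rejects out-of-range values", {
  expect_error(kineticParams(alpha = -1, gamma = 2), "alpha")
  expect_error(kineticParams(alpha = 0, gamma = 2, f0 = 1.5), "f0")
  expect_error(kineticParams(alpha = 0, gamma = 2, liPF = -0.1), "liPF")
})
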