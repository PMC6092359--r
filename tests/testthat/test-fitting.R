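test_that("normalizeTrace scales by the pre-addition mean and rezeroes time", {
  tt <- seq(0, 430, by = 1)
  f <- ifelse(tt < 30, 1000, 1000 * (0.5 + 0.5 * exp(-2 * (tt - 30))))
  tr <- normalizeTrace(tt, f, additionTime = 30)
  expect_s4_class(tr, "FluorescenceTrace")
  expect_equal(traceTime(tr)[1], 0)
  expect_equal(fluorescence(tr)[1], 1)
  expect_equal(min(fluorescence(tr)), 0.5, tolerance = 1e-6)
  expect_error(normalizeTrace(tt, f, additionTime = 1000), "inside")
  expect_error(normalizeTrace(tt, f, additionTime = 2), "pre-addition")
})

test_that("a simulated raw trace round-trips through normalization", {
  p <- pWTslow()
  raw <- simulateTrace(p, duration = 200, noiseSD = 0, seed = 1, raw = TRUE)
  tr <- normalizeTrace(raw$time_s, raw$fluorescence, additionTime = 30)
  expect_equal(fluorescence(tr), fTot(traceTime(tr), p), tolerance = 1e-12)
})

test_that("protein-free fits recover gamma, Li^PF and the leak", {
  # noise-free: exact to optimizer tolerance
  p <- kineticParams(alpha = 0, gamma = 2, f0 = 1, liPF = 0.5, leak = 0)
  tr <- simulateTrace(p, duration = 300, noiseSD = 0, seed = 1,
                      construct = "protein-free")
  fit <- fitProteinFree(tr)
  expect_equal(fitMode(fit), "protein_free")
  expect_equal(gammaRate(fit), 2, tolerance = 1e-6)
  expect_equal(innerFraction(params(fit)), 0.5, tolerance = 1e-6)
  expect_equal(alphaRate(fit), 0)       # fixed at zero
  expect_equal(emptyFraction(params(fit)), 1)
  # ~50% plateau loss is reflected in the fitted Li^PF
  p2 <- kineticParams(alpha = 0, gamma = 2, f0 = 1, liPF = 0.5,
                      leak = 5.4e-5)
  tr2 <- simulateTrace(p2, duration = 4000, noiseSD = 0.003, seed = 4,
                       construct = "protein-free")
  fit2 <- fitProteinFree(tr2)
  expect_equal(innerFraction(params(fit2)), 0.5, tolerance = 0.02)
  expect_equal(leakRate(params(fit2)), 5.4e-5, tolerance = 0.3)
})

test_that("leak recovery from noisy protein-free traces stays within 30%", {
  errs <- vapply(1:40, function(s) {
    p <- kineticParams(alpha = 0, gamma = 2, f0 = 1, liPF = 0.5,
                       leak = 5.4e-5)
    tr <- simulateTrace(p, duration = 4000, noiseSD = 0.003, seed = 100 + s,
                        construct = "protein-free")
    leakRate(params(fitProteinFree(tr))) / 5.4e-5 - 1
  }, 0)
  expect_lt(abs(median(errs)), 0.3)
  expect_gt(mean(abs(errs) < 0.3), 0.9)
})

test_that("the full fit is self-consistent on noise-free data", {
  p <- kineticParams(alpha = 0.01, beta = 0.01, gamma = 2, f0 = 0.55,
                     liPF = 0.5, leak = 0)
  tr <- simulateTrace(p, duration = 400, noiseSD = 0, seed = 1)
  fit <- fitFull(tr, liPF = 0.5, f0 = 0.55, gamma = 2, leak = 0)
  expect_equal(alphaRate(fit), 0.01, tolerance = 1e-5)
  expect_equal(betaRate(fit), 0.01, tolerance = 1e-5)
  expect_true(fit@converged)
  # fixed parameters are returned unchanged, exactly
  expect_identical(emptyFraction(params(fit)), 0.55)
  expect_identical(innerFraction(params(fit)), 0.5)
  expect_identical(gammaRate(fit), 2)
  # asymmetric truth, both rates free
  p2 <- kineticParams(alpha = 0.02, beta = 0.005, gamma = 2, f0 = 0.55,
                      liPF = 0.5, leak = 0)
  tr2 <- simulateTrace(p2, duration = 400, noiseSD = 0, seed = 1)
  fit2 <- fitFull(tr2, liPF = 0.5, f0 = 0.55, gamma = 2, leak = 0)
  expect_equal(alphaRate(fit2), 0.02, tolerance = 1e-4)
  expect_equal(betaRate(fit2), 0.005, tolerance = 1e-4)
})

test_that("f0 is fitted for WT(+Ca) traces and recovered", {
  p <- kineticParams(alpha = 0.01, beta = 0.01, gamma = 2, f0 = 0.4,
                     liPF = 0.5, leak = 0)
  tr <- simulateTrace(p, duration = 400, noiseSD = 0, seed = 1)
  fit <- fitFull(tr, liPF = 0.5, f0 = NULL, gamma = 2, leak = 0)
  expect_equal(emptyFraction(params(fit)), 0.4, tolerance = 1e-4)
  expect_true("f0" %in% fit@free)
})

test_that("slow-regime recovery: alpha = 0.001 within 20% across seeds", {
  hits <- vapply(1:40, function(s) {
    p <- kineticParams(alpha = 0.001, beta = 0.001, gamma = 2, f0 = 0.55,
                       liPF = 0.5, leak = 5.4e-5)
    tr <- simulateTrace(p, duration = 4000, noiseSD = 0.003, seed = 200 + s,
                        ca = FALSE)
    abs(alphaRate(fitFull(tr, liPF = 0.5, f0 = 0.55, gamma = 2,
                          leak = 5.4e-5)) / 0.001 - 1) < 0.2
  }, NA)
  expect_gt(mean(hits), 0.9)
})

test_that("rate-limited detection is flagged and reported as a bound", {
  fitLike <- function(alphaHat) {
    p <- kineticParams(alpha = alphaHat, beta = alphaHat, gamma = 2,
                       f0 = 0.55, liPF = 0.5, leak = 0)
    new("FitResult", params = p, free = c("alpha", "beta"), mode = "full",
        lowerBoundOnly = FALSE, bound = NA_real_, residualRMS = 0,
        converged = TRUE, stderr = c(alpha = 0))
  }
  r <- resolveRateLimited(fitLike(5), gamma = 2)
  expect_true(isLowerBound(r))
  expect_gte(r@bound, 0.2)
  expect_false(isLowerBound(resolveRateLimited(fitLike(0.001), gamma = 2)))
  # identifiability boundary: kappa * gamma
  expect_true(isLowerBound(resolveRateLimited(fitLike(0.21), gamma = 2)))
  expect_false(isLowerBound(resolveRateLimited(fitLike(0.19), gamma = 2)))
  # a dithionite-limited trace gets flagged end to end
  p <- kineticParams(alpha = 2, beta = 2, gamma = 2, f0 = 0.55, liPF = 0.5,
                     leak = 0)
  tr <- simulateTrace(p, duration = 400, noiseSD = 0.003, seed = 5)
  fit <- fitScrambling(tr, liPF = 0.5, f0 = 0.55, gamma = 2, leak = 0)
  expect_true(isLowerBound(fit))
})

test_that("the linear regime converts tail slopes to rates", {
  # pure leak: recovered alpha is zero (to numerical tolerance)
  pz <- kineticParams(alpha = 1e-9, beta = 1e-9, gamma = 2, f0 = 0.55,
                      liPF = 0.5, leak = 5.4e-5)
  trz <- simulateTrace(pz, duration = 4000, noiseSD = 0, seed = 1)
  fitz <- fitLinear(trz, leak = 5.4e-5, gamma = 2, f0 = 0.55, liPF = 0.5)
  expect_lt(alphaRate(fitz), 1e-6)
  # known slow rate, noise-free
  p <- kineticParams(alpha = 5e-5, beta = 5e-5, gamma = 2, f0 = 0.55,
                     liPF = 0.5, leak = 5.4e-5)
  tr <- simulateTrace(p, duration = 4000, noiseSD = 0, seed = 1)
  fit <- fitLinear(tr, leak = 5.4e-5, gamma = 2, f0 = 0.55, liPF = 0.5)
  expect_equal(alphaRate(fit), 5e-5, tolerance = 0.05)
  expect_equal(fitMode(fit), "linear")
  # noisy Monte Carlo: within 50% across seeds
  errs <- vapply(1:30, function(s) {
    trn <- simulateTrace(p, duration = 4000, noiseSD = 0.003, seed = 300 + s)
    alphaRate(fitLinear(trn, leak = 5.4e-5, gamma = 2, f0 = 0.55,
                        liPF = 0.5)) / 5e-5 - 1
  }, 0)
  expect_gt(mean(abs(errs) < 0.5), 0.9)
  # refuses a tail that is too short
  short <- simulateTrace(p, duration = 60, noiseSD = 0, seed = 1)
  expect_error(fitLinear(short, leak = 5.4e-5, gamma = 2, f0 = 0.55,
                         liPF = 0.5), "100 samples")
})

test_that("auto mode selects the right protocol across the rate grid", {
  # median absolute relative error < 25% over a log grid of alpha
  alphas <- 10^seq(log10(1e-5), log10(0.05), length.out = 9)
  errs <- vapply(seq_along(alphas), function(i) {
    a <- alphas[i]
    p <- kineticParams(alpha = a, beta = a, gamma = 2, f0 = 0.55,
                       liPF = 0.5, leak = 5.4e-5)
    tr <- simulateTrace(p, duration = 4000, noiseSD = 0.003, seed = 400 + i)
    fit <- fitScrambling(tr, liPF = 0.5, f0 = 0.55, gamma = 2, leak = 5.4e-5)
    abs(alphaRate(fit) / a - 1)
  }, 0)
  expect_lt(median(errs), 0.25)
})

test_that("impact classification applies the 10/100-fold thresholds", {
  expect_equal(classifyImpact(1, 0.5)$label, "low")        # fold 2
  expect_equal(classifyImpact(1, 0.02)$label, "medium")    # fold 50
  expect_equal(classifyImpact(1, 1 / 300)$label, "high")   # fold 300
  expect_equal(classifyImpact(0.001, 0.002)$label, "enhanced")  # fold 0.5-
  expect_equal(classifyImpact(1, 1, mutantLowerBound = TRUE)$label, "low")
  expect_error(classifyImpact(0, 1), "positive")
  # scale invariance
  set.seed(3)
  for (i in 1:20) {
    wt <- 10^runif(1, -4, 0); mut <- 10^runif(1, -6, 0)
    c1 <- classifyImpact(wt, mut)
    c2 <- classifyImpact(wt * 37.5, mut * 37.5)
    expect_identical(c1$label, c2$label)
    expect_equal(c1$foldReduction, c2$foldReduction)
  }
})
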