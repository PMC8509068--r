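test_that("ScatterCurve validity enforces the curve invariants", {
  expect_s4_class(ScatterCurve(c(0.01, 0.02), c(1, 2)), "ScatterCurve")
  expect_error(ScatterCurve(c(0.02, 0.01), c(1, 2)), "increasing")
  expect_error(ScatterCurve(c(-0.01, 0.02), c(1, 2)), "> 0")
  expect_error(ScatterCurve(c(0.01, 0.02), c(1, Inf)), "finite")
  expect_error(ScatterCurve(c(0.01, 0.02), c(1, 2), sigma = c(1, -1)),
               "sigma")
})

test_that("Guinier and power-law forward models evaluate their closed forms", {
  # forward-intensity identity at q -> 0
  expect_equal(evalModel(GuinierParams(1, 98), 0), 1)
  # direct evaluation of the exponential
  expect_equal(evalModel(GuinierParams(1, 98), 0.01),
               exp(-(0.01^2 * 98^2) / 3), tolerance = 1e-12)
  expect_equal(evalModel(GuinierParams(1, 98), 0.01), 0.7260, tolerance = 1e-4)
  # zero exponent is a constant
  expect_equal(evalModel(PowerLawParams(2.5, 0), c(0.01, 0.1, 0.5)),
               rep(2.5, 3))
  expect_equal(evalModel(PowerLawParams(1, 1.3), 0.1), 0.1^-1.3)
  # sums add linearly
  q <- defaultQGrid(50)
  m1 <- GuinierParams(1, 98); m2 <- PowerLawParams(0.01, 1.3)
  expect_equal(evalModel(list(m1, m2), q),
               evalModel(m1, q) + evalModel(m2, q))
  expect_error(evalModel(PowerLawParams(1, 1), c(-0.1, 0.1)), "> 0")
})

test_that("broad-peak profile attains its maximum at qPeak", {
  bp <- BroadPeakParams(qPeak = 0.058, width = 0.015, peakAmplitude = 0.1,
                        background = 1e-4, tailExponent = 1.3,
                        tailAmplitude = 1e-4)
  q <- defaultQGrid(2000, 5e-3, 0.5)
  I <- evalModel(bp, q)
  expect_equal(q[which.max(I)], 0.058, tolerance = 2e-3)
  expect_true(all(I > 0))
})

test_that("core-shell model reduces to the homogeneous sphere when the shell is contrast-matched", {
  q <- defaultQGrid(120)
  cs <- CoreShellParams(coreRadius = 1000, shellThickness = 30,
                        sldCore = 11.8, sldShell = 9.47, sldSolvent = 9.47,
                        polydispersity = 0, scale = 1e-3)
  # analytic homogeneous sphere with radius = coreRadius,
  # contrast = sldCore - sldSolvent
  f <- function(x) 3 * (sin(x) - x * cos(x)) / x^3
  V <- 4 / 3 * pi * 1000^3
  hom <- 1e7 * 1e-3 * (V * (11.8 - 9.47) * 1e-6 * f(q * 1000))^2 / V
  expect_equal(evalCoreShell(cs, q), hom, tolerance = 1e-10)
})

test_that("homogeneous-sphere limit places the first intensity minimum at qR = 4.493", {
  p <- CoreShellParams(coreRadius = 1000, shellThickness = 0, sldCore = 11.8,
                       sldShell = 9.47, sldSolvent = 9.47, scale = 1e-3)
  q <- seq(3e-3, 6e-3, by = 1e-6)
  I <- evalCoreShell(p, q)
  expect_equal(q[which.min(I)] * 1000, 4.493, tolerance = 1e-3)
})

test_that("core-shell model agrees with the brute-force quadrature oracle", {
  q <- defaultQGrid(60)
  withr::with_seed(42, {
    for (i in 1:20) {
      p <- CoreShellParams(coreRadius = runif(1, 300, 1500),
                           shellThickness = runif(1, 5, 50),
                           sldCore = runif(1, 10, 14),
                           sldShell = runif(1, 14, 18), sldSolvent = 9.47,
                           polydispersity = runif(1, 0.02, 0.3),
                           scale = 10^runif(1, -4, -2),
                           background = runif(1, 0, 1e-3))
      expect_lt(max(abs(evalCoreShell(p, q) / coreShellOracle(p, q) - 1)),
                1e-3)
    }
  })
})

test_that("q -> 0 core-shell limit matches the quadrature oracle at q = 1e-6", {
  p <- referenceNp(polydispersity = 0.1, scale = 1e-3)
  got <- evalCoreShell(p, 1e-6)
  expect_equal(got, coreShellOracle(p, 1e-6), tolerance = 1e-6)
  expect_true(is.finite(got) && got > 0)
})

test_that("core-shell guards reject invalid inputs", {
  expect_error(CoreShellParams(1000, 15, 11.8, 16, polydispersity = 1),
               "polydispersity")
  expect_error(evalCoreShell(referenceNp(), numeric(0)), "empty")
})

test_that("Bragg positions reproduce the drug-lattice reflections", {
  pos <- braggPositions(dexLattice(),
                        hkl = rbind(c(0, 1, 1), c(0, 0, 2), c(1, 0, 0)))
  # printed positions of the two low-q reflections round to 0.47 and 0.54
  expect_equal(round(pos$q[1], 2), 0.47)
  expect_equal(round(pos$q[2], 2), 0.54)
  expect_equal(pos$q[1], 2 * pi * sqrt(16.16^-2 + 23.20^-2), tolerance = 1e-12)
  expect_equal(pos$q[3], 2 * pi / 10.36, tolerance = 1e-12)
})

test_that("Bragg positions are symmetric under sign flips and monotone in the cell edges", {
  lat <- dexLattice()
  expect_equal(braggPositions(lat, hkl = c(0, -1, 1))$q,
               braggPositions(lat, hkl = c(0, 1, 1))$q)
  expect_equal(braggPositions(lat, hkl = c(-2, 1, -3))$q,
               braggPositions(lat, hkl = c(2, 1, 3))$q)
  withr::with_seed(7, {
    for (i in 1:10) {
      hkl <- sample(0:3, 3, replace = TRUE)
      if (all(hkl == 0)) hkl[1] <- 1
      q0 <- braggPositions(lat, hkl = hkl)$q
      bigger <- Lattice(lat@a * 1.1, lat@b * 1.2, lat@c * 1.3)
      expect_lt(braggPositions(bigger, hkl = hkl)$q, q0)
    }
  })
})

test_that("two-theta conversion requires a wavelength and a reachable angle", {
  pos <- braggPositions(dexLattice(), hkl = c(0, 1, 1), wavelength = 1.54)
  expect_equal(pos$twoTheta,
               2 * asin(pos$q * 1.54 / (4 * pi)) * 180 / pi)
  expect_null(braggPositions(dexLattice(), hkl = c(0, 1, 1))$twoTheta)
  expect_error(braggPositions(dexLattice(), hkl = c(0, 1, 1),
                              wavelength = 60), "exceeds")
  expect_error(braggPositions(dexLattice(), hkl = c(0, 0, 0)), "reflection")
})

test_that("model evaluations stay strictly positive with non-negative background", {
  q <- defaultQGrid(100)
  models <- list(PowerLawParams(0.01, 1.5),
                 BroadPeakParams(0.03, 0.008, 0.1, background = 0,
                                 tailExponent = 1.3, tailAmplitude = 1e-4),
                 GuinierPowerLawParams(0.1, 98, 1.5),
                 referenceNp(polydispersity = 0.1, scale = 1e-3))
  for (m in models) expect_true(all(evalModel(m, q) > 0))
  # the pure Guinier exponential within its regime of use
  expect_true(all(evalModel(GuinierParams(0.5, 70),
                            defaultQGrid(100, 1e-3, 0.05)) > 0))
})
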