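test_that("core-shell fit recovers random noise-free truths within 1%", {
  q <- defaultQGrid(150)
  truths <- withr::with_seed(11, lapply(1:5, function(i)
    CoreShellParams(coreRadius = runif(1, 500, 1500),
                    shellThickness = runif(1, 10, 50),
                    sldCore = 11.8, sldShell = 16, sldSolvent = 9.47,
                    polydispersity = runif(1, 0.05, 0.15),
                    scale = 10^runif(1, -3.5, -2),
                    background = 10^runif(1, -5, -4))))
  for (i in seq_along(truths)) {
    truth <- truths[[i]]
    cur <- ScatterCurve(q, evalCoreShell(truth, q))
    init <- truth
    jf <- jitterFactors(4, 0.1, 500 + i)
    init@coreRadius <- truth@coreRadius * jf[1]
    init@shellThickness <- truth@shellThickness * jf[2]
    init@polydispersity <- truth@polydispersity * jf[3]
    init@scale <- truth@scale * jf[4]
    fit <- fitCoreShell(cur, init = init, multiStart = 3, maxIter = 60)
    p <- coreShellParams(fit)
    expect_equal(p@coreRadius, truth@coreRadius, tolerance = 0.01)
    expect_equal(p@shellThickness, truth@shellThickness, tolerance = 0.01)
    expect_equal(p@polydispersity, truth@polydispersity, tolerance = 0.01)
    expect_true(fit@converged)
  }
})

test_that("core-shell fit tolerates 1% noise within 10%", {
  q <- defaultQGrid(150)
  truth <- referenceNp(polydispersity = 0.1, scale = 3e-3,
                       background = 1e-4)
  for (s in 1:2) {
    I <- evalCoreShell(truth, q)
    noisy <- withr::with_seed(600 + s,
                              I * (1 + 0.01 * rnorm(length(I))))
    cur <- ScatterCurve(q, pmax(noisy, 1e-12), sigma = 0.01 * I)
    init <- truth
    init@coreRadius <- 1150; init@shellThickness <- 20
    fit <- fitCoreShell(cur, init = init, multiStart = 3, maxIter = 60)
    p <- coreShellParams(fit)
    expect_equal(p@coreRadius, truth@coreRadius, tolerance = 0.1)
    expect_equal(p@shellThickness, truth@shellThickness, tolerance = 0.1)
  }
})

test_that("starting at the truth on noise-free data is a fixed point", {
  q <- defaultQGrid(120)
  truth <- referenceNp(polydispersity = 0.1, scale = 3e-3)
  cur <- ScatterCurve(q, evalCoreShell(truth, q))
  fit <- fitCoreShell(cur, init = truth, multiStart = 1, maxIter = 40)
  expect_lt(fit@chisq, 1e-16)
  expect_equal(coreShellParams(fit)@coreRadius, 1000, tolerance = 1e-6)
})

test_that("fit result is invariant to intensity rescaling up to the scale parameter", {
  q <- defaultQGrid(120)
  truth <- referenceNp(polydispersity = 0.08, scale = 1e-3)
  cur <- ScatterCurve(q, evalCoreShell(truth, q))
  cur10 <- ScatterCurve(q, 10 * intensityValues(cur))
  init <- truth; init@coreRadius <- 1100
  f1 <- fitCoreShell(cur, init = init, multiStart = 2, maxIter = 60,
                     free = c("coreRadius", "shellThickness", "scale"))
  f2 <- fitCoreShell(cur10, init = init, multiStart = 2, maxIter = 60,
                     free = c("coreRadius", "shellThickness", "scale"))
  expect_equal(coreShellParams(f2)@coreRadius,
               coreShellParams(f1)@coreRadius, tolerance = 1e-4)
  expect_equal(coreShellParams(f2)@scale / coreShellParams(f1)@scale, 10,
               tolerance = 1e-3)
})

test_that("shared-shape fitting ties curves together with per-curve scales", {
  q <- defaultQGrid(120)
  truth <- referenceNp(polydispersity = 0.1, scale = 1e-3)
  t2 <- truth; t2@scale <- 4e-3
  curves <- list(ScatterCurve(q, evalCoreShell(truth, q)),
                 ScatterCurve(q, evalCoreShell(t2, q)))
  init <- truth; init@coreRadius <- 1100
  fit <- fitCoreShell(curves, init = init, sharedShape = TRUE,
                      multiStart = 2, maxIter = 60)
  expect_equal(coreShellParams(fit)@coreRadius, 1000, tolerance = 0.01)
  expect_equal(fit@scales[2] / fit@scales[1], 4, tolerance = 0.01)
})

test_that("zero-contrast initialization is rejected", {
  flat <- CoreShellParams(1000, 15, 9.47, 9.47, 9.47)
  cur <- ScatterCurve(defaultQGrid(50), rep(1, 50))
  expect_error(fitCoreShell(cur, init = flat), "zero contrast")
})

test_that("synthetic diffraction peaks are detected and indexed", {
  pat <- makeWaxsPattern(noise = NoiseModel(level = 0.01, seed = 2))
  rep <- suppressWarnings(analyzeWaxs(pat$curve))
  expect_true(rep@crystalline)
  expect_equal(nrow(rep@assignments), 3)
  expect_equal(rep@assignments[, c("h", "k", "l")],
               as.data.frame(pat$groundTruth$params$hkl),
               ignore_attr = TRUE)
})

test_that("the two low-q reflections of the drug lattice index as (0,1,1) and (0,0,2)", {
  # narrow peaks at the printed positions over a smooth decay
  q <- seq(0.3, 0.7, length.out = 600)
  I <- 0.01 * q^-1.3 +
    0.05 * exp(-(q - 0.4739)^2 / (2 * 0.004^2)) +
    0.03 * exp(-(q - 0.5417)^2 / (2 * 0.004^2))
  rep <- analyzeWaxs(ScatterCurve(q, I), matchTolerance = 0.01)
  expect_equal(nrow(rep@assignments), 2)
  expect_equal(rep@assignments$h, c(0, 0))
  expect_equal(rep@assignments$k, c(1, 0))
  expect_equal(rep@assignments$l, c(1, 2))
})

test_that("assignments are stable under small jitter of the peak positions", {
  for (dq in c(-0.002, 0, 0.002)) {
    q <- seq(0.3, 0.7, length.out = 600)
    I <- 0.01 * q^-1.3 +
      0.05 * exp(-(q - 0.4739 - dq)^2 / (2 * 0.004^2))
    rep <- analyzeWaxs(ScatterCurve(q, I), matchTolerance = 0.01)
    expect_equal(rep@assignments[1, c("h", "k", "l")],
                 data.frame(h = 0, k = 1, l = 1), ignore_attr = TRUE)
  }
})

test_that("smooth broad-peak spectra are reported as non-crystalline", {
  dispersion <- makeHyaWaterSeries(5, noise = NoiseModel(level = 0.01,
                                                         seed = 8))
  rep <- analyzeWaxs(dispersion$curves[[1]])
  expect_false(rep@crystalline)
  expect_equal(nrow(rep@assignments), 0)
})

test_that("peak intensity scales linearly with concentration in a series", {
  concs <- c(1.4, 2.8, 5.6, 11.2)
  curves <- lapply(concs, function(cc)
    makeWaxsPattern(concentration = cc, noise = noNoise())$curve)
  rep <- suppressWarnings(
    analyzeWaxs(curves[[4]],
                concentrationSeries = list(curves = curves,
                                           concentrations = concs)))
  expect_gt(nrow(rep@concentrationSlopes), 0)
  expect_true(all(rep@concentrationSlopes$r2 > 1 - 1e-6))
  expect_true(all(rep@concentrationSlopes$slope > 0))
})
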