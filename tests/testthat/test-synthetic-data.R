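test_that("salt-free series obeys the sqrt(c) laws and the concentration ladder ratios", {
  cs <- c(1.4, 2.8, 5.6, 11.2)
  K <- 2 * pi / 270 / sqrt(1.4)   # places the 1.4 mg/mL peak at xi = 270 A
  ser <- makeHyaWaterSeries(cs, K = K, noise = noNoise())
  gt <- ser$groundTruth$params
  # peak positions in ratio 1 : sqrt(2) : 2 : sqrt(8)
  expect_equal(gt$qPeak / gt$qPeak[1], sqrt(cs / cs[1]), tolerance = 1e-12)
  expect_equal(gt$xi[1], 270, tolerance = 1e-12)
  expect_equal(gt$IPeak / gt$IPeak[1], sqrt(cs / cs[1]), tolerance = 1e-12)
  # noise-free curves equal the forward model exactly: peak intensity check
  for (i in seq_along(cs)) {
    cu <- ser$curves[[i]]
    expect_equal(max(intensityValues(cu)[qValues(cu) > 0.01]),
                 gt$IPeak[i], tolerance = 1e-3)
  }
})

test_that("generators are bit-identical under the same seed and exact when noise-free", {
  n1 <- makeHyaWaterSeries(5.6, noise = NoiseModel(seed = 3))
  n2 <- makeHyaWaterSeries(5.6, noise = NoiseModel(seed = 3))
  expect_identical(intensityValues(n1$curves[[1]]),
                   intensityValues(n2$curves[[1]]))
  n3 <- makeHyaWaterSeries(5.6, noise = NoiseModel(seed = 4))
  expect_false(identical(intensityValues(n1$curves[[1]]),
                         intensityValues(n3$curves[[1]])))
  t1 <- makeDlsTrace(300, noise = NoiseModel(seed = 5))
  t2 <- makeDlsTrace(300, noise = NoiseModel(seed = 5))
  expect_identical(g2Values(t1$trace), g2Values(t2$trace))
  # noise = none has no sigma and equals the model
  nf <- makeHyaWaterSeries(5.6, noise = noNoise())
  expect_length(sigmaValues(nf$curves[[1]]), 0)
})

test_that("mixture generator conserves the polymer mass split", {
  np <- referenceNp()
  for (b in c(0, 0.25, 0.6, 1)) {
    mix <- makeNpMixture(np, totalConc = 20, boundFraction = b,
                         noise = noNoise())
    p <- mix$groundTruth$params
    expect_equal(p$freeConcentration + p$boundConcentration,
                 p$hyaMassFraction * p$totalConc, tolerance = 1e-12)
  }
  expect_error(makeNpMixture(np, 20, boundFraction = 1.2), "boundFraction")
})

test_that("mixture limits: fully bound is pure nanoparticle, no particles is pure polymer", {
  np <- referenceNp()
  q <- defaultQGrid(150)
  allBound <- makeNpMixture(np, totalConc = 20, boundFraction = 1,
                            qGrid = q, noise = noNoise(), braggPeaks = FALSE,
                            background = 1e-4)
  npOnly <- np
  npOnly@scale <- allBound$groundTruth$params$np$scale
  expect_equal(intensityValues(allBound$curve),
               evalCoreShell(npOnly, q) + 1e-4, tolerance = 1e-12)
  # bound = 0, particle scale -> 0: pure polymer at 0.55 * totalConc
  tiny <- referenceNp(scale = 1e-12)
  noneBound <- makeNpMixture(tiny, totalConc = 20, boundFraction = 0,
                             qGrid = q, noise = noNoise(),
                             braggPeaks = FALSE, background = 0)
  hya <- makeHyaWaterSeries(0.55 * 20, qGrid = q, noise = noNoise(),
                            background = 0)
  expect_equal(intensityValues(noneBound$curve),
               intensityValues(hya$curves[[1]]), tolerance = 1e-6)
})

test_that("mixture free-polymer peak follows the generator's own scaling law", {
  np <- referenceNp()
  mix <- makeNpMixture(np, totalConc = 20, boundFraction = 0.25,
                       noise = noNoise())
  # free concentration 0.75 * 11 mg/mL; peak at K * sqrt(c_free)
  expect_equal(mix$groundTruth$params$freeConcentration, 0.75 * 11)
  hyaComp <- mix$components$hya
  qv <- qValues(hyaComp)
  iPk <- which.max(intensityValues(hyaComp))
  K <- 2 * pi / 270 / sqrt(1.4)
  expect_equal(qv[iPk], K * sqrt(0.75 * 11), tolerance = 5e-3)
})

test_that("DLS trace has the Siegert intercept, the exact decay rate and unit baseline", {
  tr <- makeDlsTrace(300, beta = 0.8, viscosity = 2.5,
                     tau = exp(seq(log(1e-7), log(10), length.out = 300)),
                     noise = noNoise())
  g2 <- g2Values(tr$trace); tau <- tauValues(tr$trace)
  expect_equal(g2[1], 1 + 0.8, tolerance = 1e-3)
  expect_equal(g2[length(g2)], 1, tolerance = 1e-6)
  # Stokes-Einstein closed form for 300 nm at 2.5 cP, 298.15 K
  expect_equal(tr$groundTruth$params$D, 5.82e-13, tolerance = 1e-3)
  # decay rate: g1 at tau = 1/(D q^2) equals exp(-1)
  gamma <- tr$groundTruth$params$D * tr$groundTruth$params$q^2
  g1 <- sqrt((g2 - 1) / 0.8)
  expect_equal(approx(tau, g1, xout = 1 / gamma)$y, exp(-1),
               tolerance = 1e-3)
})

test_that("impactor generator balances mass and respects the median property", {
  ngi <- makeNgiTable(1000, deviceFraction = 0.75, mmad = 3, gsd = 1.8,
                      cutoffs = ngiCutoffs15, noise = noNoise())
  m <- stageMasses(ngi$table)
  expect_equal(sum(m), 1000, tolerance = 1e-9)
  expect_equal(unname(m["device"]), 750)
  # per-stage masses match lognormal CDF differences
  under <- plnorm(ngiCutoffs15, log(3), log(1.8))
  expected <- 250 * (c(1, under[-7]) - under)
  expect_equal(unname(m[paste0("stage", 1:7)]), expected, tolerance = 1e-12)
  # mmad equal to a cut-off: exactly half the emitted mass below it
  ngi2 <- makeNgiTable(1000, deviceFraction = 0, mmad = 3.30, gsd = 2,
                       cutoffs = ngiCutoffs15, noise = noNoise())
  m2 <- stageMasses(ngi2$table)
  below <- sum(m2[c("stage5", "stage6", "stage7", "MOC")])
  expect_equal(below, 500, tolerance = 1e-9)
  # all mass in the device
  ngi3 <- makeNgiTable(1000, deviceFraction = 1, mmad = 3, gsd = 1.8,
                       cutoffs = ngiCutoffs15, noise = noNoise())
  expect_equal(sum(stageMasses(ngi3$table)[-1]), 0)
  expect_error(makeNgiTable(1000, 0.5, 3, 1.8, cutoffs = c(1, 2)),
               "decreasing")
})

test_that("ground truth serializes to JSON and back without loss", {
  gt <- makeNgiTable(1000, 0.75, 3, 1.8, cutoffs = ngiCutoffs15,
                     noise = noNoise())$groundTruth
  path <- withr::local_tempfile(fileext = ".json")
  writeGroundTruth(gt, path)
  back <- readGroundTruth(path)
  expect_equal(back$params$mmad, 3)
  expect_equal(back$params$cutoffs, ngiCutoffs15)
  expect_equal(back$generator, "makeNgiTable")
})
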