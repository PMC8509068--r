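test_that("correlation peak is located and converted to the inter-chain distance", {
  ser <- makeHyaWaterSeries(1.4, noise = noNoise())
  pk <- findCorrelationPeak(ser$curves[[1]])
  expect_true(peakFound(pk))
  # xi = 270 A by construction => qPeak = 2*pi/270 = 0.02327
  expect_equal(qPeak(pk), 2 * pi / 270, tolerance = 5e-3)
  expect_equal(interchainDistance(pk), 270, tolerance = 5e-3)
  # the conversion identity is exact
  expect_equal(interchainDistance(pk) * qPeak(pk), 2 * pi, tolerance = 1e-12)
})

test_that("monotone and buffered curves yield the explicit no-peak outcome", {
  pb <- makeHyaPbSeries(5.6, noise = noNoise())
  expect_false(peakFound(findCorrelationPeak(pb$curves[[1]])))
  mono <- ScatterCurve(defaultQGrid(100), 0.1 * defaultQGrid(100)^-1.5)
  expect_false(peakFound(findCorrelationPeak(mono)))
})

test_that("scaling fit recovers exponents exactly on noise-free input", {
  # two-point slope
  expect_equal(scalingExponent(fitScaling(c(1, 4), c(2, 4))), 0.5,
               tolerance = 1e-12)
  # exact power law: machine-precision recovery
  cs <- c(1.4, 2.8, 5.6, 11.2)
  sf <- fitScaling(cs, 0.0197 * sqrt(cs))
  expect_equal(scalingExponent(sf), 0.5, tolerance = 1e-10)
  expect_equal(scalingPrefactor(sf), 0.0197, tolerance = 1e-10)
  expect_error(fitScaling(c(1, -2), c(1, 2)), "> 0")
  expect_error(fitScaling(1, 1), "at least 2")
})

test_that("scaling exponent from fitted peaks averages 0.5 under 1% noise", {
  cs <- c(1.4, 2.8, 5.6, 11.2)
  expos <- vapply(1:50, function(s) {
    ser <- makeHyaWaterSeries(cs, noise = NoiseModel(level = 0.01, seed = s))
    pks <- vapply(ser$curves, function(cu) qPeak(findCorrelationPeak(cu)),
                  numeric(1))
    scalingExponent(fitScaling(cs, pks))
  }, numeric(1))
  expect_equal(mean(expos), 0.5, tolerance = 0.02 / 0.5)
})

test_that("high-q slope fit is exact on pure power laws", {
  q <- defaultQGrid(300, 0.01, 0.7)
  for (s in c(1.3, 1.5, 2)) {
    cu <- ScatterCurve(q, 0.01 * q^(-s))
    expect_equal(fitHighQSlope(cu)@s, s, tolerance = 1e-10)
  }
  expect_error(fitHighQSlope(ScatterCurve(q, q^-1), qMin = 0.69),
               "fewer than 10")
})

test_that("Guinier fit recovers exact input and respects the qRg window", {
  g <- makeGuinierCurve(2.5, 54, noise = noNoise())
  fit <- fitGuinier(g$curve)
  expect_equal(gyrationRadius(fit), 54, tolerance = 1e-3)
  expect_equal(fit@I0, 2.5, tolerance = 1e-3)
  expect_true(fit@valid)
  expect_lte(fit@window[2] * gyrationRadius(fit), 1.3 * (1 + 1e-6))
})

test_that("Guinier fit averages within 2% at Rg = 98 A under 1% noise", {
  rgs <- vapply(1:50, function(s) {
    g <- makeGuinierCurve(1, 98, noise = NoiseModel(level = 0.01, seed = s))
    gyrationRadius(fitGuinier(g$curve))
  }, numeric(1))
  expect_equal(mean(rgs), 98, tolerance = 0.02)
  expect_lt(sd(rgs), 2)
})

test_that("Guinier fit is invariant under intensity rescaling", {
  g <- makeGuinierCurve(1, 70, noise = NoiseModel(level = 0.01, seed = 9))
  f1 <- fitGuinier(g$curve)
  scaled <- ScatterCurve(qValues(g$curve), 37 * intensityValues(g$curve),
                         sigma = 37 * sigmaValues(g$curve))
  f2 <- fitGuinier(scaled)
  expect_equal(gyrationRadius(f2), gyrationRadius(f1), tolerance = 1e-10)
  expect_equal(f2@I0, 37 * f1@I0, tolerance = 1e-8)
})

test_that("increasing low-q intensity (aggregation) is rejected", {
  q <- defaultQGrid(100, 1e-3, 0.1)
  rising <- ScatterCurve(q, 1 + 5 * q)
  expect_error(fitGuinier(rising), "increases at low q")
})

test_that("inter-chain distances decrease monotonically along the concentration ladder", {
  cs <- c(1.4, 2.8, 5.6, 11.2)
  ser <- makeHyaWaterSeries(cs, noise = NoiseModel(level = 0.01, seed = 17))
  xi <- vapply(ser$curves, function(cu)
    interchainDistance(findCorrelationPeak(cu)), numeric(1))
  expect_true(all(diff(xi) < 0))
})

test_that("stage summary table collects peaks, slopes and radii per sample", {
  water <- makeHyaWaterSeries(c(2.8, 5.6), noise = noNoise())$curves
  pb <- makeHyaPbSeries(c(2.8, 5.6), noise = noNoise())$curves
  tab <- polymerSolutionSummary(c(water, pb))
  expect_equal(nrow(tab), 4)
  expect_true(all(!is.na(tab$qPeak[tab$solvent == "water"])))
  expect_true(all(is.na(tab$qPeak[tab$solvent == "PB"])))
  expect_true(all(!is.na(tab$Rg[tab$solvent == "PB"])))
})
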