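waterRefs <- makeHyaWaterSeries(c(0.7, 1.4, 2.8, 5.6, 11.2),
                                noise = noNoise())$curves
pbRefs <- makeHyaPbSeries(c(0.7, 1.4, 2.8, 5.6, 11.2),
                          noise = noNoise())$curves

test_that("bound and unbound fractions always sum to one and stay in [0, 1]", {
  np <- referenceNp()
  for (b in c(0.2, 0.5, 0.8)) {
    mix <- makeNpMixture(np, totalConc = 10, boundFraction = b,
                         noise = NoiseModel(level = 0.01, seed = 100 + b * 10))
    # at high bound fractions the residual peak is buried under the
    # particle upturn, so the intensity-based route takes over
    method <- if (b <= 0.5) "peak_position" else "high_q_intensity"
    dr <- freeFraction(mix$curve, waterRefs, nominalHyaConc = 5.5,
                       method = method)
    expect_equal(boundFraction(dr) + unboundFraction(dr), 1)
    expect_gte(boundFraction(dr), 0)
    expect_lte(boundFraction(dr), 1)
  }
})

test_that("peak-position method recovers the generating split", {
  np <- referenceNp()
  for (b in c(0.25, 0.5)) {
    est <- vapply(1:5, function(s) {
      mix <- makeNpMixture(np, totalConc = 20, boundFraction = b,
                           noise = NoiseModel(level = 0.01, seed = s))
      unboundFraction(freeFraction(mix$curve, waterRefs,
                                   nominalHyaConc = 11,
                                   method = "peak_position"))
    }, numeric(1))
    expect_equal(mean(est), 1 - b, tolerance = 0.05 / (1 - b))
  }
})

test_that("peak-position and high-q-intensity methods concord within 0.05", {
  np <- referenceNp()
  mix <- makeNpMixture(np, totalConc = 20, boundFraction = 0.3,
                       noise = NoiseModel(level = 0.01, seed = 21))
  u1 <- unboundFraction(freeFraction(mix$curve, waterRefs,
                                     nominalHyaConc = 11,
                                     method = "peak_position"))
  u2 <- unboundFraction(freeFraction(mix$curve, waterRefs,
                                     nominalHyaConc = 11,
                                     method = "high_q_intensity"))
  expect_lt(abs(u1 - u2), 0.05)
})

test_that("buffered-sample discrepancy method recovers a 20% bound fraction", {
  np <- referenceNp()
  est <- vapply(1:5, function(s) {
    mix <- makeNpMixture(np, totalConc = 20, boundFraction = 0.2,
                         solvent = "PB",
                         noise = NoiseModel(level = 0.01, seed = 30 + s))
    boundFraction(freeFraction(mix$curve, pbRefs, nominalHyaConc = 11,
                               method = "pb_discrepancy", solvent = "PB"))
  }, numeric(1))
  expect_equal(mean(est), 0.2, tolerance = 0.05 / 0.2)
})

test_that("subtraction method recovers 30/70 and 40/60 for the 5 and 2.5 mg/mL pair", {
  np <- referenceNp()
  m1 <- makeNpMixture(np, totalConc = 5, boundFraction = 0.30,
                      noise = NoiseModel(level = 0.01, seed = 41))
  m2 <- makeNpMixture(np, totalConc = 2.5, boundFraction = 0.40,
                      noise = NoiseModel(level = 0.01, seed = 42))
  drs <- freeFraction(list(m1$curve, m2$curve), waterRefs,
                      nominalHyaConc = 0.55 * c(5, 2.5),
                      method = "subtraction")
  expect_equal(boundFraction(drs[[1]]), 0.30, tolerance = 0.03 / 0.30)
  expect_equal(boundFraction(drs[[2]]), 0.40, tolerance = 0.03 / 0.40)
})

test_that("unbound polymer at zero binding gives unbound fraction one", {
  # all polymer free, vanishing particle signal
  tiny <- referenceNp(scale = 1e-10)
  mix <- makeNpMixture(tiny, totalConc = 10, boundFraction = 0,
                       noise = noNoise())
  dr <- freeFraction(mix$curve, waterRefs, nominalHyaConc = 5.5,
                     method = "peak_position")
  expect_equal(unboundFraction(dr), 1, tolerance = 0.02)
})

test_that("the peak method refuses buffered (peak-free) samples", {
  np <- referenceNp()
  mix <- makeNpMixture(np, totalConc = 20, boundFraction = 0.2,
                       solvent = "PB", noise = noNoise())
  expect_error(freeFraction(mix$curve, pbRefs, nominalHyaConc = 11,
                            method = "peak_position", solvent = "PB"),
               "salt-free")
})

test_that("profile extraction subtracts the free-polymer component", {
  np <- referenceNp()
  mix <- makeNpMixture(np, totalConc = 20, boundFraction = 0.25,
                       noise = noNoise(), background = 0)
  # subtracting zero leaves the curve unchanged
  zero <- ScatterCurve(qValues(mix$curve),
                       rep(1e-300, length(mix$curve)))
  same <- extractNpProfile(mix$curve, zero)
  expect_equal(intensityValues(same), intensityValues(mix$curve),
               tolerance = 1e-12)
  # subtracting the true component recovers the particle contribution
  prof <- extractNpProfile(mix$curve, mix$components$hya)
  expect_equal(intensityValues(prof), intensityValues(mix$components$np),
               tolerance = 1e-6)
  expect_equal(prof@meta$negativePoints, 0)
})

test_that("oversubtraction is reported through the negative-point count", {
  np <- referenceNp()
  mix <- makeNpMixture(np, totalConc = 20, boundFraction = 0.5,
                       noise = noNoise())
  tooMuch <- hyaModelAtConcentration(waterRefs, 11, "water",
                                     qOut = qValues(mix$curve))
  prof <- extractNpProfile(mix$curve, tooMuch)
  expect_gt(prof@meta$negativePoints, 0)
  expect_true(all(intensityValues(prof) >= 0))
  kept <- extractNpProfile(mix$curve, tooMuch, clipNegative = "keep")
  expect_true(any(intensityValues(kept) < 0))
})

test_that("grids that cannot be aligned by interpolation are rejected", {
  short <- ScatterCurve(seq(0.1, 0.2, length.out = 20), rep(1, 20))
  full <- ScatterCurve(defaultQGrid(50), rep(1, 50))
  expect_error(extractNpProfile(full, short), "not alignable")
})

test_that("exact mixtures pass the linear-combination stability test", {
  a <- makeMucinCurve(1, noise = noNoise())$curve
  b <- pbRefs[[4]]
  mix <- ScatterCurve(qValues(a),
                      intensityValues(a) + intensityValues(b))
  res <- mucinStabilityTest(mix, list(a, b))
  expect_equal(unname(res@coefficients), c(1, 1), tolerance = 1e-8)
  expect_lt(res@residualNorm, 1e-10)
  expect_false(res@interacting)
  # scaled single component
  res2 <- mucinStabilityTest(ScatterCurve(qValues(a),
                                          0.5 * intensityValues(a)),
                             list(a))
  expect_equal(unname(res2@coefficients), 0.5, tolerance = 1e-10)
})

test_that("a 20% low-q perturbation is flagged and localized at low q", {
  a <- makeMucinCurve(1, noise = noNoise())$curve
  b <- pbRefs[[4]]
  qv <- qValues(a)
  Ia <- intensityValues(a)
  lowQ <- qv <= quantile(qv, 1 / 3)
  Ia[lowQ] <- Ia[lowQ] * 1.2
  mix <- ScatterCurve(qv, Ia + intensityValues(b))
  res <- mucinStabilityTest(mix, list(a, b))
  expect_true(res@interacting)
  expect_gt(res@regionResiduals["low"], res@regionResiduals["high"])
  expect_error(mucinStabilityTest(mix, list()), "at least one")
})
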