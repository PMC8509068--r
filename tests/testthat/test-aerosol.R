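test_that("ideal lognormal deposition returns its MMAD and GSD exactly", {
  ngi <- makeNgiTable(1000, deviceFraction = 0.75, mmad = 3, gsd = 1.8,
                      cutoffs = ngiCutoffs15, noise = noNoise())
  res <- aerodynamicParams(ngi$table)
  expect_equal(res@MMAD, 3, tolerance = 1e-3)
  expect_equal(res@GSD, 1.8, tolerance = 1e-3)
  expect_equal(res@r2, 1, tolerance = 1e-9)
  expect_equal(res@EF, 25, tolerance = 1e-9)
  expect_false(res@extrapolated)
})

test_that("MMAD/GSD recovery holds across the parameter grid within 1%", {
  for (mmad in c(1, 2.5, 4, 6)) {
    for (gsd in c(1.3, 1.8, 2.5)) {
      ngi <- makeNgiTable(500, deviceFraction = 0.3, mmad = mmad, gsd = gsd,
                          cutoffs = ngiCutoffs15, noise = noNoise())
      res <- aerodynamicParams(ngi$table)
      expect_equal(res@MMAD, mmad, tolerance = 0.01)
      expect_equal(res@GSD, gsd, tolerance = 0.01)
    }
  }
})

test_that("dose bookkeeping: ED, EF, FPD and mass conservation", {
  ngi <- makeNgiTable(800, deviceFraction = 0.75, mmad = 3, gsd = 1.8,
                      cutoffs = ngiCutoffs15, ipFraction = 0.1,
                      noise = noNoise())
  res <- aerodynamicParams(ngi$table)
  m <- stageMasses(ngi$table)
  expect_equal(res@ED + unname(m["device"]), sum(m), tolerance = 1e-9)
  expect_equal(res@EF, 25, tolerance = 1e-9)
  expect_lte(res@FPD, res@ED)
  expect_equal(res@FPF, 100 * res@FPD / res@ED, tolerance = 1e-12)
})

test_that("aerodynamic invariants hold on fuzzed random tables", {
  withr::with_seed(99, {
    for (i in 1:20) {
      ngi <- makeNgiTable(runif(1, 100, 2000),
                          deviceFraction = runif(1, 0, 0.9),
                          mmad = runif(1, 1, 6), gsd = runif(1, 1.3, 2.5),
                          cutoffs = ngiCutoffs15,
                          ipFraction = runif(1, 0, 0.3),
                          noise = NoiseModel(level = 0.05, seed = i))
      res <- aerodynamicParams(ngi$table)   # validity enforces the rest
      expect_s4_class(res, "AeroResult")
      if (!is.na(res@GSD)) expect_gte(res@GSD, 1)
      expect_lte(res@FPD, res@ED + 1e-9)
    }
  })
})

test_that("degenerate tables are handled explicitly", {
  # all mass in the device: ratios undefined
  allDev <- makeNgiTable(100, deviceFraction = 1, mmad = 3, gsd = 1.8,
                         cutoffs = ngiCutoffs15, noise = noNoise())
  res <- aerodynamicParams(allDev$table)
  expect_equal(res@ED, 0)
  expect_true(is.na(res@FPF))
  # mass only on the MOC: everything fine, median out of range
  tab <- DepositionTable(c("device", "IP", paste0("stage", 1:7), "MOC"),
                         c(0, 0, rep(0, 7), 50),
                         c(NA, NA, ngiCutoffs15, NA))
  res2 <- aerodynamicParams(tab)
  expect_equal(res2@FPF, 100)
  expect_true(res2@extrapolated)
  expect_true(is.na(res2@MMAD))
})

test_that("the rounded 85/16 percentile pair gives a slightly different GSD", {
  ngi <- makeNgiTable(1000, deviceFraction = 0.2, mmad = 3, gsd = 1.8,
                      cutoffs = ngiCutoffs15, noise = noNoise())
  std <- aerodynamicParams(ngi$table)
  rnd <- aerodynamicParams(ngi$table, gsdPercentiles = "rounded")
  expect_equal(std@GSD, 1.8, tolerance = 1e-6)
  expect_gt(rnd@GSD, std@GSD)           # 85/16 brackets slightly wider
  expect_equal(rnd@GSD, 1.8, tolerance = 0.02)
})

test_that("loading metrics follow the measured/nominal arithmetic", {
  res <- loadingMetrics(34.3, 45)
  expect_equal(res@capacity, 34.3)
  expect_equal(res@efficiency, 100 * 34.3 / 45, tolerance = 1e-12)
  expect_equal(round(res@efficiency, 1), 76.2)
  expect_equal(loadingMetrics(40, 40)@efficiency, 100)
  expect_equal(loadingMetrics(10, 40)@efficiency, 25)
  expect_error(loadingMetrics(34.3, 0), "0, 100")
})

test_that("formulation fractions reproduce the 55:45 composition numbers", {
  res <- formulationFractions(c(HYA = 55, DEX = 45),
                              molarMasses = c(HYA = 750000, DEX = 392.5),
                              antisolventVolumes = c(29.5, 14.5),
                              solventVolumes = 36)
  expect_equal(round(100 * res$moleFractions[["HYA"]], 2), 0.06)
  expect_equal(res$massFractions[["HYA"]], 0.55)
  expect_equal(res$antisolventPct, 55, tolerance = 1e-12)
  # equal molar masses: mole fractions equal mass fractions
  eq <- formulationFractions(c(a = 30, b = 70), molarMasses = c(a = 1, b = 1))
  expect_equal(eq$moleFractions, eq$massFractions)
})

test_that("volume percentiles interpolate the cumulative curve", {
  # symmetric triangular distribution centred at 10 um
  d <- seq(5, 15, by = 0.1)
  w <- pmax(0, 5 - abs(d - 10))
  pct <- volumePercentiles(d, w)
  expect_equal(unname(pct["Dv50"]), 10, tolerance = 1e-3)
  # lognormal: percentiles match the closed-form quantiles
  sdlog <- log(31.7 / 11.2) / qnorm(0.9)
  dg <- exp(seq(log(0.2), log(400), length.out = 4000))
  wg <- dlnorm(dg, log(11.2), sdlog) * dg     # weight per log-spaced bin
  pct2 <- volumePercentiles(dg, wg)
  expect_equal(unname(pct2["Dv50"]), 11.2, tolerance = 5e-3)
  expect_equal(unname(pct2["Dv90"]), 31.7, tolerance = 5e-3)
  expect_equal(unname(pct2["Dv10"]),
               qlnorm(0.1, log(11.2), sdlog), tolerance = 5e-3)
  # single point: all percentiles collapse onto it
  expect_equal(unname(volumePercentiles(7, 1)), rep(7, 3))
  expect_error(volumePercentiles(numeric(0), numeric(0)), "non-empty")
})
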