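# nanoscatter

Scattering and aerodynamic characterization of polymer–drug nanosuspensions
in R, built around reconstituted hyaluronic-acid (HYA) coated dexamethasone
(DEX) nanoparticles for pulmonary delivery.

When a spray-dried 55:45 HYA:DEX powder is redispersed in water or phosphate
buffer (PB), the resulting nanosuspension is characterized by a standard
battery of colloid physics: dynamic light scattering (DLS), small- and
wide-angle X-ray scattering (SAXS/WAXS), and cascade impaction of the
nebulized suspension. `nanoscatter` implements that entire analysis chain as
tested, reusable functions, together with seeded synthetic-data generators
that attach their exact ground truth to every dataset so each estimator can
be validated by parameter recovery.

## What it computes

| Stage | Physics | Key functions |
|---|---|---|
| Forward models | Guinier `I₀·exp(−q²Rg²/3)`; power law `A·q⁻ˢ`; polyelectrolyte correlation peak at `q_peak = 2π/ξ`; Guinier–Porod; polydisperse core-shell sphere; orthorhombic Bragg positions `q_hkl = 2π√((h/a)²+(k/b)²+(l/c)²)` | `evalModel`, `evalCoreShell`, `braggPositions` |
| Polymer solutions | peak location and `q_peak ∝ √c`, `I(q_peak) ∝ √c` scaling; high-q conformation exponent; Guinier radii in buffer | `findCorrelationPeak`, `fitScaling`, `fitHighQSlope`, `fitGuinier` |
| Bound/unbound polymer | four decomposition routes (peak position, high-q intensity, buffered discrepancy, congruent subtraction); profile extraction; mucin linear-combination stability | `freeFraction`, `extractNpProfile`, `mucinStabilityTest` |
| Particle structure | bounded multi-start core-shell fitting; WAXS peak detection and Bragg indexing against the DEX cell (a = 10.36, b = 16.16, c = 23.20 Å) | `fitCoreShell`, `analyzeWaxs`, `dexLattice` |
| Hydrodynamics | Siegert inversion (cumulant and NNLS), Stokes–Einstein `D_H = k_BT/(3πηD)` with solution-viscosity correction; ζ summaries | `dlsAnalyze`, `stokesEinstein`, `summarizeZeta` |
| Aerodynamics | MMAD/GSD by probit regression of cumulative undersize vs log cut-off; ED, EF%, FPD, FPF%; loading and formulation arithmetic; volume percentiles | `aerodynamicParams`, `loadingMetrics`, `formulationFractions`, `volumePercentiles` |
| Synthetic data | every input above with ground truth and bit-reproducible noise | `makeHyaWaterSeries`, `makeHyaPbSeries`, `makeNpMixture`, `makeDlsTrace`, `makeNgiTable`, `makeWaxsPattern`, `makeMucinCurve` |
| I/O + pipeline | ASCII/CSV/JSON round trips, config-driven driver | `readScatterCurve`, `writeReport`, `runPipeline` |

## Worked example

Calibrate the polyelectrolyte scaling on a salt-free dilution ladder, then
quantify how much polymer is free in a 20 mg/mL reconstituted
nanosuspension, size the particles by DLS, and compute aerosol performance:

```r
library(nanoscatter)

## 1. water calibration: q_peak = K * sqrt(c)
refs <- makeHyaWaterSeries(c(1.4, 2.8, 5.6, 11.2), noise = noNoise())
pks  <- lapply(refs$curves, findCorrelationPeak)
fitScaling(c(1.4, 2.8, 5.6, 11.2), sapply(pks, qPeak))
#> ScalingFit: value ~ prefactor * c^exponent
#>   exponent: 0.5001
#>   prefactor: 0.01967
#>   r2: 1

## 2. bound/unbound split of a 20 mg/mL mixture (true split 25/75)
np  <- CoreShellParams(coreRadius = 1000, shellThickness = 15,
                       sldCore = 11.8, sldShell = 16, sldSolvent = 9.47,
                       polydispersity = 0.1)
mix <- makeNpMixture(np, totalConc = 20, boundFraction = 0.25,
                     noise = NoiseModel(level = 0.01, seed = 1))
freeFraction(mix$curve, refs$curves, nominalHyaConc = 0.55 * 20,
             method = "peak_position")
#> DecompositionResult [peak_position]
#>   boundFraction: 0.2458
#>   unboundFraction: 0.7542
#>   freeConcentration: 8.296

## 3. viscosity-corrected DLS size (300 nm spheres in a 2.5 cP solution)
tr <- makeDlsTrace(300, viscosity = 2.5, noise = NoiseModel(level = 0.01, seed = 1))
dlsAnalyze(tr$trace)
#> HydroResult [cumulant] (D m^2/s, DH nm)
#>   D: 5.812e-13
#>   DH: 300.6
#>   PDI: 0

## 4. impactor aerodynamics (3 um MMAD aerosol, 75% retained in the device)
ngi <- makeNgiTable(1000, deviceFraction = 0.75, mmad = 3, gsd = 1.8,
                    cutoffs = c(14.1, 8.61, 5.39, 3.30, 2.08, 1.36, 0.98),
                    noise = noNoise())
round(aeroSummary(aerodynamicParams(ngi$table)), 2)
#>   MMAD    GSD     ED     EF    FPD    FPF
#>   3.00   1.80 250.00  25.00 240.89  96.36
```

Reading the numbers: the fitted scaling exponent 0.50 confirms classical
polyelectrolyte behaviour (`q_peak ∝ √c`); the decomposition recovers the
75% unbound fraction the mixture was built with to better than one
percentage point; the DLS inversion returns the generating 300 nm diameter
after correcting for the 2.5 cP solution viscosity; and the impactor stage
returns the generating MMAD and GSD exactly, with an emitted fraction of
25% of the loaded dose.

## Documentation

The methods vignette
(`vignettes/nanosuspension-characterization.Rmd`) describes the models and
their assumptions, every tunable parameter with units and defaults, what
the synthetic generators do and do not emulate, the numerical choices, and
known limitations.
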