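## Seeded synthetic-data generators. Every generator returns its inputs in a
## groundTruth record so that recovery tests can compare estimates against
## the exact generating parameters.

.groundTruth <- function(generator, params, seed) {
  structure(list(generator = generator, params = params, seed = seed),
            class = "groundTruth")
}

#' @export
print.groundTruth <- function(x, ...) {
  cat(sprintf("groundTruth [%s], seed %s\n", x$generator,
              format(x$seed)))
  utils::str(x$params, max.level = 2, give.attr = FALSE)
  invisible(x)
}

## apply a NoiseModel to a non-negative signal; returns list(value, sigma).
## gaussian_relative: sd = level * value; poisson_like: sd = level *
## sqrt(value * max(value)) (counting-like, larger relative noise where the
## signal is weak). kind = "none" returns the input exactly.
.applyNoise <- function(value, noise, seedOffset = 0) {
  stopifnot(is(noise, "NoiseModel"))
  validObject(noise)
  if (noise@kind == "none" || noise@level == 0)
    return(list(value = value, sigma = NULL))
  sigma <- switch(noise@kind,
    gaussian_relative = noise@level * abs(value),
    poisson_like = noise@level * sqrt(abs(value) * max(abs(value))))
  sigma <- pmax(sigma, 1e-12 * max(abs(value)))
  noisy <- .withSeed(.childSeed(noise@seed, seedOffset),
                     value + stats::rnorm(length(value)) * sigma)
  list(value = noisy, sigma = sigma)
}

## default water-solution calibration: the correlation peak of the 1.4 mg/mL
## reference sits at 2*pi/270 A^-1, so qPeak = K sqrt(c) with
.defaultK <- function() 2 * pi / 270 / sqrt(1.4)

## broad-peak model of a salt-free polyelectrolyte solution at concentration
## c, self-similar across c: qPeak = K sqrt(c), I(qPeak) = J sqrt(c), width
## proportional to qPeak, tail a fixed fraction of the peak intensity at
## qPeak. Self-similarity makes peak-location bias cancel in concentration
## ratios.
.hyaWaterModel <- function(c, K, J, s, relWidth = 0.25, tailFraction = 0.3,
                           background = 1e-4) {
  qPeak <- K * sqrt(c)
  iPeak <- J * sqrt(c)
  ## tail amplitude set so the damped tail contributes tailFraction * iPeak
  ## at the peak position
  tailAmp <- tailFraction * iPeak / .dampedTail(qPeak, qPeak, s)
  peakAmp <- (1 - tailFraction) * iPeak - background
  if (peakAmp <= 0) stop("background too large for the requested peak intensity")
  BroadPeakParams(qPeak = qPeak, width = relWidth * qPeak,
                  peakAmplitude = peakAmp, background = background,
                  tailExponent = s, tailAmplitude = tailAmp)
}

## buffered (salt-screened) polymer model: monotone Guinier-Porod profile
## with concentration-dependent gyration radius (denser regions shrink as c
## grows); the amplitude is linear in c, so intensity-vs-c calibration is
## exact in this solvent
.hyaPbModel <- function(c, Gpb = 0.01, s = 1.5, Rg = NULL,
                        RgRef = 98, cRef = 1.4, RgExponent = -0.287,
                        background = 1e-4) {
  if (is.null(Rg)) Rg <- RgRef * (c / cRef)^RgExponent
  GuinierPowerLawParams(I0 = Gpb * c, Rg = Rg, s = s,
                        background = background)
}

#' Synthetic salt-free polymer dilution series
#'
#' Generates SAXS curves of a polyelectrolyte (hyaluronic acid) in salt-free
#' water at the requested concentrations, with the correlation peak obeying
#' \eqn{q_{peak} = K\sqrt{c}} and \eqn{I(q_{peak}) = J\sqrt{c}} and a high-q
#' tail \eqn{q^{-s}}.
#'
#' @param concentrations mg/mL, all positive.
#' @param K peak-position prefactor, \eqn{\mathrm{\AA}^{-1}(mg/mL)^{-1/2}};
#'   default places the 1.4 mg/mL peak at \eqn{2\pi/270\,\mathrm{\AA}^{-1}}
#'   (inter-chain distance 270 \eqn{\mathrm{\AA}}).
#' @param J peak-intensity prefactor, \eqn{mm^{-1}(mg/mL)^{-1/2}}.
#' @param s high-q tail exponent (1.3: rod-like chains).
#' @param qGrid momentum-transfer grid.
#' @param noise a [NoiseModel-class].
#' @param relWidth peak half-width as a fraction of the peak position.
#' @param tailFraction tail contribution at \eqn{q_{peak}} as a fraction of
#'   the peak intensity.
#' @param background flat background, \eqn{mm^{-1}}.
#' @return list with \code{curves} (list of [ScatterCurve-class]) and
#'   \code{groundTruth}.
#' @examples
#' ser <- makeHyaWaterSeries(c(1.4, 2.8, 5.6, 11.2), noise = noNoise())
#' length(ser$curves)
#' @export
makeHyaWaterSeries <- function(concentrations, K = .defaultK(), J = 0.05,
                               s = 1.3, qGrid = defaultQGrid(),
                               noise = NoiseModel(), relWidth = 0.25,
                               tailFraction = 0.3, background = 1e-4) {
  if (!length(concentrations)) stop("empty concentration list")
  if (any(concentrations <= 0) || K <= 0 || J <= 0)
    stop("concentrations, K and J must be > 0")
  .checkQGrid(qGrid)
  curves <- lapply(seq_along(concentrations), function(i) {
    ci <- concentrations[i]
    model <- .hyaWaterModel(ci, K, J, s, relWidth, tailFraction, background)
    I <- evalModel(model, qGrid)
    ns <- .applyNoise(I, noise, seedOffset = i)
    ScatterCurve(qGrid, ns$value, sigma = ns$sigma,
                 meta = list(concentration = ci, solvent = "water",
                             label = sprintf("HYA %g mg/mL water", ci)))
  })
  gt <- .groundTruth("makeHyaWaterSeries",
                     list(concentrations = concentrations, K = K, J = J,
                          s = s, relWidth = relWidth,
                          tailFraction = tailFraction,
                          background = background,
                          qPeak = K * sqrt(concentrations),
                          xi = 2 * pi / (K * sqrt(concentrations)),
                          IPeak = J * sqrt(concentrations),
                          noise = list(kind = noise@kind,
                                       level = noise@level)),
                     noise@seed)
  list(curves = curves, groundTruth = gt)
}

#' Synthetic buffered polymer dilution series
#'
#' Salt-screened counterpart of [makeHyaWaterSeries()]: no correlation peak;
#' each curve is a Guinier-to-power-law profile whose gyration radius shrinks
#' with concentration as \eqn{R_g = R_{g,ref}(c/c_{ref})^{\gamma}}.
#'
#' @inheritParams makeHyaWaterSeries
#' @param Gpb Guinier forward-intensity prefactor, \eqn{mm^{-1}} per mg/mL.
#' @param s high-q exponent (1.5: compacted but still rigid chains).
#' @param RgRef,cRef,RgExponent gyration-radius law.
#' @return list with \code{curves} and \code{groundTruth}.
#' @export
makeHyaPbSeries <- function(concentrations, Gpb = 0.01, s = 1.5,
                            RgRef = 98, cRef = 1.4, RgExponent = -0.287,
                            qGrid = defaultQGrid(), noise = NoiseModel(),
                            background = 1e-4) {
  if (!length(concentrations)) stop("empty concentration list")
  if (any(concentrations <= 0)) stop("concentrations must be > 0")
  .checkQGrid(qGrid)
  Rg <- RgRef * (concentrations / cRef)^RgExponent
  curves <- lapply(seq_along(concentrations), function(i) {
    ci <- concentrations[i]
    model <- .hyaPbModel(ci, Gpb, s, Rg = Rg[i], background = background)
    I <- evalModel(model, qGrid)
    ns <- .applyNoise(I, noise, seedOffset = i)
    ScatterCurve(qGrid, ns$value, sigma = ns$sigma,
                 meta = list(concentration = ci, solvent = "PB",
                             label = sprintf("HYA %g mg/mL PB", ci)))
  })
  gt <- .groundTruth("makeHyaPbSeries",
                     list(concentrations = concentrations, Gpb = Gpb,
                          s = s, Rg = Rg, background = background,
                          noise = list(kind = noise@kind,
                                       level = noise@level)),
                     noise@seed)
  list(curves = curves, groundTruth = gt)
}

#' Synthetic Guinier curve
#'
#' Pure Guinier decay \eqn{I_0\exp(-q^2R_g^2/3)} plus optional noise; the
#' basic fixture for gyration-radius recovery tests.
#'
#' @param I0 forward intensity, \eqn{mm^{-1}}.
#' @param Rg gyration radius, \eqn{\mathrm{\AA}}.
#' @param qGrid momentum-transfer grid.
#' @param noise a [NoiseModel-class].
#' @return list with \code{curve} and \code{groundTruth}.
#' @export
makeGuinierCurve <- function(I0, Rg, qGrid = defaultQGrid(qMax = 0.1),
                             noise = NoiseModel()) {
  I <- evalModel(GuinierParams(I0, Rg), qGrid)
  ns <- .applyNoise(I, noise)
  list(curve = ScatterCurve(qGrid, ns$value, sigma = ns$sigma,
                            meta = list(label = "synthetic Guinier")),
       groundTruth = .groundTruth("makeGuinierCurve",
                                  list(I0 = I0, Rg = Rg), noise@seed))
}

#' Synthetic nanoparticle / free-polymer mixture spectrum
#'
#' Builds the SAXS spectrum of a reconstituted nanosuspension as the sum of a
#' polydisperse core-shell nanoparticle contribution and the contribution of
#' the polymer fraction that remains free in solution. In water the free
#' polymer shows the salt-free correlation peak; in phosphate buffer it is a
#' peak-free Guinier-to-power-law profile. Narrow Bragg peaks from the
#' nanocrystalline drug core can be superposed.
#'
#' The drug volume fraction used to scale the nanoparticle term is
#' \eqn{\phi = (1 - w_{HYA})\,c_{tot} / \rho_{DEX}} with
#' \eqn{\rho_{DEX} = 1300} mg/mL, multiplied by the \code{scale} slot of
#' \code{np}.
#'
#' @param np nanoparticle [CoreShellParams-class] (its \code{scale} acts as a
#'   multiplier on the drug volume fraction).
#' @param totalConc total formulation concentration, mg/mL.
#' @param hyaMassFraction polymer mass fraction of the formulation (0.55 for
#'   the 55:45 HYA:DEX powder).
#' @param boundFraction fraction of the polymer complexed in nanoparticles,
#'   in \eqn{[0, 1]}; the free-polymer concentration is
#'   \eqn{(1 - bound)\,w_{HYA}\,c_{tot}}.
#' @param hyaScaling list with the water-calibration constants \code{K},
#'   \code{J}, \code{s} (and optionally \code{relWidth},
#'   \code{tailFraction}) or, for PB, \code{Gpb}, \code{s}.
#' @param solvent \code{"water"} or \code{"PB"}.
#' @param qGrid momentum-transfer grid.
#' @param noise a [NoiseModel-class].
#' @param braggPeaks logical: superpose the two lowest drug-lattice
#'   reflections as narrow Gaussians.
#' @param braggAmplitude Bragg peak height per unit drug volume fraction,
#'   \eqn{mm^{-1}}.
#' @param braggWidth Gaussian sd of the Bragg peaks, \eqn{\mathrm{\AA}^{-1}}.
#' @param background flat background, \eqn{mm^{-1}}.
#' @return list with \code{curve}, \code{components} (noise-free \code{np}
#'   and \code{hya} [ScatterCurve-class]s) and \code{groundTruth} (records
#'   the free polymer concentration).
#' @examples
#' np <- CoreShellParams(coreRadius = 1000, shellThickness = 15,
#'                       sldCore = 11.8, sldShell = 16)
#' mix <- makeNpMixture(np, totalConc = 20, boundFraction = 0.25,
#'                      noise = noNoise())
#' mix$groundTruth$params$freeConcentration
#' @export
makeNpMixture <- function(np, totalConc, hyaMassFraction = 0.55,
                          boundFraction, hyaScaling = list(), solvent = "water",
                          qGrid = defaultQGrid(), noise = NoiseModel(),
                          braggPeaks = TRUE, braggAmplitude = 2,
                          braggWidth = 0.004, background = 1e-4) {
  stopifnot(is(np, "CoreShellParams"))
  if (boundFraction < 0 || boundFraction > 1)
    stop("boundFraction must lie in [0, 1]")
  if (hyaMassFraction <= 0 || hyaMassFraction >= 1)
    stop("hyaMassFraction must lie in (0, 1)")
  solvent <- match.arg(solvent, c("water", "PB"))
  .checkQGrid(qGrid)

  cHya <- hyaMassFraction * totalConc
  cFree <- (1 - boundFraction) * cHya
  phi <- (1 - hyaMassFraction) * totalConc / 1300  # DEX density 1.3 g/cm^3

  npScaled <- np
  npScaled@scale <- np@scale * phi
  npScaled@background <- 0
  iNp <- evalCoreShell(npScaled, qGrid)

  if (braggPeaks) {
    refl <- braggPositions(dexLattice(), hkl = rbind(c(0, 1, 1), c(0, 0, 2)))
    for (qB in refl$q)
      iNp <- iNp + braggAmplitude * phi * exp(-(qGrid - qB)^2 /
                                              (2 * braggWidth^2))
  }

  if (cFree > 0) {
    hyaModel <- if (solvent == "water") {
      .hyaWaterModel(cFree,
                     K = hyaScaling$K %||% .defaultK(),
                     J = hyaScaling$J %||% 0.05,
                     s = hyaScaling$s %||% 1.3,
                     relWidth = hyaScaling$relWidth %||% 0.25,
                     tailFraction = hyaScaling$tailFraction %||% 0.3,
                     background = 0)
    } else {
      .hyaPbModel(cFree,
                  Gpb = hyaScaling$Gpb %||% 0.01,
                  s = hyaScaling$s %||% 1.5,
                  background = 0)
    }
    iHya <- evalModel(hyaModel, qGrid)
  } else iHya <- numeric(length(qGrid))

  iTot <- iNp + iHya + background
  ns <- .applyNoise(iTot, noise)
  meta <- list(concentration = totalConc, solvent = solvent,
               hyaMassFraction = hyaMassFraction,
               label = sprintf("HYA-DEX %g mg/mL %s", totalConc, solvent))
  gt <- .groundTruth("makeNpMixture",
                     list(np = list(coreRadius = np@coreRadius,
                                    shellThickness = np@shellThickness,
                                    sldCore = np@sldCore,
                                    sldShell = np@sldShell,
                                    sldSolvent = np@sldSolvent,
                                    polydispersity = np@polydispersity,
                                    scale = npScaled@scale),
                          totalConc = totalConc,
                          hyaMassFraction = hyaMassFraction,
                          boundFraction = boundFraction,
                          freeConcentration = cFree,
                          boundConcentration = cHya - cFree,
                          solvent = solvent, braggPeaks = braggPeaks,
                          background = background,
                          noise = list(kind = noise@kind,
                                       level = noise@level)),
                     noise@seed)
  list(curve = ScatterCurve(qGrid, ns$value, sigma = ns$sigma, meta = meta),
       components = list(
         np = ScatterCurve(qGrid, iNp + background, meta = meta),
         hya = if (cFree > 0)
           ScatterCurve(qGrid, iHya,
                        meta = list(concentration = cFree, solvent = solvent))
         else NULL),
       groundTruth = gt)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Synthetic mucin spectrum
#'
#' Empirical Guinier-to-power-law profile standing in for the SAXS signal of
#' dispersed gastric mucin at the given weight-per-volume concentration.
#' Synthetic stand-in only: amplitudes are plausible, not measured.
#'
#' @param concPct mucin concentration, percent w/v.
#' @param Rg apparent gyration radius of mucin subunits, \eqn{\mathrm{\AA}}.
#' @param s high-q exponent.
#' @param qGrid momentum-transfer grid.
#' @param noise a [NoiseModel-class].
#' @return list with \code{curve} and \code{groundTruth}.
#' @export
makeMucinCurve <- function(concPct, Rg = 150, s = 1.8,
                           qGrid = defaultQGrid(), noise = NoiseModel()) {
  if (concPct <= 0) stop("concPct must be > 0")
  model <- GuinierPowerLawParams(I0 = 0.5 * concPct, Rg = Rg, s = s,
                                 background = 1e-4)
  I <- evalModel(model, qGrid)
  ns <- .applyNoise(I, noise)
  list(curve = ScatterCurve(qGrid, ns$value, sigma = ns$sigma,
                            meta = list(concentration = concPct,
                                        solvent = "PB",
                                        label = sprintf("mucin %g%% w/v",
                                                        concPct))),
       groundTruth = .groundTruth("makeMucinCurve",
                                  list(concPct = concPct, Rg = Rg, s = s),
                                  noise@seed))
}

#' Synthetic WAXS diffraction pattern
#'
#' Gaussian Bragg peaks at the reflections of a lattice, heights proportional
#' to concentration, over a smooth power-law background.
#'
#' @param lattice a [Lattice-class].
#' @param hkl matrix of Miller indices (one reflection per row).
#' @param heights peak heights at unit concentration, \eqn{mm^{-1}}, one per
#'   reflection.
#' @param concentration sample concentration (multiplies the heights).
#' @param width Gaussian sd of the peaks, \eqn{\mathrm{\AA}^{-1}}.
#' @param qGrid momentum-transfer grid (WAXS window 1--2
#'   \eqn{\mathrm{\AA}^{-1}} by default).
#' @param bgAmplitude,bgExponent smooth background \eqn{A q^{-e}}.
#' @param noise a [NoiseModel-class].
#' @return list with \code{curve} and \code{groundTruth}.
#' @export
makeWaxsPattern <- function(lattice = dexLattice(),
                            hkl = rbind(c(2, 0, 0), c(1, 3, 2), c(2, 2, 3)),
                            heights = c(1, 0.7, 0.5), concentration = 1,
                            width = 0.005,
                            qGrid = seq(1, 2, length.out = 500),
                            bgAmplitude = 0.01, bgExponent = 1,
                            noise = NoiseModel()) {
  stopifnot(length(heights) == nrow(hkl))
  refl <- braggPositions(lattice, hkl = hkl)
  ## braggPositions sorts by q: re-order heights accordingly
  key <- paste(refl$h, refl$k, refl$l)
  key0 <- paste(hkl[, 1], hkl[, 2], hkl[, 3])
  heights <- heights[match(key, key0)]
  I <- bgAmplitude * qGrid^(-bgExponent)
  for (i in seq_len(nrow(refl)))
    I <- I + concentration * heights[i] *
      exp(-(qGrid - refl$q[i])^2 / (2 * width^2))
  ns <- .applyNoise(I, noise)
  list(curve = ScatterCurve(qGrid, ns$value, sigma = ns$sigma,
                            meta = list(concentration = concentration,
                                        label = "synthetic WAXS")),
       groundTruth = .groundTruth("makeWaxsPattern",
                                  list(hkl = refl[, c("h", "k", "l")],
                                       q = refl$q,
                                       heights = heights,
                                       concentration = concentration,
                                       width = width), noise@seed))
}

#' Synthetic DLS autocorrelation trace
#'
#' Intensity autocorrelation of a (possibly multimodal) suspension of
#' spheres via the Siegert relation,
#' \deqn{g_2(\tau) = 1 + \beta\left|\sum_i w_i e^{-D_i q^2 \tau}\right|^2,}
#' with \eqn{q = (4\pi n/\lambda)\sin(\theta/2)} and each \eqn{D_i} from
#' Stokes-Einstein at the given temperature and viscosity.
#'
#' @param diameters particle diameters, nm.
#' @param weights intensity weights (normalized internally).
#' @param beta coherence factor, in (0, 1].
#' @param viscosity solution viscosity, cP.
#' @param temperature absolute temperature, K.
#' @param angle scattering angle, degrees.
#' @param wavelength laser wavelength, nm.
#' @param refractiveIndex solvent refractive index.
#' @param tau lag-time grid, s.
#' @param noise a [NoiseModel-class]; relative noise is applied to the
#'   correlation amplitude \eqn{g_2 - 1}.
#' @return list with \code{trace} ([DLSTrace-class]) and \code{groundTruth}.
#' @examples
#' tr <- makeDlsTrace(300, viscosity = 2.5, noise = noNoise())
#' head(g2Values(tr$trace))
#' @export
makeDlsTrace <- function(diameters, weights = rep(1, length(diameters)),
                         beta = 0.8, viscosity = 0.89, temperature = 298.15,
                         angle = 90, wavelength = 532,
                         refractiveIndex = 1.33,
                         tau = exp(seq(log(1e-6), log(1), length.out = 200)),
                         noise = NoiseModel()) {
  if (any(weights < 0) || sum(weights) <= 0)
    stop("weights must be >= 0 and not all zero")
  if (beta <= 0 || beta > 1) stop("beta must lie in (0, 1]")
  if (viscosity <= 0 || temperature <= 0)
    stop("non-physical viscosity or temperature")
  w <- weights / sum(weights)
  D <- inverseStokesEinstein(diameters, temperature = temperature,
                             viscosity = viscosity)
  q <- dlsQ(wavelength, angle, refractiveIndex)  # m^-1
  g1 <- colSums(w * exp(-outer(D * q^2, tau)))
  g2 <- 1 + beta * g1^2
  ns <- .applyNoise(g2 - 1, noise)
  trace <- DLSTrace(tau, 1 + ns$value, wavelength = wavelength,
                    angle = angle, refractiveIndex = refractiveIndex,
                    temperature = temperature, viscosity = viscosity)
  gt <- .groundTruth("makeDlsTrace",
                     list(diameters = diameters, weights = w, beta = beta,
                          viscosity = viscosity, temperature = temperature,
                          D = D, q = q,
                          noise = list(kind = noise@kind,
                                       level = noise@level)),
                     noise@seed)
  list(trace = trace, groundTruth = gt)
}

#' Synthetic cascade-impactor deposition table
#'
#' Deposits a lognormal aerosol (median \code{mmad}, geometric sd \code{gsd})
#' onto impactor stages by cut-off diameter: the emitted mass (total minus
#' the fraction retained in the device, minus an optional size-independent
#' induction-port bite) is apportioned between consecutive cut-offs by the
#' lognormal CDF; the MOC collects everything below the last cut-off. With
#' \code{noise = noNoise()} the masses balance exactly.
#'
#' @param totalDose total drug mass loaded, ug.
#' @param deviceFraction fraction of the dose retained in the device, [0, 1].
#' @param mmad mass median aerodynamic diameter, um.
#' @param gsd geometric standard deviation, > 1.
#' @param cutoffs stage cut-off diameters, um, strictly decreasing. These
#'   are configuration: supply the values for your impactor and flow rate.
#' @param ipFraction size-independent fraction of the emitted dose deposited
#'   in the induction port.
#' @param flowRate air flow, L/min (metadata).
#' @param noise a [NoiseModel-class] applied per-location.
#' @return list with \code{table} ([DepositionTable-class]) and
#'   \code{groundTruth}.
#' @examples
#' ngi <- makeNgiTable(1000, deviceFraction = 0.75, mmad = 3, gsd = 1.8,
#'                     cutoffs = c(14.1, 8.61, 5.39, 3.3, 2.08, 1.36, 0.98),
#'                     noise = noNoise())
#' sum(stageMasses(ngi$table))
#' @export
makeNgiTable <- function(totalDose, deviceFraction, mmad, gsd, cutoffs,
                         ipFraction = 0, flowRate = 15,
                         noise = NoiseModel()) {
  if (deviceFraction < 0 || deviceFraction > 1)
    stop("deviceFraction must lie in [0, 1]")
  if (gsd <= 1) stop("gsd must be > 1")
  if (length(cutoffs) < 2 || any(diff(cutoffs) >= 0))
    stop("cutoffs must be strictly decreasing")
  emitted <- totalDose * (1 - deviceFraction)
  ipMass <- emitted * ipFraction
  sized <- emitted - ipMass
  under <- stats::plnorm(cutoffs, meanlog = log(mmad), sdlog = log(gsd))
  upper <- c(1, under[-length(under)])
  stageMass <- sized * (upper - under)
  mocMass <- sized * under[length(under)]
  location <- c("device", "IP", paste0("stage", seq_along(cutoffs)), "MOC")
  mass <- c(totalDose * deviceFraction, ipMass, stageMass, mocMass)
  if (noise@kind != "none" && noise@level > 0) {
    ns <- .applyNoise(mass, noise)
    mass <- pmax(ns$value, 0)
  }
  tab <- DepositionTable(location, mass,
                         cutoff = c(NA, NA, cutoffs, NA),
                         flowRate = flowRate)
  gt <- .groundTruth("makeNgiTable",
                     list(totalDose = totalDose,
                          deviceFraction = deviceFraction, mmad = mmad,
                          gsd = gsd, cutoffs = cutoffs,
                          ipFraction = ipFraction,
                          noise = list(kind = noise@kind,
                                       level = noise@level)),
                     noise@seed)
  list(table = tab, groundTruth = gt)
}
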