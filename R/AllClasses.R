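#' @import methods
NULL

## ---------------------------------------------------------------------------
## Data containers
## ---------------------------------------------------------------------------

#' One-dimensional scattering curve on absolute scale
#'
#' Container for a reduced small- or wide-angle X-ray scattering curve:
#' momentum transfer \eqn{q} (\eqn{\mathrm{\AA}^{-1}}), excess scattered
#' intensity \eqn{I(q)} on absolute scale (\eqn{mm^{-1}}) and, optionally,
#' per-point uncertainties. Sample metadata (concentration in mg/mL, solvent,
#' composition label, ...) travels in the \code{meta} list.
#'
#' @slot q numeric, strictly increasing, all positive; \eqn{\mathrm{\AA}^{-1}}.
#' @slot intensity numeric, same length as \code{q}, finite; \eqn{mm^{-1}}.
#' @slot sigma numeric, either empty or same length as \code{q}, all positive.
#' @slot meta named list of sample descriptors. Conventional keys:
#'   \code{concentration} (mg/mL), \code{solvent} (\code{"water"} or
#'   \code{"PB"}), \code{label}.
#'
#' @seealso [ScatterCurve()] for the constructor, [readScatterCurve()] for
#'   file input.
#' @export
setClass("ScatterCurve",
  representation(q = "numeric", intensity = "numeric", sigma = "numeric",
                 meta = "list"),
  prototype(sigma = numeric(0), meta = list()))

setValidity("ScatterCurve", function(object) {
  msg <- character(0)
  q <- object@q
  if (length(q) == 0L) msg <- c(msg, "q must be non-empty")
  if (any(!is.finite(q)) || any(q <= 0)) msg <- c(msg, "q must be finite and > 0")
  if (length(q) > 1L && any(diff(q) <= 0)) msg <- c(msg, "q must be strictly increasing")
  if (length(object@intensity) != length(q))
    msg <- c(msg, "intensity must have the same length as q")
  if (any(!is.finite(object@intensity)))
    msg <- c(msg, "intensity must be finite")
  if (length(object@sigma) &&
      (length(object@sigma) != length(q) || any(!is.finite(object@sigma)) ||
       any(object@sigma <= 0)))
    msg <- c(msg, "sigma, when present, must be positive and match q in length")
  if (length(msg)) msg else TRUE
})

#' Construct a ScatterCurve
#'
#' @param q momentum transfer, \eqn{\mathrm{\AA}^{-1}}, strictly increasing.
#' @param intensity absolute intensity, \eqn{mm^{-1}}.
#' @param sigma optional per-point uncertainty, \eqn{mm^{-1}}.
#' @param meta named list of sample metadata.
#' @return A [ScatterCurve-class] object.
#' @examples
#' sc <- ScatterCurve(q = c(0.01, 0.02, 0.04), intensity = c(1, 0.5, 0.2))
#' qValues(sc)
#' @export
ScatterCurve <- function(q, intensity, sigma = NULL, meta = list()) {
  new("ScatterCurve", q = as.numeric(q), intensity = as.numeric(intensity),
      sigma = if (is.null(sigma)) numeric(0) else as.numeric(sigma),
      meta = meta)
}

#' Dynamic light scattering trace
#'
#' Intensity autocorrelation \eqn{g_2(\tau)} with the optical and solvent
#' conditions needed to convert decay rates to sizes.
#'
#' @slot tau lag time, seconds, strictly increasing.
#' @slot g2 intensity autocorrelation, dimensionless.
#' @slot setup named list: \code{wavelength} (nm), \code{angle} (degrees),
#'   \code{refractiveIndex}, \code{temperature} (K), \code{viscosity} (cP).
#' @export
setClass("DLSTrace",
  representation(tau = "numeric", g2 = "numeric", setup = "list"))

setValidity("DLSTrace", function(object) {
  msg <- character(0)
  if (length(object@tau) < 3L) msg <- c(msg, "need at least 3 lag points")
  if (any(object@tau <= 0) || any(diff(object@tau) <= 0))
    msg <- c(msg, "tau must be positive and strictly increasing")
  if (length(object@g2) != length(object@tau))
    msg <- c(msg, "g2 must match tau in length")
  need <- c("wavelength", "angle", "refractiveIndex", "temperature", "viscosity")
  if (!all(need %in% names(object@setup)))
    msg <- c(msg, paste("setup must contain:", paste(need, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a DLSTrace
#'
#' @param tau lag times, s.
#' @param g2 intensity autocorrelation values.
#' @param wavelength laser wavelength, nm.
#' @param angle scattering angle, degrees.
#' @param refractiveIndex solvent refractive index.
#' @param temperature absolute temperature, K.
#' @param viscosity solvent (solution) viscosity, cP.
#' @return A [DLSTrace-class] object.
#' @export
DLSTrace <- function(tau, g2, wavelength = 532, angle = 90,
                     refractiveIndex = 1.33, temperature = 298.15,
                     viscosity = 0.89) {
  new("DLSTrace", tau = as.numeric(tau), g2 = as.numeric(g2),
      setup = list(wavelength = wavelength, angle = angle,
                   refractiveIndex = refractiveIndex,
                   temperature = temperature, viscosity = viscosity))
}

#' Cascade-impactor deposition table
#'
#' Drug mass recovered at each location of a Next Generation Impactor run:
#' the device (nebulizer ampoule), the induction port (IP, grouped with its
#' adaptor), the sized stages with their aerodynamic cut-off diameters, and
#' the micro-orifice collector (MOC).
#'
#' @slot location character vector of location names, in deposition order.
#' @slot mass drug mass per location, micrograms, non-negative.
#' @slot cutoff aerodynamic cut-off diameter per location, micrometres;
#'   \code{NA} for unsized locations (device, IP, MOC). Cut-offs must be
#'   strictly decreasing over the sized stages.
#' @slot flowRate air flow, L/min (metadata).
#' @export
setClass("DepositionTable",
  representation(location = "character", mass = "numeric",
                 cutoff = "numeric", flowRate = "numeric"))

setValidity("DepositionTable", function(object) {
  msg <- character(0)
  n <- length(object@location)
  if (length(object@mass) != n || length(object@cutoff) != n)
    msg <- c(msg, "location, mass and cutoff must have equal length")
  if (any(object@mass < 0, na.rm = TRUE)) msg <- c(msg, "masses must be >= 0")
  cuts <- object@cutoff[!is.na(object@cutoff)]
  if (length(cuts) && any(diff(cuts) >= 0))
    msg <- c(msg, "stage cut-offs must be strictly decreasing")
  if (length(cuts) && any(cuts <= 0)) msg <- c(msg, "cut-offs must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a DepositionTable
#'
#' @param location location names; by convention \code{"device"}, \code{"IP"},
#'   \code{"stage1"}..\code{"stage7"}, \code{"MOC"}.
#' @param mass drug mass per location, ug.
#' @param cutoff cut-off diameter per location, um (\code{NA} where unsized).
#' @param flowRate air flow, L/min.
#' @return A [DepositionTable-class] object.
#' @export
DepositionTable <- function(location, mass, cutoff, flowRate = 15) {
  new("DepositionTable", location = as.character(location),
      mass = as.numeric(mass), cutoff = as.numeric(cutoff),
      flowRate = as.numeric(flowRate))
}

## ---------------------------------------------------------------------------
## Model parameter classes
## ---------------------------------------------------------------------------

#' Guinier model parameters
#'
#' \eqn{I(q) = I_0 \exp(-q^2 R_g^2 / 3)}; the low-q law for globular
#' scatterers, here the denser regions of hyaluronic acid in buffer.
#'
#' @slot I0 forward intensity, \eqn{mm^{-1}}, > 0.
#' @slot Rg gyration radius, \eqn{\mathrm{\AA}}, > 0.
#' @export
setClass("GuinierParams", representation(I0 = "numeric", Rg = "numeric"))
setValidity("GuinierParams", function(object) {
  if (object@I0 > 0 && object@Rg > 0) TRUE else "I0 and Rg must be > 0"
})

#' @rdname GuinierParams-class
#' @param I0 forward intensity, \eqn{mm^{-1}}.
#' @param Rg gyration radius, \eqn{\mathrm{\AA}}.
#' @export
GuinierParams <- function(I0, Rg) new("GuinierParams", I0 = I0, Rg = Rg)

#' Power-law decay parameters
#'
#' \eqn{I(q) = A\, q^{-s}}: the high-q conformational signature of a polymer
#' chain (s = 1 rigid rod, s = 2 random walk).
#'
#' @slot amplitude prefactor \eqn{A}, \eqn{mm^{-1}\mathrm{\AA}^{-s}}, > 0.
#' @slot s decay exponent, in \eqn{[0, 4]}.
#' @export
setClass("PowerLawParams", representation(amplitude = "numeric", s = "numeric"))
setValidity("PowerLawParams", function(object) {
  msg <- character(0)
  if (object@amplitude <= 0) msg <- c(msg, "amplitude must be > 0")
  if (object@s < 0 || object@s > 4) msg <- c(msg, "s must be in [0, 4]")
  if (length(msg)) msg else TRUE
})

#' @rdname PowerLawParams-class
#' @param amplitude prefactor.
#' @param s decay exponent.
#' @export
PowerLawParams <- function(amplitude, s) new("PowerLawParams",
                                             amplitude = amplitude, s = s)

#' Polyelectrolyte correlation-peak (broad peak) parameters
#'
#' Empirical lineshape for the inter-chain correlation peak of a salt-free
#' polyelectrolyte solution:
#' \deqn{I(q) = \frac{P}{1 + (|q - q_{peak}|/w)^m} +
#'   A\,\left[\mathrm{erf}(3\,q/q_{peak}/\sqrt 6)^3/q\right]^{t} + B}
#' with \eqn{m = 2} (Lorentzian). The second term behaves as \eqn{A q^{-t}}
#' above the peak and is cut off by the error-function crossover below it
#' (low-q scattering is suppressed in salt-free polyelectrolyte solutions,
#' and an undamped power law would otherwise dominate the peak at low q).
#' Only the peak position \eqn{q_{peak} = 2\pi/\xi} and the peak intensity
#' carry physical meaning; the lineshape itself is a package convention.
#'
#' @slot qPeak peak position, \eqn{\mathrm{\AA}^{-1}}, > 0.
#' @slot width peak half-width \eqn{w}, \eqn{\mathrm{\AA}^{-1}}, > 0.
#' @slot peakAmplitude Lorentzian amplitude \eqn{P}, \eqn{mm^{-1}}.
#' @slot background flat background \eqn{B}, \eqn{mm^{-1}}, >= 0.
#' @slot tailExponent high-q tail exponent \eqn{t}.
#' @slot tailAmplitude tail prefactor \eqn{A} (default 0).
#' @slot m Lorentzian exponent, default 2.
#' @export
setClass("BroadPeakParams",
  representation(qPeak = "numeric", width = "numeric",
                 peakAmplitude = "numeric", background = "numeric",
                 tailExponent = "numeric", tailAmplitude = "numeric",
                 m = "numeric"),
  prototype(background = 0, tailExponent = 0, tailAmplitude = 0, m = 2))
setValidity("BroadPeakParams", function(object) {
  msg <- character(0)
  if (object@qPeak <= 0) msg <- c(msg, "qPeak must be > 0")
  if (object@width <= 0) msg <- c(msg, "width must be > 0")
  if (object@peakAmplitude <= 0) msg <- c(msg, "peakAmplitude must be > 0")
  if (object@background < 0) msg <- c(msg, "background must be >= 0")
  if (object@tailAmplitude < 0) msg <- c(msg, "tailAmplitude must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname BroadPeakParams-class
#' @param qPeak,width,peakAmplitude,background,tailExponent,tailAmplitude,m
#'   see slots.
#' @export
BroadPeakParams <- function(qPeak, width, peakAmplitude, background = 0,
                            tailExponent = 0, tailAmplitude = 0, m = 2) {
  new("BroadPeakParams", qPeak = qPeak, width = width,
      peakAmplitude = peakAmplitude, background = background,
      tailExponent = tailExponent, tailAmplitude = tailAmplitude, m = m)
}

#' Guinier-power-law (Guinier-Porod) parameters
#'
#' Monotone empirical profile joining a Guinier regime at low q to a
#' power-law decay at high q with value-and-slope continuity at the
#' crossover \eqn{q_1 = \sqrt{3s/2}/R_g}:
#' \deqn{I(q) = I_0 e^{-q^2R_g^2/3} + B \quad (q \le q_1), \qquad
#'       I(q) = D\,q^{-s} + B \quad (q > q_1),}
#' with \eqn{D = I_0 e^{-q_1^2R_g^2/3} q_1^{s}}. Used as the salt-screened
#' (buffered) polymer profile -- which displays no correlation peak -- and as
#' the empirical mucin profile. The whole curve scales linearly in \eqn{I_0},
#' hence linearly in concentration when \eqn{I_0 \propto c}.
#'
#' @slot I0 Guinier forward intensity, \eqn{mm^{-1}}.
#' @slot Rg gyration radius, \eqn{\mathrm{\AA}}.
#' @slot s power-law exponent, in (0, 4].
#' @slot background flat background \eqn{B}, \eqn{mm^{-1}}.
#' @export
setClass("GuinierPowerLawParams",
  representation(I0 = "numeric", Rg = "numeric", s = "numeric",
                 background = "numeric"),
  prototype(background = 0))
setValidity("GuinierPowerLawParams", function(object) {
  ok <- object@I0 > 0 && object@Rg > 0 &&
    object@s > 0 && object@s <= 4 && object@background >= 0
  if (ok) TRUE else "invalid Guinier-power-law parameters"
})

#' @rdname GuinierPowerLawParams-class
#' @param I0,Rg,s,background see slots.
#' @export
GuinierPowerLawParams <- function(I0, Rg, s, background = 0) {
  new("GuinierPowerLawParams", I0 = I0, Rg = Rg, s = s,
      background = background)
}

#' Polydisperse core-shell sphere parameters
#'
#' Spherical particle with a homogeneous core and a concentric shell, number
#' averaged over a Schulz distribution of core radii (fixed shell thickness).
#' Lengths in \eqn{\mathrm{\AA}}, scattering length densities (SLD) in
#' \eqn{10^{-6}\,\mathrm{\AA}^{-2}}.
#'
#' @slot coreRadius mean core radius, \eqn{\mathrm{\AA}}, > 0.
#' @slot shellThickness shell thickness, \eqn{\mathrm{\AA}}, >= 0.
#' @slot sldCore,sldShell,sldSolvent scattering length densities,
#'   \eqn{10^{-6}\,\mathrm{\AA}^{-2}}.
#' @slot polydispersity relative width (sd/mean) of the core-radius
#'   distribution, in \eqn{[0, 1)}.
#' @slot scale volume-fraction-like multiplier, > 0.
#' @slot background flat background, \eqn{mm^{-1}}, >= 0.
#' @export
setClass("CoreShellParams",
  representation(coreRadius = "numeric", shellThickness = "numeric",
                 sldCore = "numeric", sldShell = "numeric",
                 sldSolvent = "numeric", polydispersity = "numeric",
                 scale = "numeric", background = "numeric"),
  prototype(polydispersity = 0, scale = 1, background = 0))
setValidity("CoreShellParams", function(object) {
  msg <- character(0)
  if (object@coreRadius <= 0) msg <- c(msg, "coreRadius must be > 0")
  if (object@shellThickness < 0) msg <- c(msg, "shellThickness must be >= 0")
  if (object@polydispersity < 0 || object@polydispersity >= 1)
    msg <- c(msg, "polydispersity must be in [0, 1)")
  if (object@scale <= 0) msg <- c(msg, "scale must be > 0")
  if (object@background < 0) msg <- c(msg, "background must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname CoreShellParams-class
#' @param coreRadius,shellThickness,sldCore,sldShell,sldSolvent,polydispersity,scale,background
#'   see slots.
#' @export
CoreShellParams <- function(coreRadius, shellThickness, sldCore, sldShell,
                            sldSolvent = 9.47, polydispersity = 0, scale = 1,
                            background = 0) {
  new("CoreShellParams", coreRadius = coreRadius,
      shellThickness = shellThickness, sldCore = sldCore, sldShell = sldShell,
      sldSolvent = sldSolvent, polydispersity = polydispersity, scale = scale,
      background = background)
}

#' Orthorhombic lattice
#'
#' @slot a,b,c cell edges, \eqn{\mathrm{\AA}}, all > 0.
#' @export
setClass("Lattice", representation(a = "numeric", b = "numeric", c = "numeric"))
setValidity("Lattice", function(object) {
  if (object@a > 0 && object@b > 0 && object@c > 0) TRUE
  else "all cell edges must be > 0"
})

#' @rdname Lattice-class
#' @param a,b,c cell edges, \eqn{\mathrm{\AA}}.
#' @export
Lattice <- function(a, b, c) new("Lattice", a = a, b = b, c = c)

#' Dexamethasone orthorhombic lattice
#'
#' The literature unit cell of crystalline dexamethasone
#' (a = 10.36, b = 16.16, c = 23.20 \eqn{\mathrm{\AA}}), used to index the
#' diffraction peaks of the nanocrystalline drug core.
#'
#' @return A [Lattice-class] object.
#' @examples
#' braggPositions(dexLattice(), hkl = rbind(c(0, 1, 1), c(0, 0, 2)))
#' @export
dexLattice <- function() Lattice(a = 10.36, b = 16.16, c = 23.20)

#' Noise model for the synthetic generators
#'
#' @slot kind one of \code{"none"}, \code{"gaussian_relative"},
#'   \code{"poisson_like"}.
#' @slot level relative noise level (sd/value), >= 0.
#' @slot seed integer seed; fully determines the noisy realization.
#' @export
setClass("NoiseModel",
  representation(kind = "character", level = "numeric", seed = "numeric"),
  prototype(kind = "gaussian_relative", level = 0.01, seed = 1))
setValidity("NoiseModel", function(object) {
  msg <- character(0)
  if (!object@kind %in% c("none", "gaussian_relative", "poisson_like"))
    msg <- c(msg, "unknown noise kind")
  if (object@level < 0) msg <- c(msg, "level must be >= 0")
  if (length(msg)) msg else TRUE
})

#' @rdname NoiseModel-class
#' @param kind,level,seed see slots.
#' @export
NoiseModel <- function(kind = "gaussian_relative", level = 0.01, seed = 1) {
  new("NoiseModel", kind = kind, level = level, seed = seed)
}

#' @rdname NoiseModel-class
#' @export
noNoise <- function() NoiseModel(kind = "none", level = 0)

## ---------------------------------------------------------------------------
## Result classes (one light S4 class per stage output)
## ---------------------------------------------------------------------------

#' Correlation-peak fit
#'
#' @slot found logical; \code{FALSE} is the explicit "no peak" outcome.
#' @slot qPeak peak position, \eqn{\mathrm{\AA}^{-1}}.
#' @slot xi inter-chain distance \eqn{\xi = 2\pi/q_{peak}}, \eqn{\mathrm{\AA}}.
#' @slot IPeak intensity at the peak, \eqn{mm^{-1}}.
#' @slot qPeakSE standard error on qPeak (NA when unavailable).
#' @export
setClass("PeakFit",
  representation(found = "logical", qPeak = "numeric", xi = "numeric",
                 IPeak = "numeric", qPeakSE = "numeric"),
  prototype(found = FALSE, qPeak = NA_real_, xi = NA_real_, IPeak = NA_real_,
            qPeakSE = NA_real_))
setValidity("PeakFit", function(object) {
  if (isTRUE(object@found) &&
      abs(object@xi * object@qPeak - 2 * pi) > 1e-9 * 2 * pi)
    "xi * qPeak must equal 2*pi" else TRUE
})

#' Concentration scaling fit (log-log regression)
#'
#' @slot exponent fitted exponent (slope in log-log).
#' @slot prefactor fitted prefactor.
#' @slot r2 coefficient of determination.
#' @slot ci 95% confidence interval on the exponent (length 2; NA for n = 2).
#' @slot n number of (c, value) pairs used.
#' @export
setClass("ScalingFit",
  representation(exponent = "numeric", prefactor = "numeric", r2 = "numeric",
                 ci = "numeric", n = "numeric"))

#' High-q power-law slope fit
#'
#' @slot s fitted decay exponent.
#' @slot window fit window (qMin, qMax), \eqn{\mathrm{\AA}^{-1}}.
#' @slot r2 coefficient of determination of the log-log fit.
#' @export
setClass("SlopeFit",
  representation(s = "numeric", window = "numeric", r2 = "numeric"))

#' Guinier fit
#'
#' @slot Rg gyration radius, \eqn{\mathrm{\AA}}.
#' @slot I0 forward intensity, \eqn{mm^{-1}}.
#' @slot window fit window (qMin, qMax) actually used.
#' @slot valid logical: all fitted points satisfy \eqn{q R_g \le} cutoff.
#' @slot nPoints number of points in the final window.
#' @export
setClass("GuinierFit",
  representation(Rg = "numeric", I0 = "numeric", window = "numeric",
                 valid = "logical", nPoints = "numeric"))

#' Bound/unbound polymer decomposition result
#'
#' @slot method one of \code{"subtraction"}, \code{"peak_position"},
#'   \code{"high_q_intensity"}, \code{"pb_discrepancy"}.
#' @slot boundFraction,unboundFraction fractions of the admixed polymer;
#'   always sum to 1.
#' @slot freeConcentration free (unbound) polymer concentration, mg/mL.
#' @slot npProfile nanoparticle contribution after removal of the unbound
#'   polymer component ([ScatterCurve-class] or NULL).
#' @slot residual goodness metric of the decomposition objective.
#' @slot clamped logical: TRUE when the raw estimate fell outside [0, 1].
#' @export
setClass("DecompositionResult",
  representation(method = "character", boundFraction = "numeric",
                 unboundFraction = "numeric", freeConcentration = "numeric",
                 npProfile = "ANY", residual = "numeric", clamped = "logical"),
  prototype(npProfile = NULL, residual = NA_real_, clamped = FALSE))
setValidity("DecompositionResult", function(object) {
  msg <- character(0)
  b <- object@boundFraction; u <- object@unboundFraction
  if (abs(b + u - 1) > 1e-12) msg <- c(msg, "bound + unbound must equal 1")
  if (b < 0 || b > 1) msg <- c(msg, "boundFraction must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' Linear-combination mixture test result
#'
#' @slot coefficients non-negative per-component weights.
#' @slot residualNorm relative residual norm of the reconstruction.
#' @slot interacting logical: residual above threshold.
#' @slot regionResiduals named numeric: relative residual in the low/mid/high
#'   q thirds of the fitted window.
#' @export
setClass("MixtureTestResult",
  representation(coefficients = "numeric", residualNorm = "numeric",
                 interacting = "logical", regionResiduals = "numeric"))
setValidity("MixtureTestResult", function(object) {
  if (any(object@coefficients < 0)) "coefficients must be >= 0"
  else if (object@residualNorm < 0) "residualNorm must be >= 0"
  else TRUE
})

#' Core-shell fit result
#'
#' @slot params fitted [CoreShellParams-class].
#' @slot se named per-parameter standard errors (NA where unavailable).
#' @slot chisq reduced chi-square (mean squared weighted residual).
#' @slot fitted list of fitted [ScatterCurve-class] curves (one per input).
#' @slot scales per-curve scale factors (shared-shape fits).
#' @slot atBound names of parameters that ended on a bound.
#' @slot converged logical.
#' @export
setClass("CoreShellFitResult",
  representation(params = "CoreShellParams", se = "numeric", chisq = "numeric",
                 fitted = "list", scales = "numeric", atBound = "character",
                 converged = "logical"))

#' WAXS crystallinity and indexing report
#'
#' @slot peaks data.frame of detected peaks: q, intensity, prominence, width.
#' @slot assignments data.frame: q, h, k, l, qBragg, deltaQ, nCandidates.
#' @slot crystalline logical.
#' @slot concentrationSlopes data.frame per assigned peak: slope of intensity
#'   versus concentration and its R^2 (empty unless a series is supplied).
#' @export
setClass("WaxsReport",
  representation(peaks = "data.frame", assignments = "data.frame",
                 crystalline = "logical", concentrationSlopes = "data.frame"),
  prototype(concentrationSlopes = data.frame()))
setValidity("WaxsReport", function(object) {
  if (!object@crystalline && nrow(object@assignments) > 0)
    "non-crystalline report cannot carry assignments" else TRUE
})

#' Hydrodynamic analysis result
#'
#' @slot D mean translational diffusion coefficient, \eqn{m^2/s}.
#' @slot DH hydrodynamic diameter, nm (Stokes-Einstein at the trace's T, eta).
#' @slot PDI polydispersity index \eqn{\mu_2/\Gamma^2}.
#' @slot beta Siegert coherence factor used.
#' @slot method \code{"cumulant"} or \code{"nnls"}.
#' @slot distribution list with \code{diameter} (nm) and \code{weight}
#'   vectors (NNLS method only; empty otherwise).
#' @export
setClass("HydroResult",
  representation(D = "numeric", DH = "numeric", PDI = "numeric",
                 beta = "numeric", method = "character",
                 distribution = "list"),
  prototype(distribution = list()))
setValidity("HydroResult", function(object) {
  if (object@D <= 0 || object@DH <= 0) "D and DH must be > 0"
  else if (object@PDI < -1e-6) "PDI must be >= 0"
  else TRUE
})

#' Zeta-potential summary
#'
#' @slot mean mean zeta potential, mV.
#' @slot sd sample standard deviation, mV (0 with \code{singleValue} flag for
#'   n = 1).
#' @slot n number of measurements.
#' @slot singleValue logical flag for n = 1.
#' @export
setClass("ZetaSummary",
  representation(mean = "numeric", sd = "numeric", n = "numeric",
                 singleValue = "logical"),
  prototype(singleValue = FALSE))

#' Aerodynamic performance result
#'
#' @slot MMAD mass median aerodynamic diameter, um.
#' @slot GSD geometric standard deviation (>= 1).
#' @slot ED emitted dose, ug.
#' @slot EF emitted fraction, percent of total recovered.
#' @slot FPD fine particle dose, ug.
#' @slot FPF fine particle fraction, percent of ED.
#' @slot r2 R^2 of the probit regression.
#' @slot extrapolated logical: MMAD outside the cut-off range.
#' @export
setClass("AeroResult",
  representation(MMAD = "numeric", GSD = "numeric", ED = "numeric",
                 EF = "numeric", FPD = "numeric", FPF = "numeric",
                 r2 = "numeric", extrapolated = "logical"),
  prototype(extrapolated = FALSE))
setValidity("AeroResult", function(object) {
  msg <- character(0)
  if (!is.na(object@GSD) && object@GSD < 1) msg <- c(msg, "GSD must be >= 1")
  if (!is.na(object@EF) && (object@EF < 0 || object@EF > 100))
    msg <- c(msg, "EF must lie in [0, 100]")
  if (!is.na(object@FPF) && (object@FPF < 0 || object@FPF > 100))
    msg <- c(msg, "FPF must lie in [0, 100]")
  if (!is.na(object@FPD) && !is.na(object@ED) &&
      object@FPD > object@ED + 1e-9 * max(1, object@ED))
    msg <- c(msg, "FPD cannot exceed ED")
  if (length(msg)) msg else TRUE
})

#' Drug loading result
#'
#' @slot capacity loading capacity, percent w/w.
#' @slot efficiency loading efficiency, percent of nominal.
#' @export
setClass("LoadingResult",
  representation(capacity = "numeric", efficiency = "numeric"))
setValidity("LoadingResult", function(object) {
  if (object@capacity < 0 || object@capacity > 100)
    "capacity must lie in [0, 100]"
  else if (object@efficiency <= 0) "efficiency must be > 0"
  else TRUE
})
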