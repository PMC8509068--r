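#' Evaluate a scattering model on a q grid
#'
#' Pointwise forward evaluation of a closed-form scattering model. A plain
#' list of models evaluates to the sum of the members' intensities
#' (contributions add linearly).
#'
#' @param model a model parameter object ([GuinierParams-class],
#'   [PowerLawParams-class], [BroadPeakParams-class],
#'   [GuinierPowerLawParams-class], [CoreShellParams-class]) or a list of
#'   them.
#' @param q momentum-transfer grid, \eqn{\mathrm{\AA}^{-1}}, strictly
#'   increasing and positive.
#' @param ... method-specific arguments (e.g. \code{nodes} for the
#'   polydisperse core-shell average).
#' @return Numeric intensity vector, \eqn{mm^{-1}}.
#' @examples
#' q <- c(0.005, 0.01, 0.02)
#' evalModel(GuinierParams(I0 = 1, Rg = 98), q)
#' @export
setGeneric("evalModel", function(model, q, ...) standardGeneric("evalModel"))

## --- ScatterCurve accessors -------------------------------------------------

#' @describeIn ScatterCurve-class momentum-transfer vector.
#' @param x,object a \code{ScatterCurve}.
#' @export
setGeneric("qValues", function(x) standardGeneric("qValues"))

#' @describeIn ScatterCurve-class intensity vector.
#' @export
setGeneric("intensityValues", function(x) standardGeneric("intensityValues"))

#' @describeIn ScatterCurve-class uncertainty vector (length 0 when absent).
#' @export
setGeneric("sigmaValues", function(x) standardGeneric("sigmaValues"))

#' @describeIn ScatterCurve-class metadata list.
#' @export
setGeneric("curveMeta", function(x) standardGeneric("curveMeta"))

setMethod("qValues", "ScatterCurve", function(x) x@q)
setMethod("intensityValues", "ScatterCurve", function(x) x@intensity)
setMethod("sigmaValues", "ScatterCurve", function(x) x@sigma)
setMethod("curveMeta", "ScatterCurve", function(x) x@meta)

#' @describeIn ScatterCurve-class number of points.
#' @export
setMethod("length", "ScatterCurve", function(x) length(x@q))

setMethod("show", "ScatterCurve", function(object) {
  cat(sprintf("ScatterCurve: %d points, q in [%.4g, %.4g] A^-1%s\n",
              length(object@q), min(object@q), max(object@q),
              if (length(object@sigma)) ", with sigma" else ""))
  if (length(object@meta)) {
    keys <- vapply(object@meta, function(v) paste(format(v), collapse = ","),
                   character(1))
    cat("  meta:", paste(names(keys), keys, sep = "=", collapse = "; "), "\n")
  }
})

#' Coerce a ScatterCurve to a data.frame
#'
#' @param x a [ScatterCurve-class].
#' @param ... unused.
#' @return data.frame with columns \code{q}, \code{intensity} and, when
#'   present, \code{sigma}.
#' @export
as.data.frame.ScatterCurve <- function(x, ...) {
  df <- data.frame(q = x@q, intensity = x@intensity)
  if (length(x@sigma)) df$sigma <- x@sigma
  df
}

## --- DLSTrace / DepositionTable accessors ----------------------------------

#' @describeIn DLSTrace-class lag-time vector, s.
#' @param x,object a \code{DLSTrace}.
#' @export
setGeneric("tauValues", function(x) standardGeneric("tauValues"))

#' @describeIn DLSTrace-class autocorrelation vector.
#' @export
setGeneric("g2Values", function(x) standardGeneric("g2Values"))

#' @describeIn DLSTrace-class instrument/solvent setup list.
#' @export
setGeneric("dlsSetup", function(x) standardGeneric("dlsSetup"))

setMethod("tauValues", "DLSTrace", function(x) x@tau)
setMethod("g2Values", "DLSTrace", function(x) x@g2)
setMethod("dlsSetup", "DLSTrace", function(x) x@setup)

setMethod("show", "DLSTrace", function(object) {
  s <- object@setup
  cat(sprintf(
    "DLSTrace: %d lags in [%.3g, %.3g] s | %g nm, %g deg, n=%g, T=%g K, eta=%g cP\n",
    length(object@tau), min(object@tau), max(object@tau), s$wavelength,
    s$angle, s$refractiveIndex, s$temperature, s$viscosity))
})

#' Coerce a DepositionTable to a data.frame
#'
#' @param x a [DepositionTable-class].
#' @param ... unused.
#' @export
as.data.frame.DepositionTable <- function(x, ...) {
  data.frame(location = x@location, mass_ug = x@mass, cutoff_um = x@cutoff)
}

#' @describeIn DepositionTable-class per-location masses, ug, named by
#'   location.
#' @param x,object a \code{DepositionTable}.
#' @export
setGeneric("stageMasses", function(x) standardGeneric("stageMasses"))
setMethod("stageMasses", "DepositionTable",
          function(x) stats::setNames(x@mass, x@location))

#' @describeIn DepositionTable-class stage cut-off diameters, um, named by
#'   location (sized stages only).
#' @export
setGeneric("stageCutoffs", function(x) standardGeneric("stageCutoffs"))
setMethod("stageCutoffs", "DepositionTable", function(x) {
  keep <- !is.na(x@cutoff)
  stats::setNames(x@cutoff[keep], x@location[keep])
})

setMethod("show", "DepositionTable", function(object) {
  cat(sprintf("DepositionTable: %d locations, %.4g ug total, %g L/min\n",
              length(object@location), sum(object@mass), object@flowRate))
  print(as.data.frame.DepositionTable(object), row.names = FALSE)
})

## --- compact show methods for parameter and result classes ------------------

.showSlots <- function(object, title, digits = 4) {
  cat(title, "\n", sep = "")
  for (nm in slotNames(class(object))) {
    v <- slot(object, nm)
    if (is.numeric(v) || is.logical(v) || is.character(v)) {
      if (length(v) > 6) v <- c(format(v[1:6]), "...")
      cat(sprintf("  %s: %s\n", nm, paste(format(v, digits = digits),
                                          collapse = " ")))
    }
  }
  invisible(NULL)
}

setMethod("show", "GuinierParams", function(object)
  .showSlots(object, "GuinierParams (I0 mm^-1, Rg A)"))
setMethod("show", "PowerLawParams", function(object)
  .showSlots(object, "PowerLawParams"))
setMethod("show", "BroadPeakParams", function(object)
  .showSlots(object, "BroadPeakParams (q A^-1, I mm^-1)"))
setMethod("show", "GuinierPowerLawParams", function(object)
  .showSlots(object, "GuinierPowerLawParams"))
setMethod("show", "CoreShellParams", function(object)
  .showSlots(object, "CoreShellParams (lengths A, SLD 1e-6 A^-2)"))
setMethod("show", "Lattice", function(object)
  .showSlots(object, "Orthorhombic Lattice (A)"))
setMethod("show", "NoiseModel", function(object)
  .showSlots(object, "NoiseModel"))
setMethod("show", "PeakFit", function(object) {
  if (!object@found) cat("PeakFit: no peak found\n")
  else .showSlots(object, "PeakFit (q A^-1, xi A)")
})
setMethod("show", "ScalingFit", function(object)
  .showSlots(object, "ScalingFit: value ~ prefactor * c^exponent"))
setMethod("show", "SlopeFit", function(object)
  .showSlots(object, "SlopeFit: I(q) ~ q^-s"))
setMethod("show", "GuinierFit", function(object)
  .showSlots(object, "GuinierFit (Rg A)"))
setMethod("show", "DecompositionResult", function(object)
  .showSlots(object, sprintf("DecompositionResult [%s]", object@method)))
setMethod("show", "MixtureTestResult", function(object)
  .showSlots(object, "MixtureTestResult"))
setMethod("show", "CoreShellFitResult", function(object) {
  cat("CoreShellFitResult\n")
  show(object@params)
  cat(sprintf("  chisq: %.4g | converged: %s%s\n", object@chisq,
              object@converged,
              if (length(object@atBound))
                paste0(" | at bound: ", paste(object@atBound, collapse = ","))
              else ""))
})
setMethod("show", "WaxsReport", function(object) {
  cat(sprintf("WaxsReport: crystalline = %s, %d peak(s) detected\n",
              object@crystalline, nrow(object@peaks)))
  if (nrow(object@assignments)) print(object@assignments, row.names = FALSE)
})
setMethod("show", "HydroResult", function(object)
  .showSlots(object, sprintf("HydroResult [%s] (D m^2/s, DH nm)",
                             object@method)))
setMethod("show", "ZetaSummary", function(object)
  .showSlots(object, "ZetaSummary (mV)"))
setMethod("show", "AeroResult", function(object)
  .showSlots(object, "AeroResult (MMAD um, doses ug, fractions %)"))
setMethod("show", "LoadingResult", function(object)
  .showSlots(object, "LoadingResult (%)"))

## --- result accessors --------------------------------------------------------

#' @describeIn PeakFit-class peak position \eqn{q_{peak}}.
#' @param x,object a \code{PeakFit}.
#' @export
setGeneric("qPeak", function(x) standardGeneric("qPeak"))
setMethod("qPeak", "PeakFit", function(x) x@qPeak)

#' @describeIn PeakFit-class inter-chain distance \eqn{\xi}.
#' @export
setGeneric("interchainDistance", function(x) standardGeneric("interchainDistance"))
setMethod("interchainDistance", "PeakFit", function(x) x@xi)

#' @describeIn PeakFit-class TRUE when a peak was located.
#' @export
setGeneric("peakFound", function(x) standardGeneric("peakFound"))
setMethod("peakFound", "PeakFit", function(x) x@found)

#' @describeIn ScalingFit-class fitted exponent.
#' @param x,object a \code{ScalingFit}.
#' @export
setGeneric("scalingExponent", function(x) standardGeneric("scalingExponent"))
setMethod("scalingExponent", "ScalingFit", function(x) x@exponent)

#' @describeIn ScalingFit-class fitted prefactor.
#' @export
setGeneric("scalingPrefactor", function(x) standardGeneric("scalingPrefactor"))
setMethod("scalingPrefactor", "ScalingFit", function(x) x@prefactor)

#' @describeIn GuinierFit-class fitted gyration radius, \eqn{\mathrm{\AA}}.
#' @param x,object a \code{GuinierFit}.
#' @export
setGeneric("gyrationRadius", function(x) standardGeneric("gyrationRadius"))
setMethod("gyrationRadius", "GuinierFit", function(x) x@Rg)

#' @describeIn DecompositionResult-class bound fraction.
#' @param x,object a \code{DecompositionResult}.
#' @export
setGeneric("boundFraction", function(x) standardGeneric("boundFraction"))
setMethod("boundFraction", "DecompositionResult", function(x) x@boundFraction)

#' @describeIn DecompositionResult-class unbound fraction.
#' @export
setGeneric("unboundFraction", function(x) standardGeneric("unboundFraction"))
setMethod("unboundFraction", "DecompositionResult",
          function(x) x@unboundFraction)

#' @describeIn DecompositionResult-class free polymer concentration, mg/mL.
#' @export
setGeneric("freeConcentration", function(x) standardGeneric("freeConcentration"))
setMethod("freeConcentration", "DecompositionResult",
          function(x) x@freeConcentration)

#' @describeIn CoreShellFitResult-class fitted parameter object.
#' @param x,object a \code{CoreShellFitResult}.
#' @export
setGeneric("coreShellParams", function(x) standardGeneric("coreShellParams"))
setMethod("coreShellParams", "CoreShellFitResult", function(x) x@params)

#' @describeIn HydroResult-class hydrodynamic diameter, nm.
#' @param x,object a \code{HydroResult}.
#' @export
setGeneric("hydroDiameter", function(x) standardGeneric("hydroDiameter"))
setMethod("hydroDiameter", "HydroResult", function(x) x@DH)

#' @describeIn HydroResult-class polydispersity index.
#' @export
setGeneric("polydispersityIndex", function(x) standardGeneric("polydispersityIndex"))
setMethod("polydispersityIndex", "HydroResult", function(x) x@PDI)

#' @describeIn AeroResult-class named numeric vector of the six aerodynamic
#'   parameters.
#' @param x,object an \code{AeroResult}.
#' @export
setGeneric("aeroSummary", function(x) standardGeneric("aeroSummary"))
setMethod("aeroSummary", "AeroResult", function(x)
  c(MMAD = x@MMAD, GSD = x@GSD, ED = x@ED, EF = x@EF, FPD = x@FPD,
    FPF = x@FPF))
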