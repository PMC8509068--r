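## Aerodynamic performance from impactor deposition tables, plus the
## formulation arithmetic (loading, fractions, size percentiles).

#' Aerodynamic parameters from a cascade-impactor run
#'
#' Computes the standard inhalation performance metrics from a deposition
#' table:
#' \itemize{
#'   \item ED (emitted dose): drug mass from the induction port to the MOC;
#'   \item EF\%: ED as a percentage of the total drug recovered;
#'   \item FPD (fine particle dose): drug mass from stage 3 to the MOC
#'     (aerodynamic diameter below ~5 um at the nominal flow);
#'   \item FPF\%: FPD as a percentage of ED;
#'   \item MMAD and GSD from probit regression: the cumulative undersize
#'     fraction of the sized mass at each stage cut-off is transformed by the
#'     inverse standard-normal CDF and regressed linearly on
#'     \eqn{\log_{10}}(cut-off); the MMAD is the diameter at probit 0 and the
#'     GSD is \eqn{\sqrt{d_{hi}/d_{lo}}} at the configured percentile pair.
#' }
#' Cumulative fractions of exactly 0 or 1 are excluded from the probit fit.
#' When every sized point lies on one side of the median the MMAD is an
#' extrapolation and is flagged as such.
#'
#' @param table a [DepositionTable-class].
#' @param fineStage first location counted into the FPD (default
#'   \code{"stage3"}).
#' @param gsdPercentiles \code{"standard"} (84.13/15.87, exact for a
#'   lognormal) or \code{"rounded"} (85/16).
#' @return An [AeroResult-class]. With all mass in the device (ED = 0) the
#'   ratios are reported as \code{NA}.
#' @examples
#' ngi <- makeNgiTable(1000, deviceFraction = 0.75, mmad = 3, gsd = 1.8,
#'                     cutoffs = c(14.1, 8.61, 5.39, 3.3, 2.08, 1.36, 0.98),
#'                     noise = noNoise())
#' aeroSummary(aerodynamicParams(ngi$table))
#' @export
aerodynamicParams <- function(table, fineStage = "stage3",
                              gsdPercentiles = c("standard", "rounded")) {
  stopifnot(is(table, "DepositionTable"))
  validObject(table)
  gsdPercentiles <- match.arg(gsdPercentiles)
  loc <- table@location; mass <- table@mass; cutoff <- table@cutoff
  total <- sum(mass)
  iDevice <- which(loc == "device")
  iIP <- which(loc == "IP")
  iMOC <- which(loc == "MOC")
  sized <- which(!is.na(cutoff))
  if (!length(sized)) stop("no sized stages in the table")

  emittedIdx <- setdiff(seq_along(loc), iDevice)
  ED <- sum(mass[emittedIdx])
  EF <- if (total > 0) 100 * ED / total else NA_real_

  iFine <- which(loc == fineStage)
  if (!length(iFine)) stop("fineStage not found in the table")
  fineIdx <- seq(from = iFine, to = max(c(sized, iMOC)))
  FPD <- sum(mass[fineIdx])
  FPF <- if (ED > 0) 100 * FPD / ED else NA_real_

  ## probit regression on the sized (stage + MOC) mass only; the device and
  ## the size-independent IP bite carry no size information
  sizedMass <- sum(mass[sized]) + if (length(iMOC)) mass[iMOC] else 0
  if (ED <= 0 || sizedMass <= 0)
    return(new("AeroResult", MMAD = NA_real_, GSD = NA_real_, ED = ED,
               EF = EF, FPD = FPD, FPF = NA_real_, r2 = NA_real_,
               extrapolated = FALSE))
  cuts <- cutoff[sized]
  ## undersize at cut-off d: everything on stages below + MOC
  under <- rev(cumsum(rev(c(mass[sized], if (length(iMOC)) mass[iMOC]))))[-1] /
    sizedMass
  keep <- under > 0 & under < 1
  if (sum(keep) < 2) {
    ## entire mass on one side of every cut-off: the median is outside the
    ## sized range and cannot be located, only bracketed
    return(new("AeroResult", MMAD = NA_real_, GSD = NA_real_, ED = ED,
               EF = EF, FPD = FPD, FPF = FPF, r2 = NA_real_,
               extrapolated = TRUE))
  }
  z <- stats::qnorm(under[keep])
  lf <- .linfit(log10(cuts[keep]), z)
  mmad <- 10^(-lf$intercept / lf$slope)
  ## "standard" = the 84.13/15.87 pair, i.e. exactly +/-1 sd of the probit
  ## line (exact for a lognormal); "rounded" = the 85/16 convention
  zPair <- if (gsdPercentiles == "standard") c(1, -1) else
    stats::qnorm(c(0.85, 0.16))
  dPair <- 10^((zPair - lf$intercept) / lf$slope)
  gsd <- sqrt(dPair[1] / dPair[2])
  extrapolated <- mmad < min(cuts) || mmad > max(cuts)
  new("AeroResult", MMAD = mmad, GSD = max(gsd, 1), ED = ED, EF = EF,
      FPD = FPD, FPF = FPF,
      r2 = if (is.null(lf$r2)) NA_real_ else lf$r2,
      extrapolated = extrapolated)
}

#' Drug loading capacity and efficiency
#'
#' Capacity is the measured drug content of the powder (percent w/w);
#' efficiency is the measured content as a percentage of the nominal one.
#'
#' @param measuredContent measured drug content, percent w/w, in (0, 100].
#' @param nominalContent nominal drug content, percent w/w, in (0, 100].
#' @return A [LoadingResult-class].
#' @examples
#' loadingMetrics(34.3, 45)  # capacity 34.3%, efficiency 76.2%
#' @export
loadingMetrics <- function(measuredContent, nominalContent) {
  if (measuredContent <= 0 || measuredContent > 100 ||
      nominalContent <= 0 || nominalContent > 100)
    stop("contents must lie in (0, 100]")
  new("LoadingResult", capacity = measuredContent,
      efficiency = 100 * measuredContent / nominalContent)
}

#' Formulation mole/mass fractions and anti-solvent volume
#'
#' Converts component masses and molar masses to mole and mass fractions
#' (\eqn{x_i = (m_i/M_i)/\sum_j m_j/M_j}) and computes the anti-solvent
#' volume percentage from the solvent volumes.
#'
#' @param masses named component masses (any common unit).
#' @param molarMasses molar masses, g/mol, same order/names.
#' @param antisolventVolumes volumes of anti-solvent additions, mL.
#' @param solventVolumes volumes of the solvent phase, mL.
#' @return list with \code{moleFractions}, \code{massFractions} and, when
#'   volumes are given, \code{antisolventPct} (\% v/v).
#' @examples
#' formulationFractions(c(HYA = 55, DEX = 45),
#'                      molarMasses = c(HYA = 750000, DEX = 392.5),
#'                      antisolventVolumes = c(29.5, 14.5),
#'                      solventVolumes = 36)
#' @export
formulationFractions <- function(masses, molarMasses = NULL,
                                 antisolventVolumes = NULL,
                                 solventVolumes = NULL) {
  if (any(masses <= 0)) stop("masses must be > 0")
  out <- list(massFractions = masses / sum(masses))
  if (!is.null(molarMasses)) {
    if (any(molarMasses <= 0)) stop("molar masses must be > 0")
    mol <- masses / molarMasses
    out$moleFractions <- mol / sum(mol)
  }
  if (!is.null(antisolventVolumes) && !is.null(solventVolumes)) {
    vA <- sum(antisolventVolumes); vS <- sum(solventVolumes)
    if (vA + vS <= 0) stop("zero total volume")
    out$antisolventPct <- 100 * vA / (vA + vS)
  }
  out
}

#' Volume-weighted size percentiles
#'
#' Dv(10), Dv(50) and Dv(90) by linear interpolation on the cumulative
#' volume curve of a diameter distribution.
#'
#' @param diameter diameters, um, increasing.
#' @param volumeWeight volume weights, >= 0, summing to > 0.
#' @param probs percentiles to report (fractions).
#' @return named numeric vector of diameters, um.
#' @examples
#' volumePercentiles(c(5, 10, 15), c(1, 2, 1))
#' @export
volumePercentiles <- function(diameter, volumeWeight,
                              probs = c(0.1, 0.5, 0.9)) {
  if (!length(diameter) || length(diameter) != length(volumeWeight))
    stop("diameter and volumeWeight must be non-empty and equal length")
  if (any(volumeWeight < 0) || sum(volumeWeight) <= 0)
    stop("weights must be >= 0 with positive sum")
  ord <- order(diameter)
  d <- diameter[ord]; w <- volumeWeight[ord]
  if (length(d) == 1L)
    return(stats::setNames(rep(d, length(probs)),
                           sprintf("Dv%02.0f", 100 * probs)))
  cum <- cumsum(w) / sum(w)
  ## midpoint convention: each point carries half its weight below it
  cumMid <- cum - w / (2 * sum(w))
  out <- stats::approx(cumMid, d, xout = probs, rule = 2, ties = "ordered")$y
  stats::setNames(out, sprintf("Dv%02.0f", 100 * probs))
}
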