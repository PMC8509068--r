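## Quantification of bound vs unbound polymer in reconstituted nanoparticle
## spectra, and mucin-stability testing by linear combination.

#' Free-polymer model at an arbitrary concentration
#'
#' Builds the expected SAXS contribution of free polymer at concentration
#' \code{conc} from measured (or synthetic) reference curves at known
#' concentrations.
#'
#' In salt-free water the polyelectrolyte spectra are self-similar under the
#' \eqn{\sqrt{c}} scaling laws, so a single reference at \eqn{c_0} maps onto
#' any concentration by the rigid log-log shift
#' \eqn{I_c(q) = \sqrt{c/c_0}\, I_{c_0}(q\sqrt{c_0/c})}. In buffer no peak
#' exists and the reference amplitude is scaled linearly in concentration
#' (nearest reference; per-q log-log interpolation across references when
#' several are given).
#'
#' @param reference a [ScatterCurve-class] or list of them, each carrying
#'   \code{concentration} in its metadata.
#' @param conc target concentration, mg/mL.
#' @param solvent \code{"water"} or \code{"PB"}.
#' @param qOut output q grid; defaults to the (first) reference grid.
#' @return A [ScatterCurve-class] of the modelled free-polymer intensity.
#' @export
hyaModelAtConcentration <- function(reference, conc, solvent = "water",
                                    qOut = NULL) {
  if (is(reference, "ScatterCurve")) reference <- list(reference)
  solvent <- match.arg(solvent, c("water", "PB"))
  if (conc < 0) stop("conc must be >= 0")
  concs <- vapply(reference, function(r) r@meta$concentration %||% NA_real_,
                  numeric(1))
  if (any(is.na(concs))) stop("reference curves must carry a concentration")
  if (is.null(qOut)) qOut <- reference[[1]]@q
  if (conc == 0)
    return(ScatterCurve(qOut, numeric(length(qOut)) + 1e-300,
                        meta = list(concentration = 0, solvent = solvent)))
  if (solvent == "water") {
    ## nearest reference, then the sqrt(c) self-similar shift
    ref <- reference[[which.min(abs(log(concs / conc)))]]
    c0 <- ref@meta$concentration
    I <- sqrt(conc / c0) *
      .interpLogLog(ref@q * sqrt(conc / c0), ref@intensity, qOut,
                    extrapolate = TRUE)
  } else if (length(reference) >= 2L) {
    ## per-q log-log regression of intensity on concentration
    grid <- qOut
    mats <- vapply(reference, function(r)
      .interpLogLog(r@q, r@intensity, grid, extrapolate = TRUE),
      numeric(length(grid)))
    lc <- log(concs)
    lcBar <- mean(lc)
    slope <- as.vector(log(mats) %*% (lc - lcBar)) / sum((lc - lcBar)^2)
    intercept <- rowMeans(log(mats)) - slope * lcBar
    I <- exp(intercept + slope * log(conc))
  } else {
    ref <- reference[[1]]
    I <- (conc / concs[1]) * .interpLogLog(ref@q, ref@intensity, qOut,
                                           extrapolate = TRUE)
  }
  ScatterCurve(qOut, pmax(I, 1e-300),
               meta = list(concentration = conc, solvent = solvent))
}

## joint 1-D fit of the free-polymer concentration in an intensity window:
## I_mix(q) ~ I_hya(q; c) + A q^-4 + B  (A, B >= 0 absorb the residual
## nanoparticle Porod tail and flat background), minimized over c.
.fitFreeConcIntensity <- function(curve, reference, solvent, qWindow,
                                  cMax) {
  keep <- which(curve@q >= qWindow[1] & curve@q <= qWindow[2])
  if (length(keep) < 10L) stop("intensity window must contain >= 10 points")
  q <- curve@q[keep]; I <- curve@intensity[keep]
  w <- 1 / pmax(I, 1e-300)          # relative weighting
  design <- cbind(porod = q^-4, flat = rep(1, length(q)))
  obj <- function(cc) {
    hya <- hyaModelAtConcentration(reference, cc, solvent, qOut = q)@intensity
    r <- I - hya
    sol <- pracma::lsqnonneg(design * w, r * w)
    mean(((design %*% sol$x - r) * w)^2)
  }
  opt <- stats::optimize(obj, interval = c(1e-4 * cMax, cMax), tol = 1e-6)
  list(cFree = opt$minimum, residual = opt$objective)
}

#' Quantify the unbound polymer fraction
#'
#' Decomposes reconstituted nanoparticle spectra into a nanoparticle
#' contribution and the contribution of polymer free in solution, reporting
#' the bound/unbound split of the admixed polymer. Four parallel methods are
#' provided:
#' \describe{
#'   \item{\code{peak_position}}{(salt-free water only) the correlation peak
#'     of the mixture lies on the free-polymer scaling curve at the free --
#'     not the nominal -- concentration: \eqn{c_{free}} is read off by
#'     inverting the \eqn{q_{peak}(c)} calibration.}
#'   \item{\code{high_q_intensity}}{\eqn{c_{free}} from the absolute
#'     intensity of the free-polymer contribution in the high-q window,
#'     via a per-q intensity-concentration calibration; the residual
#'     nanoparticle Porod tail and a flat background are absorbed by
#'     non-negative nuisance terms.}
#'   \item{\code{pb_discrepancy}}{same intensity analysis for buffered
#'     (peak-free) samples against buffered references.}
#'   \item{\code{subtraction}}{two or more mixture curves at different total
#'     concentrations: candidate unbound fractions are scanned jointly and
#'     the fractions minimizing the incongruence of the
#'     concentration-normalized residual spectra are selected (identical
#'     nanoparticles must give residuals that coincide after rigid scaling).
#'     The congruence objective runs over \code{subtractionWindow}, which
#'     must include the correlation-peak region: in the far tail the
#'     free-polymer contributions of all samples share the same \eqn{q^{-s}}
#'     shape and carry no information on the split.}
#' }
#'
#' @param npCurves a [ScatterCurve-class] or list of them
#'   (\code{subtraction} needs at least two at different concentrations).
#' @param hyaReference free-polymer reference curve(s) at known
#'   concentrations (same solvent as the mixtures).
#' @param nominalHyaConc nominal admixed polymer concentration, mg/mL, one
#'   value per curve (polymer mass fraction times total concentration).
#' @param method decomposition method, see above.
#' @param qWindow intensity window for the intensity-based methods; default
#'   \code{c(0.06, 0.7)} \eqn{\mathrm{\AA}^{-1}}.
#' @param subtractionWindow congruence window for the subtraction method;
#'   default \code{c(0.01, 0.15)} \eqn{\mathrm{\AA}^{-1}}.
#' @param peakCalibration optional [ScalingFit-class] of \eqn{q_{peak}}
#'   versus concentration; computed from \code{hyaReference} when absent.
#' @param solvent \code{"water"} or \code{"PB"}; defaults to the curve
#'   metadata, else water.
#' @return A [DecompositionResult-class], or a list of them (one per curve)
#'   for \code{subtraction} with several inputs. Estimates falling outside
#'   [0, 1] are clamped, with the \code{clamped} flag raised.
#' @examples
#' np <- CoreShellParams(coreRadius = 1000, shellThickness = 15,
#'                       sldCore = 11.8, sldShell = 16, polydispersity = 0.1)
#' refs <- makeHyaWaterSeries(c(2.8, 5.6, 11.2), noise = noNoise())$curves
#' mix <- makeNpMixture(np, totalConc = 20, boundFraction = 0.25,
#'                      noise = noNoise())
#' dr <- freeFraction(mix$curve, refs, nominalHyaConc = 0.55 * 20,
#'                    method = "peak_position")
#' unboundFraction(dr)
#' @export
freeFraction <- function(npCurves, hyaReference, nominalHyaConc,
                         method = c("peak_position", "high_q_intensity",
                                    "pb_discrepancy", "subtraction"),
                         qWindow = c(0.06, 0.7),
                         subtractionWindow = c(0.01, 0.15),
                         peakCalibration = NULL, solvent = NULL) {
  method <- match.arg(method)
  if (is(npCurves, "ScatterCurve")) npCurves <- list(npCurves)
  if (is(hyaReference, "ScatterCurve")) hyaReference <- list(hyaReference)
  if (length(nominalHyaConc) == 1L)
    nominalHyaConc <- rep(nominalHyaConc, length(npCurves))
  stopifnot(length(nominalHyaConc) == length(npCurves))
  if (is.null(solvent))
    solvent <- npCurves[[1]]@meta$solvent %||% "water"

  makeResult <- function(mth, cFree, nominal, curve, residual = NA_real_) {
    clamped <- cFree > nominal || cFree < 0
    unbound <- min(max(cFree / nominal, 0), 1)
    npProf <- tryCatch({
      hyaC <- hyaModelAtConcentration(hyaReference, unbound * nominal,
                                      solvent, qOut = curve@q)
      extractNpProfile(curve, hyaC)
    }, error = function(e) NULL)
    new("DecompositionResult", method = mth, boundFraction = 1 - unbound,
        unboundFraction = unbound, freeConcentration = unbound * nominal,
        npProfile = npProf, residual = residual, clamped = clamped)
  }

  if (method == "peak_position") {
    if (identical(solvent, "PB"))
      stop("peak_position requires a salt-free (water) sample: buffered spectra display no correlation peak")
    if (is.null(peakCalibration)) {
      pk <- lapply(hyaReference, findCorrelationPeak)
      if (any(!vapply(pk, peakFound, logical(1))))
        stop("no correlation peak in one or more reference curves")
      peakCalibration <- fitScaling(
        vapply(hyaReference, function(r) r@meta$concentration, numeric(1)),
        vapply(pk, qPeak, numeric(1)))
    }
    out <- lapply(seq_along(npCurves), function(i) {
      pk <- findCorrelationPeak(npCurves[[i]])
      if (!peakFound(pk))
        stop("no correlation peak in the mixture curve; use an intensity-based method")
      cFree <- (pk@qPeak / peakCalibration@prefactor)^(1 / peakCalibration@exponent)
      makeResult(method, cFree, nominalHyaConc[i], npCurves[[i]])
    })
    return(if (length(out) == 1L) out[[1]] else out)
  }

  if (method %in% c("high_q_intensity", "pb_discrepancy")) {
    if (method == "pb_discrepancy" && !identical(solvent, "PB"))
      warning("pb_discrepancy is intended for buffered samples")
    out <- lapply(seq_along(npCurves), function(i) {
      fit <- .fitFreeConcIntensity(npCurves[[i]], hyaReference, solvent,
                                   qWindow, cMax = 1.5 * nominalHyaConc[i])
      refConcs <- vapply(hyaReference,
                         function(r) r@meta$concentration, numeric(1))
      if (fit$cFree > max(refConcs) * 1.2 || fit$cFree < min(refConcs) / 1.2)
        warning("inferred free concentration extrapolates beyond the calibration range")
      makeResult(method, fit$cFree, nominalHyaConc[i], npCurves[[i]],
                 residual = fit$residual)
    })
    return(if (length(out) == 1L) out[[1]] else out)
  }

  ## subtraction: joint scan of per-curve unbound fractions for congruent,
  ## rigidly-scaled residual nanoparticle spectra
  if (length(npCurves) < 2L)
    stop("subtraction requires at least two mixture curves at different total concentrations")
  totConc <- vapply(npCurves, function(cu)
    cu@meta$concentration %||% NA_real_, numeric(1))
  if (any(is.na(totConc)))
    stop("subtraction requires total concentrations in the curve metadata")
  qRef <- npCurves[[1]]@q
  keep <- which(qRef >= subtractionWindow[1] & qRef <= subtractionWindow[2])
  qW <- qRef[keep]

  residLog <- function(i, f) {
    cu <- npCurves[[i]]
    hya <- hyaModelAtConcentration(hyaReference, f * nominalHyaConc[i],
                                   solvent, qOut = qW)@intensity
    mixI <- .interpLogLog(cu@q, cu@intensity, qW, extrapolate = TRUE)
    r <- mixI - hya
    bad <- mean(r <= 0)
    r <- pmax(r, 1e-12 * max(mixI))
    list(logn = log(r / totConc[i]), bad = bad)
  }
  objective <- function(fs) {
    rl <- lapply(seq_along(npCurves), function(i) residLog(i, fs[i]))
    penalty <- sum(vapply(rl, `[[`, numeric(1), "bad"))
    tot <- 0; npair <- 0
    for (i in seq_along(rl)) for (j in seq_len(i - 1L)) {
      tot <- tot + mean((rl[[i]]$logn - rl[[j]]$logn)^2)
      npair <- npair + 1
    }
    tot / npair + penalty
  }
  n <- length(npCurves)
  grid <- seq(0.05, 1, by = 0.05)
  if (n == 2L) {
    gridPts <- as.matrix(expand.grid(grid, grid))
  } else {
    ## coarse scan along the diagonal (common fraction), refined per-curve
    gridPts <- matrix(rep(grid, n), ncol = n)
  }
  vals <- apply(gridPts, 1, objective)
  start <- gridPts[which.min(vals), ]
  opt <- stats::optim(start, objective, method = "L-BFGS-B",
                      lower = rep(1e-3, n), upper = rep(1, n))
  fs <- opt$par
  out <- lapply(seq_along(npCurves), function(i)
    makeResult(method, fs[i] * nominalHyaConc[i], nominalHyaConc[i],
               npCurves[[i]], residual = opt$value))
  if (length(out) == 1L) out[[1]] else out
}

#' Subtract the free-polymer contribution from a mixture spectrum
#'
#' Pointwise difference between a mixture curve and the modelled free-polymer
#' contribution (interpolated onto the mixture grid). Negative differences
#' are handled per policy; the count of negative points is recorded in the
#' result metadata (\code{negativePoints}) -- a large count signals
#' oversubtraction.
#'
#' @param npCurve mixture [ScatterCurve-class].
#' @param hyaModel free-polymer contribution: a [ScatterCurve-class] or a
#'   model parameter object evaluable by [evalModel()].
#' @param clipNegative \code{"floor"} (default: clamp at 0) or \code{"keep"}.
#' @return A [ScatterCurve-class] of the nanoparticle contribution.
#' @export
extractNpProfile <- function(npCurve, hyaModel,
                             clipNegative = c("floor", "keep")) {
  clipNegative <- match.arg(clipNegative)
  stopifnot(is(npCurve, "ScatterCurve"))
  hyaI <- if (is(hyaModel, "ScatterCurve")) {
    if (min(npCurve@q) < min(hyaModel@q) * (1 - 1e-9) ||
        max(npCurve@q) > max(hyaModel@q) * (1 + 1e-9))
      stop("q grids not alignable by interpolation")
    .interpLogLog(hyaModel@q, hyaModel@intensity, npCurve@q,
                  extrapolate = TRUE)
  } else evalModel(hyaModel, npCurve@q)
  diff <- npCurve@intensity - hyaI
  nNeg <- sum(diff < 0)
  if (clipNegative == "floor") diff <- pmax(diff, 0)
  meta <- npCurve@meta
  meta$negativePoints <- nNeg
  meta$label <- paste0(meta$label %||% "curve", " (free polymer removed)")
  out <- ScatterCurve(npCurve@q, diff, meta = meta)
  out
}

#' Mucin-stability (linear combination) test
#'
#' Tests whether a mixture spectrum is reproduced by a non-negative linear
#' combination of its single-component spectra over the whole q range, the
#' signature of structurally non-interacting components. Coefficients are
#' obtained by (sigma-weighted) non-negative least squares; the relative
#' residual norm is compared against a threshold, and residuals are also
#' reported per q region (low/mid/high thirds in log q) since incipient
#' interaction typically appears at low q only.
#'
#' @param mixture mixture [ScatterCurve-class].
#' @param components list of component [ScatterCurve-class]s (interpolated
#'   onto the mixture grid as needed).
#' @param residualThreshold relative residual norm above which the mixture is
#'   flagged as interacting; default 0.05.
#' @return A [MixtureTestResult-class].
#' @examples
#' a <- makeMucinCurve(1, noise = noNoise())$curve
#' b <- makeHyaPbSeries(5.6, noise = noNoise())$curves[[1]]
#' mix <- ScatterCurve(qValues(a), intensityValues(a) + intensityValues(b))
#' mucinStabilityTest(mix, list(a, b))
#' @export
mucinStabilityTest <- function(mixture, components, residualThreshold = 0.05) {
  stopifnot(is(mixture, "ScatterCurve"))
  if (is(components, "ScatterCurve")) components <- list(components)
  if (!length(components)) stop("need at least one component")
  q <- mixture@q
  X <- vapply(components, function(cu) {
    if (min(q) < min(cu@q) * (1 - 1e-9) || max(q) > max(cu@q) * (1 + 1e-9))
      stop("component grid does not cover the mixture grid")
    .interpLogLog(cu@q, cu@intensity, q, extrapolate = TRUE)
  }, numeric(length(q)))
  X <- as.matrix(X)
  if (all(X == 0)) stop("degenerate (all-zero) components")
  ## sigma-weighted when uncertainties exist; otherwise relative residuals,
  ## so every decade of the spectrum carries comparable weight
  w <- if (length(mixture@sigma)) 1 / mixture@sigma else
    1 / pmax(mixture@intensity, 1e-300)
  sol <- pracma::lsqnonneg(X * w, mixture@intensity * w)
  fit <- drop(X %*% sol$x)
  relNorm <- function(idx) {
    num <- sqrt(sum((w[idx] * (mixture@intensity[idx] - fit[idx]))^2))
    den <- sqrt(sum((w[idx] * mixture@intensity[idx])^2))
    num / den
  }
  all <- relNorm(seq_along(q))
  breaks <- exp(seq(log(min(q)), log(max(q)), length.out = 4))
  regions <- c(low = relNorm(which(q <= breaks[2])),
               mid = relNorm(which(q > breaks[2] & q <= breaks[3])),
               high = relNorm(which(q > breaks[3])))
  new("MixtureTestResult",
      coefficients = stats::setNames(sol$x, vapply(components, function(cu)
        cu@meta$label %||% "component", character(1))),
      residualNorm = all,
      interacting = all > residualThreshold ||
        any(regions > residualThreshold),
      regionResiduals = regions)
}
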