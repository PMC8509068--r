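## Correlation-peak, scaling, slope and Guinier descriptors of polymer
## solutions (the salt-free / buffered HYA characterization stage).

#' Locate the polyelectrolyte correlation peak
#'
#' Finds the broad inter-chain correlation peak of a salt-free
#' polyelectrolyte solution and converts its position to the inter-chain
#' distance \eqn{\xi = 2\pi/q_{peak}}. The discrete maximum inside the search
#' window is refined to sub-grid precision by a parabolic fit to
#' log-intensity over +/-5 surrounding points. A curve without an interior
#' local maximum (e.g. any buffered sample) yields the explicit "no peak"
#' outcome (\code{peakFound(x)} is \code{FALSE}).
#'
#' @param curve a [ScatterCurve-class].
#' @param searchWindow optional \code{c(qMin, qMax)}; default
#'   \code{c(0.01, 0.3)} \eqn{\mathrm{\AA}^{-1}}, the polyelectrolyte-peak
#'   regime (excludes both the nanoparticle low-q upturn and any crystalline
#'   reflections at higher q).
#' @param halfPoints grid points on each side of the discrete maximum used in
#'   the parabolic refinement.
#' @return A [PeakFit-class].
#' @examples
#' ser <- makeHyaWaterSeries(5.6, noise = noNoise())
#' findCorrelationPeak(ser$curves[[1]])
#' @export
findCorrelationPeak <- function(curve, searchWindow = c(0.01, 0.3),
                                halfPoints = 5) {
  stopifnot(is(curve, "ScatterCurve"))
  q <- curve@q; I <- curve@intensity
  inWin <- which(q >= searchWindow[1] & q <= searchWindow[2])
  if (length(inWin) < 10L)
    stop("search window must contain at least 10 points")
  qi <- q[inWin]; Ii <- I[inWin]
  ## candidate = most prominent interior local maximum of the median-smoothed
  ## log curve; prominence in log units, so a correlation peak riding on the
  ## steep nanoparticle upturn is still found while noise bumps on a
  ## monotone decay are not
  s <- stats::runmed(log(pmax(Ii, .Machine$double.xmin)), 7)
  n <- length(s)
  isMax <- c(FALSE, s[2:(n - 1)] > s[1:(n - 2)] & s[2:(n - 1)] >= s[3:n],
             FALSE)
  cand <- which(isMax)
  if (!length(cand)) return(new("PeakFit", found = FALSE))
  prom <- vapply(cand, function(i) {
    higherL <- which(s[seq_len(i - 1)] > s[i])
    lo <- if (length(higherL)) max(higherL) else 1L
    higherR <- which(s[(i + 1):n] > s[i]) + i
    hi <- if (length(higherR)) min(higherR) else n
    s[i] - max(min(s[lo:i]), min(s[i:hi]))
  }, numeric(1))
  best <- cand[which.max(prom)]
  if (max(prom) < 0.1) return(new("PeakFit", found = FALSE))
  iMax <- best
  if (iMax <= 1L || iMax >= length(Ii)) return(new("PeakFit", found = FALSE))
  idx <- max(1, iMax - halfPoints):min(length(Ii), iMax + halfPoints)
  x <- qi[idx]; y <- log(pmax(Ii[idx], .Machine$double.xmin))
  fit <- stats::lm(y ~ x + I(x^2))
  cf <- stats::coef(fit)
  if (!is.finite(cf[3]) || cf[3] >= 0) return(new("PeakFit", found = FALSE))
  qPeak <- unname(-cf[2] / (2 * cf[3]))
  if (qPeak < min(x) || qPeak > max(x)) qPeak <- qi[iMax]
  ## delta-method standard error of the vertex from the quadratic fit
  se <- tryCatch({
    V <- stats::vcov(fit)
    gr <- c(0, -1 / (2 * cf[3]), cf[2] / (2 * cf[3]^2))
    sqrt(drop(t(gr) %*% V %*% gr))
  }, error = function(e) NA_real_)
  iPeak <- exp(stats::predict(fit,
                              newdata = data.frame(x = qPeak))[[1]])
  new("PeakFit", found = TRUE, qPeak = qPeak, xi = 2 * pi / qPeak,
      IPeak = iPeak, qPeakSE = se)
}

#' Fit a concentration scaling law
#'
#' Least-squares line in \eqn{\log(\mathrm{value})} versus \eqn{\log c}:
#' the exponent is the slope, the prefactor the exponentiated intercept.
#' Used to test the polyelectrolyte predictions
#' \eqn{q_{peak} \propto c^{1/2}} and \eqn{I(q_{peak}) \propto c^{1/2}}.
#'
#' @param concentration concentrations, mg/mL, all > 0.
#' @param value measured quantity at each concentration, all > 0.
#' @return A [ScalingFit-class].
#' @examples
#' scalingExponent(fitScaling(c(1, 4), c(2, 4)))  # 0.5
#' @export
fitScaling <- function(concentration, value) {
  if (length(concentration) < 2L || length(value) != length(concentration))
    stop("need at least 2 (concentration, value) pairs of equal length")
  if (any(concentration <= 0) || any(value <= 0))
    stop("concentrations and values must be > 0")
  lf <- .linfit(log(concentration), log(value))
  ci <- if (length(concentration) > 2L)
    tryCatch(suppressWarnings(unname(stats::confint(lf$fit)[2, ])),
             error = function(e) c(NA_real_, NA_real_))
  else c(NA_real_, NA_real_)
  new("ScalingFit", exponent = lf$slope, prefactor = exp(lf$intercept),
      r2 = if (is.null(lf$r2)) NA_real_ else lf$r2, ci = ci,
      n = length(concentration))
}

#' Fit the high-q power-law slope
#'
#' Log-log linear fit of \eqn{I(q) = q^{-s}} over the high-q window, the
#' conformational signature of the chains (s near 1: rod-like; s = 2:
#' random walk).
#'
#' @param curve a [ScatterCurve-class].
#' @param qMin lower edge of the fit window, \eqn{\mathrm{\AA}^{-1}};
#'   default 0.25.
#' @param qMax upper edge; defaults to the end of the curve.
#' @return A [SlopeFit-class].
#' @export
fitHighQSlope <- function(curve, qMin = 0.25, qMax = NULL) {
  stopifnot(is(curve, "ScatterCurve"))
  if (is.null(qMax)) qMax <- max(curve@q)
  keep <- which(curve@q >= qMin & curve@q <= qMax & curve@intensity > 0)
  if (length(keep) < 10L) stop("fewer than 10 points above qMin")
  w <- if (length(curve@sigma))
    (curve@intensity[keep] / curve@sigma[keep])^2 else NULL
  lf <- .linfit(log(curve@q[keep]), log(curve@intensity[keep]), w)
  new("SlopeFit", s = -lf$slope, window = c(qMin, qMax),
      r2 = if (is.null(lf$r2)) NA_real_ else lf$r2)
}

#' Guinier fit with iterative window selection
#'
#' Linear fit of \eqn{\ln I} versus \eqn{q^2}
#' (\eqn{I(q) = I_0 e^{-q^2R_g^2/3}}), iteratively restricting the window
#' until every fitted point satisfies \eqn{q R_g \le} \code{qRgMax}
#' (default 1.3, the conventional validity limit for globular scatterers).
#' Increasing intensity at low q (a negative apparent \eqn{R_g^2}, the
#' aggregation signature) is an error.
#'
#' @param curve a [ScatterCurve-class].
#' @param qRgMax Guinier validity cutoff on \eqn{q R_g}.
#' @param minPoints minimum number of points in the final window.
#' @param maxIter iteration cap for the window search.
#' @return A [GuinierFit-class].
#' @examples
#' g <- makeGuinierCurve(I0 = 1, Rg = 98, noise = noNoise())
#' gyrationRadius(fitGuinier(g$curve))
#' @export
fitGuinier <- function(curve, qRgMax = 1.3, minPoints = 5, maxIter = 50) {
  stopifnot(is(curve, "ScatterCurve"))
  q <- curve@q; I <- curve@intensity
  pos <- I > 0
  q <- q[pos]; I <- I[pos]
  if (length(q) < minPoints) stop("too few positive low-q points")
  sig <- if (length(curve@sigma)) curve@sigma[pos] else NULL

  fitWindow <- function(keep) {
    w <- if (!is.null(sig)) (I[keep] / sig[keep])^2 else NULL
    lf <- .linfit(q[keep]^2, log(I[keep]), w)
    lf
  }
  ## initial window: out to where the (smoothed) intensity has fallen to
  ## half its forward value, i.e. qRg ~ 1.4 -- robust to noise at the
  ## near-flat low-q end; if the curve never decays that far, use all points
  ## and let the slope sign decide
  sm <- if (length(I) >= 7) stats::runmed(I, 7) else I
  i0 <- stats::median(sm[seq_len(min(5L, length(sm)))])
  cross <- which(sm < 0.5 * i0)
  keep <- if (length(cross)) seq_len(max(minPoints, cross[1]))
          else seq_along(q)
  lastN <- -1L
  for (it in seq_len(maxIter)) {
    lf <- fitWindow(keep)
    if (lf$slope >= 0)
      stop("intensity increases at low q (negative Rg^2): aggregation or invalid window")
    rg <- sqrt(-3 * lf$slope)
    newKeep <- which(q * rg <= qRgMax)
    if (length(newKeep) < minPoints)
      newKeep <- seq_len(minPoints)
    if (length(newKeep) == lastN) break
    lastN <- length(newKeep)
    keep <- newKeep
  }
  lf <- fitWindow(keep)
  if (lf$slope >= 0)
    stop("intensity increases at low q (negative Rg^2): aggregation or invalid window")
  rg <- sqrt(-3 * lf$slope)
  valid <- all(q[keep] * rg <= qRgMax * (1 + 1e-6))
  new("GuinierFit", Rg = rg, I0 = exp(lf$intercept),
      window = c(min(q[keep]), max(q[keep])), valid = valid,
      nPoints = length(keep))
}

#' Per-sample polymer-solution summary
#'
#' Convenience wrapper running peak location, high-q slope and (for buffered
#' samples) Guinier analysis on a list of curves, returning the stage summary
#' table.
#'
#' @param curves list of [ScatterCurve-class] with \code{concentration} and
#'   \code{solvent} metadata.
#' @param qMinSlope lower edge of the slope window.
#' @return data.frame with one row per curve: concentration, solvent,
#'   qPeak, xi, IPeak, s, Rg.
#' @export
polymerSolutionSummary <- function(curves, qMinSlope = 0.25) {
  rows <- lapply(curves, function(cu) {
    meta <- cu@meta
    pk <- tryCatch(findCorrelationPeak(cu), error = function(e)
      new("PeakFit", found = FALSE))
    sl <- tryCatch(fitHighQSlope(cu, qMin = qMinSlope),
                   error = function(e) NULL)
    gu <- if (identical(meta$solvent, "PB"))
      tryCatch(fitGuinier(cu), error = function(e) NULL) else NULL
    data.frame(concentration = meta$concentration %||% NA_real_,
               solvent = meta$solvent %||% NA_character_,
               qPeak = if (pk@found) pk@qPeak else NA_real_,
               xi = if (pk@found) pk@xi else NA_real_,
               IPeak = if (pk@found) pk@IPeak else NA_real_,
               s = if (is.null(sl)) NA_real_ else sl@s,
               Rg = if (is.null(gu)) NA_real_ else gu@Rg)
  })
  do.call(rbind, rows)
}
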