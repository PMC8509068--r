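## Core-shell form-factor fitting of decomposed nanoparticle spectra, and
## WAXS crystallinity / Bragg indexing.

.csParamVector <- function(params) {
  c(coreRadius = params@coreRadius, shellThickness = params@shellThickness,
    sldCore = params@sldCore, sldShell = params@sldShell,
    sldSolvent = params@sldSolvent, polydispersity = params@polydispersity,
    scale = params@scale, background = params@background)
}

.csFromVector <- function(v) {
  CoreShellParams(coreRadius = v[["coreRadius"]],
                  shellThickness = max(v[["shellThickness"]], 0),
                  sldCore = v[["sldCore"]], sldShell = v[["sldShell"]],
                  sldSolvent = v[["sldSolvent"]],
                  polydispersity = min(max(v[["polydispersity"]], 0), 0.999),
                  scale = v[["scale"]], background = max(v[["background"]], 0))
}

#' Fit the polydisperse core-shell model to decomposed spectra
#'
#' Bounded Levenberg-Marquardt least squares of [evalCoreShell()] against one
#' or more nanoparticle spectra (after removal of the free-polymer
#' contribution). With several curves and \code{sharedShape = TRUE} a single
#' set of shape parameters is fitted with one scale factor per curve -- the
#' appropriate model when the same particles are measured at different
#' concentrations or in different redispersion solvents. Because the
#' form-factor objective is oscillatory, the optimizer is restarted from
#' \code{multiStart} deterministically jittered initial values and the best
#' minimum is kept.
#'
#' Residuals are \eqn{(I_{model} - I)/\sigma} when uncertainties are present
#' and logarithmic (\eqn{\log I_{model} - \log I}) otherwise, so that the
#' many decades of a SAXS curve contribute comparably.
#'
#' @param curves a [ScatterCurve-class] or list of them.
#' @param init initial [CoreShellParams-class].
#' @param free names of parameters to vary; default core radius, shell
#'   thickness, polydispersity, scale and background (SLDs are usually known
#'   from composition and fixed).
#' @param lower,upper optional named bounds on the free parameters.
#' @param sharedShape share shape parameters across curves with per-curve
#'   scales (default when several curves are given).
#' @param multiStart number of jittered starts (>= 1).
#' @param jitter relative jitter of the starting values.
#' @param nodes quadrature nodes for the polydispersity average.
#' @param maxIter Levenberg-Marquardt iteration cap per start.
#' @return A [CoreShellFitResult-class].
#' @examples
#' \donttest{
#' truth <- CoreShellParams(coreRadius = 1000, shellThickness = 15,
#'                          sldCore = 11.8, sldShell = 16,
#'                          polydispersity = 0.1, scale = 1e-3)
#' q <- defaultQGrid(150)
#' cur <- ScatterCurve(q, evalCoreShell(truth, q))
#' fit <- fitCoreShell(cur, init = truth)
#' coreShellParams(fit)
#' }
#' @export
fitCoreShell <- function(curves, init,
                         free = c("coreRadius", "shellThickness",
                                  "polydispersity", "scale", "background"),
                         lower = NULL, upper = NULL, sharedShape = TRUE,
                         multiStart = 5, jitter = 0.1, nodes = 61,
                         maxIter = 100) {
  if (is(curves, "ScatterCurve")) curves <- list(curves)
  stopifnot(is(init, "CoreShellParams"))
  validObject(init)
  if (init@sldCore == init@sldShell && init@sldShell == init@sldSolvent)
    stop("zero contrast (sldCore = sldShell = sldSolvent): model unidentifiable")
  for (cu in curves) {
    if (min(cu@q) * (init@coreRadius + init@shellThickness) > 3)
      warning("q range may not constrain the particle size (qMin * R > 3)")
  }
  full <- .csParamVector(init)
  free <- match.arg(free, names(full), several.ok = TRUE)
  nCurve <- length(curves)
  shared <- sharedShape && nCurve > 1L
  if (shared) free <- setdiff(free, "scale")

  defLower <- c(coreRadius = full[["coreRadius"]] / 5,
                shellThickness = 0.1, sldCore = -5, sldShell = -5,
                sldSolvent = -5, polydispersity = 0,
                scale = full[["scale"]] / 1e3, background = 0)
  defUpper <- c(coreRadius = full[["coreRadius"]] * 5,
                shellThickness = max(10 * full[["shellThickness"]], 100),
                sldCore = 30, sldShell = 30, sldSolvent = 30,
                polydispersity = 0.6, scale = full[["scale"]] * 1e3,
                background = max(full[["background"]] * 1e3, 1))
  lo <- defLower[free]; hi <- defUpper[free]
  if (!is.null(lower)) lo[names(lower)] <- lower
  if (!is.null(upper)) hi[names(upper)] <- upper
  start0 <- pmin(pmax(full[free], lo), hi)
  nShape <- length(start0)
  if (shared) {
    start0 <- c(start0, logScale = rep(log(full[["scale"]]), nCurve))
    lo <- c(lo, rep(log(full[["scale"]] / 1e3), nCurve))
    hi <- c(hi, rep(log(full[["scale"]] * 1e3), nCurve))
  }

  residFun <- function(par) {
    v <- full
    v[free] <- par[seq_len(nShape)]
    unlist(lapply(seq_len(nCurve), function(i) {
      vi <- v
      if (shared) vi["scale"] <- exp(par[nShape + i])
      p <- .csFromVector(vi)
      I <- evalCoreShell(p, curves[[i]]@q, nodes = nodes)
      if (length(curves[[i]]@sigma))
        (I - curves[[i]]@intensity) / curves[[i]]@sigma
      else log(pmax(I, 1e-300)) - log(pmax(curves[[i]]@intensity, 1e-300))
    }))
  }

  ## deterministic jitter pattern: start 1 is the supplied init
  jitterMat <- .withSeed(20201, matrix(stats::runif(multiStart *
                                                     length(start0), -1, 1),
                                       nrow = multiStart))
  best <- NULL
  for (k in seq_len(multiStart)) {
    sk <- if (k == 1) start0 else
      pmin(pmax(start0 * (1 + jitter * jitterMat[k, ]), lo), hi)
    fit <- tryCatch(minpack.lm::nls.lm(
      par = sk, fn = residFun, lower = lo, upper = hi,
      control = minpack.lm::nls.lm.control(maxiter = maxIter)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance))
      best <- fit
  }
  if (is.null(best)) stop("core-shell fit failed to converge from any start")

  par <- best$par
  v <- full; v[free] <- par[seq_len(nShape)]
  scales <- if (shared) unname(exp(par[nShape + seq_len(nCurve)])) else
    rep(v[["scale"]], nCurve)
  if (shared) v["scale"] <- scales[1]
  params <- .csFromVector(v)

  se <- rep(NA_real_, length(free))
  names(se) <- free
  seAll <- tryCatch(summary(best)$coefficients[, "Std. Error"],
                    error = function(e) NULL)
  if (!is.null(seAll)) se[] <- seAll[seq_len(nShape)]

  atBound <- free[abs(par[seq_len(nShape)] - lo[seq_len(nShape)]) <
                    1e-8 * pmax(abs(lo[seq_len(nShape)]), 1) |
                  abs(par[seq_len(nShape)] - hi[seq_len(nShape)]) <
                    1e-8 * pmax(abs(hi[seq_len(nShape)]), 1)]
  nObs <- sum(vapply(curves, length, numeric(1)))
  nPar <- length(par)
  fitted <- lapply(seq_len(nCurve), function(i) {
    pi <- params
    pi@scale <- scales[i]
    ScatterCurve(curves[[i]]@q, evalCoreShell(pi, curves[[i]]@q,
                                              nodes = nodes),
                 meta = curves[[i]]@meta)
  })
  new("CoreShellFitResult", params = params, se = se,
      chisq = best$deviance / max(nObs - nPar, 1), fitted = fitted,
      scales = scales, atBound = as.character(atBound),
      converged = best$info %in% 1:4)
}

#' WAXS crystallinity analysis and Bragg indexing
#'
#' Detects diffraction peaks as local maxima of the residual over a
#' rolling-median background, requiring a prominence of at least
#' \code{prominenceFactor} times the robust residual scale (MAD), at least
#' \code{minRelProminence} of the local background, and a half-prominence
#' width below \code{maxRelWidth} times the peak position (crystalline
#' reflections are narrow; broad diffuse maxima such as the polyelectrolyte
#' correlation peak are never flagged as crystalline). Detected
#' peaks are assigned to the nearest reflection of the lattice within
#' \code{matchTolerance}; ties are broken by lowest \eqn{|h|+|k|+|l|}, and
#' ambiguous matches (several reflections within tolerance) are reported in
#' the \code{nCandidates} column with a warning rather than silently
#' resolved.
#'
#' @param curve a [ScatterCurve-class] covering the diffraction window.
#' @param lattice a [Lattice-class]; defaults to the dexamethasone cell.
#' @param matchTolerance assignment tolerance, \eqn{\mathrm{\AA}^{-1}}.
#' @param concentrationSeries optional named list with \code{curves} (list of
#'   [ScatterCurve-class]) and \code{concentrations}; per-peak heights are
#'   then regressed against concentration (a crystalline drug load scales
#'   linearly).
#' @param prominenceFactor MAD multiplier for the detection threshold.
#' @param minRelProminence minimum prominence relative to the local
#'   background.
#' @param maxRelWidth maximum half-prominence width as a fraction of the
#'   peak position.
#' @return A [WaxsReport-class].
#' @examples
#' pat <- makeWaxsPattern(noise = noNoise())
#' analyzeWaxs(pat$curve)
#' @export
analyzeWaxs <- function(curve, lattice = dexLattice(), matchTolerance = 0.01,
                        concentrationSeries = NULL, prominenceFactor = 3,
                        minRelProminence = 0.2, maxRelWidth = 0.1) {
  stopifnot(is(curve, "ScatterCurve"))
  validObject(lattice)

  detect <- function(cu) {
    I <- cu@intensity; q <- cu@q; n <- length(q)
    k <- max(7L, 2L * floor(0.04 * n) + 1L)
    bg <- stats::runmed(I, k, endrule = "median")
    resid <- I - bg
    scl <- stats::mad(resid)
    if (scl == 0) scl <- 1e-12 * max(abs(I))
    isMax <- c(FALSE, resid[2:(n - 1)] > resid[1:(n - 2)] &
                 resid[2:(n - 1)] >= resid[3:n], FALSE)
    hit <- which(isMax & resid > prominenceFactor * scl &
                   resid > minRelProminence * pmax(bg, 1e-300))
    if (!length(hit))
      return(data.frame(q = numeric(0), intensity = numeric(0),
                        prominence = numeric(0), width = numeric(0)))
    ## half-prominence width around each maximum
    width <- vapply(hit, function(i) {
      half <- resid[i] / 2
      l <- i; while (l > 1 && resid[l] > half) l <- l - 1
      r <- i; while (r < n && resid[r] > half) r <- r + 1
      q[r] - q[l]
    }, numeric(1))
    out <- data.frame(q = q[hit], intensity = I[hit],
                      prominence = resid[hit], width = width)
    out[out$width <= maxRelWidth * out$q, , drop = FALSE]
  }

  peaks <- detect(curve)
  crystalline <- nrow(peaks) > 0
  assignments <- data.frame()
  if (crystalline) {
    refl <- braggPositions(lattice, qMax = max(curve@q) + matchTolerance)
    rows <- lapply(seq_len(nrow(peaks)), function(i) {
      dq <- abs(refl$q - peaks$q[i])
      cand <- which(dq <= matchTolerance)
      if (!length(cand)) return(NULL)
      ord <- order(dq[cand], abs(refl$h[cand]) + abs(refl$k[cand]) +
                     abs(refl$l[cand]))
      bestIdx <- cand[ord[1]]
      data.frame(q = peaks$q[i], h = refl$h[bestIdx], k = refl$k[bestIdx],
                 l = refl$l[bestIdx], qBragg = refl$q[bestIdx],
                 deltaQ = dq[bestIdx], nCandidates = length(cand))
    })
    assignments <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
    if (is.null(assignments)) assignments <- data.frame()
    if (nrow(assignments) && any(assignments$nCandidates > 1))
      warning("ambiguous assignment: several reflections within tolerance; nearest reported")
  }

  slopes <- data.frame()
  if (!is.null(concentrationSeries) && nrow(assignments)) {
    cs <- concentrationSeries
    stopifnot(length(cs$curves) == length(cs$concentrations))
    slopes <- do.call(rbind, lapply(seq_len(nrow(assignments)), function(i) {
      q0 <- assignments$q[i]
      h <- vapply(cs$curves, function(cu) {
        pk <- detect(cu)
        if (!nrow(pk)) return(NA_real_)
        j <- which.min(abs(pk$q - q0))
        if (abs(pk$q[j] - q0) > matchTolerance) NA_real_ else pk$prominence[j]
      }, numeric(1))
      ok <- !is.na(h)
      if (sum(ok) < 2) return(NULL)
      lf <- .linfit(cs$concentrations[ok], h[ok])
      data.frame(q = q0, slope = lf$slope,
                 r2 = if (is.null(lf$r2)) NA_real_ else lf$r2)
    }))
    if (is.null(slopes)) slopes <- data.frame()
  }

  new("WaxsReport", peaks = peaks, assignments = assignments,
      crystalline = crystalline, concentrationSlopes = slopes)
}
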