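## Closed-form forward models for every scattering signal the pipeline
## generates or fits.

## sphere form-factor amplitude 3(sin x - x cos x)/x^3, f(0) = 1
## series expansion below x = 0.01 avoids catastrophic cancellation
.sphereAmp <- function(x) {
  out <- numeric(length(x))
  small <- x < 1e-2
  xs <- x[small]
  out[small] <- 1 - xs^2 / 10 + xs^4 / 280
  xl <- x[!small]
  out[!small] <- 3 * (sin(xl) - xl * cos(xl)) / xl^3
  out
}

#' @describeIn evalModel Guinier law \eqn{I_0 \exp(-q^2 R_g^2/3)}.
#' @export
setMethod("evalModel", signature(model = "GuinierParams"),
  function(model, q, ...) {
    if (any(q < 0)) stop("q must be >= 0")
    model@I0 * exp(-q^2 * model@Rg^2 / 3)
  })

#' @describeIn evalModel power law \eqn{A q^{-s}}.
#' @export
setMethod("evalModel", signature(model = "PowerLawParams"),
  function(model, q, ...) {
    .checkQGrid(q)
    model@amplitude * q^(-model@s)
  })

#' @describeIn evalModel correlation-peak lineshape: Lorentzian of exponent
#'   \code{m} centred at \code{qPeak}, plus a high-q \eqn{q^{-t}} tail (cut
#'   off below the peak) and flat background.
#' @export
setMethod("evalModel", signature(model = "BroadPeakParams"),
  function(model, q, ...) {
    .checkQGrid(q)
    model@peakAmplitude / (1 + (abs(q - model@qPeak) / model@width)^model@m) +
      model@tailAmplitude * .dampedTail(q, model@qPeak, model@tailExponent) +
      model@background
  })

## high-q power-law tail with an error-function cutoff below qPeak: behaves
## as q^-t for q >> qPeak, vanishes as q^(2t) for q -> 0; self-similar in
## q/qPeak so that concentration ratios of self-similar spectra are exact
.dampedTail <- function(q, qPeak, t) {
  (erf(3 * q / qPeak / sqrt(6))^3 / q)^t
}

#' @describeIn evalModel monotone Guinier-to-power-law (Guinier-Porod)
#'   profile with continuity-matched crossover.
#' @export
setMethod("evalModel", signature(model = "GuinierPowerLawParams"),
  function(model, q, ...) {
    .checkQGrid(q)
    q1 <- sqrt(3 * model@s / 2) / model@Rg
    D <- model@I0 * exp(-q1^2 * model@Rg^2 / 3) * q1^model@s
    ifelse(q <= q1, model@I0 * exp(-q^2 * model@Rg^2 / 3),
           D * q^(-model@s)) + model@background
  })

## error function via pnorm (no extra dependency)
erf <- function(x) 2 * stats::pnorm(x * sqrt(2)) - 1

#' @describeIn evalModel polydisperse core-shell sphere (delegates to
#'   [evalCoreShell()]).
#' @export
setMethod("evalModel", signature(model = "CoreShellParams"),
  function(model, q, ...) evalCoreShell(model, q, ...))

#' @describeIn evalModel sum of models: contributions add linearly.
#' @export
setMethod("evalModel", signature(model = "list"),
  function(model, q, ...) {
    if (!length(model)) stop("empty model list")
    Reduce(`+`, lapply(model, evalModel, q = q, ...))
  })

## scattering amplitude of a single core-shell sphere, A^{1} units
## (contrast [A^-2] x volume [A^3]); vectorized over q for one core radius
.coreShellAmplitude <- function(q, rCore, shell, dRhoCore, dRhoShell) {
  rTot <- rCore + shell
  vC <- 4 / 3 * pi * rCore^3
  vT <- 4 / 3 * pi * rTot^3
  vC * dRhoCore * .sphereAmp(q * rCore) + vT * dRhoShell * .sphereAmp(q * rTot)
}

#' Polydisperse core-shell sphere intensity
#'
#' Orientation-averaged scattered intensity of spheres with a homogeneous
#' core and a concentric shell of fixed thickness, number-averaged over a
#' Schulz (gamma) distribution of core radii:
#' \deqn{I(q) = 10^7\,\frac{\phi}{\langle V_c\rangle}
#'   \langle |F(q)|^2 \rangle + B,\qquad
#'   F(q) = V_c\,\Delta\rho_c\,f(qR_c) + V_t\,\Delta\rho_s\,f(qR_t),}
#' with \eqn{f(x) = 3(\sin x - x\cos x)/x^3},
#' \eqn{\Delta\rho_c = \rho_{core}-\rho_{shell}},
#' \eqn{\Delta\rho_s = \rho_{shell}-\rho_{solv}}, volumes in
#' \eqn{\mathrm{\AA}^3} and SLDs in \eqn{\mathrm{\AA}^{-2}}; the factor
#' \eqn{10^7} converts \eqn{\mathrm{\AA}^{-1}} to \eqn{mm^{-1}}. The
#' intensity is normalized per mean core volume, so \code{scale} is the
#' volume fraction of core (drug) material and a contrast-matched shell
#' (\eqn{\rho_{shell} = \rho_{solv}}) reduces exactly to the homogeneous
#' sphere of radius \eqn{R_c}. The Schulz average is computed by
#' Gauss-Legendre quadrature over the central \eqn{1-10^{-7}} quantile range
#' of the radius distribution; the node count grows with
#' \eqn{q_{max}\,\Delta r} so the oscillatory integrand stays resolved at
#' wide polydispersity.
#'
#' @param params a [CoreShellParams-class].
#' @param q momentum-transfer grid, \eqn{\mathrm{\AA}^{-1}}, positive and
#'   strictly increasing.
#' @param nodes minimum number of quadrature nodes for the polydispersity
#'   average.
#' @return intensity vector, \eqn{mm^{-1}}.
#' @examples
#' p <- CoreShellParams(coreRadius = 1000, shellThickness = 15,
#'                      sldCore = 11.8, sldShell = 16, sldSolvent = 9.47,
#'                      polydispersity = 0.1, scale = 1e-3)
#' evalCoreShell(p, c(0.001, 0.01, 0.1))
#' @export
evalCoreShell <- function(params, q, nodes = 61) {
  stopifnot(is(params, "CoreShellParams"))
  validObject(params)
  .checkQGrid(q)
  dRhoCore <- (params@sldCore - params@sldShell) * 1e-6
  dRhoShell <- (params@sldShell - params@sldSolvent) * 1e-6
  p <- params@polydispersity
  if (p == 0) {
    F <- .coreShellAmplitude(q, params@coreRadius, params@shellThickness,
                             dRhoCore, dRhoShell)
    vC <- 4 / 3 * pi * params@coreRadius^3
    return(1e7 * params@scale * F^2 / vC + params@background)
  }
  ## Schulz: gamma with shape 1/p^2, mean coreRadius
  shape <- 1 / p^2
  scl <- params@coreRadius * p^2
  lo <- stats::qgamma(1e-7, shape = shape, scale = scl)
  hi <- stats::qgamma(1 - 1e-7, shape = shape, scale = scl)
  ## the integrand oscillates in r with period ~pi/q: keep >= ~2 nodes per
  ## half-period at the highest q (Gauss-Legendre resolves ~2n/(range*q))
  nEff <- max(nodes, ceiling(0.5 * (hi - lo) * max(q)) + 30)
  gl <- pracma::gaussLegendre(nEff, lo, hi)
  pdf <- stats::dgamma(gl$x, shape = shape, scale = scl)
  w <- gl$w * pdf
  w <- w / sum(w)
  ## nq x nodes amplitude matrix
  Fmat <- vapply(seq_along(gl$x), function(i)
    .coreShellAmplitude(q, gl$x[i], params@shellThickness, dRhoCore,
                        dRhoShell), numeric(length(q)))
  meanF2 <- drop(Fmat^2 %*% w)
  meanVc <- sum(w * 4 / 3 * pi * gl$x^3)
  1e7 * params@scale * meanF2 / meanVc + params@background
}

#' Bragg reflections of an orthorhombic lattice
#'
#' Reflection positions \eqn{q_{hkl} = 2\pi\sqrt{(h/a)^2 + (k/b)^2 + (l/c)^2}}
#' for a given set of Miller indices, or for all symmetry-inequivalent
#' (non-negative) indices up to \code{qMax}. Positions are symmetric under
#' sign flips of h, k, l.
#'
#' @param lattice a [Lattice-class].
#' @param hkl optional matrix (or length-3 vector) of Miller indices, one
#'   reflection per row. \code{(0,0,0)} is rejected.
#' @param qMax when \code{hkl} is missing: enumerate all reflections with
#'   \eqn{q \le} \code{qMax}.
#' @param wavelength optional X-ray wavelength, \eqn{\mathrm{\AA}}; when
#'   given, the diffraction angle \eqn{2\theta = 2\arcsin(q\lambda/4\pi)}
#'   (degrees) is added.
#' @return data.frame with columns \code{h}, \code{k}, \code{l}, \code{q}
#'   (\eqn{\mathrm{\AA}^{-1}}) and optionally \code{twoTheta}, sorted by
#'   \code{q} (ties broken by lowest \eqn{|h|+|k|+|l|}).
#' @examples
#' braggPositions(dexLattice(), hkl = rbind(c(0, 1, 1), c(0, 0, 2)))
#' @export
braggPositions <- function(lattice, hkl = NULL, qMax = NULL,
                           wavelength = NULL) {
  stopifnot(is(lattice, "Lattice"))
  validObject(lattice)
  if (is.null(hkl)) {
    if (is.null(qMax) || qMax <= 0)
      stop("supply either hkl or a positive qMax")
    hMax <- floor(qMax * lattice@a / (2 * pi))
    kMax <- floor(qMax * lattice@b / (2 * pi))
    lMax <- floor(qMax * lattice@c / (2 * pi))
    hkl <- as.matrix(expand.grid(h = 0:hMax, k = 0:kMax, l = 0:lMax))
    hkl <- hkl[rowSums(abs(hkl)) > 0, , drop = FALSE]
  } else {
    if (is.null(dim(hkl))) hkl <- matrix(hkl, ncol = 3, byrow = TRUE)
    hkl <- as.matrix(hkl)
    if (ncol(hkl) != 3) stop("hkl must have three columns")
    if (any(rowSums(abs(hkl)) == 0)) stop("(0,0,0) is not a reflection")
  }
  q <- 2 * pi * sqrt((hkl[, 1] / lattice@a)^2 + (hkl[, 2] / lattice@b)^2 +
                     (hkl[, 3] / lattice@c)^2)
  out <- data.frame(h = hkl[, 1], k = hkl[, 2], l = hkl[, 3], q = q)
  if (!is.null(qMax)) out <- out[out$q <= qMax, , drop = FALSE]
  if (!is.null(wavelength)) {
    sinTheta <- out$q * wavelength / (4 * pi)
    if (any(sinTheta > 1))
      stop("q * wavelength / (4*pi) exceeds 1; reflection unreachable")
    out$twoTheta <- 2 * asin(sinTheta) * 180 / pi
  }
  ord <- order(out$q, abs(out$h) + abs(out$k) + abs(out$l))
  out <- out[ord, , drop = FALSE]
  rownames(out) <- NULL
  out
}
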