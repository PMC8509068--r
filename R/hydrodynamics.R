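## DLS inversion and Stokes-Einstein sizing.

.kB <- 1.380649e-23  # J/K

#' Stokes-Einstein conversions
#'
#' \code{stokesEinstein} converts a translational diffusion coefficient to a
#' hydrodynamic diameter, \eqn{D_H = k_B T / (3\pi\eta D)};
#' \code{inverseStokesEinstein} is its exact inverse. Viscosity is accepted
#' in centipoise (1 cP = \eqn{10^{-3}} Pa s). Use the solution viscosity, not
#' the solvent one, when dissolved polymer thickens the sample (e.g. 2.5 cP
#' at 1 mg/mL and 1.2 cP at 0.5 mg/mL for the HYA-DEX suspensions; 0.89 cP
#' for water at 25 C).
#'
#' @param D diffusion coefficient, \eqn{m^2/s}.
#' @param DH hydrodynamic diameter, nm.
#' @param temperature absolute temperature, K.
#' @param viscosity viscosity, cP.
#' @return \code{stokesEinstein}: diameter in nm; \code{inverseStokesEinstein}:
#'   diffusion coefficient in \eqn{m^2/s}.
#' @examples
#' stokesEinstein(4.907e-12)         # ~100 nm in water at 25 C
#' inverseStokesEinstein(300, viscosity = 2.5)
#' @export
stokesEinstein <- function(D, temperature = 298.15, viscosity = 0.89) {
  if (any(D <= 0) || temperature <= 0 || viscosity <= 0)
    stop("all inputs must be > 0")
  1e9 * .kB * temperature / (3 * pi * viscosity * 1e-3 * D)
}

#' @rdname stokesEinstein
#' @export
inverseStokesEinstein <- function(DH, temperature = 298.15,
                                  viscosity = 0.89) {
  if (any(DH <= 0) || temperature <= 0 || viscosity <= 0)
    stop("all inputs must be > 0")
  .kB * temperature / (3 * pi * viscosity * 1e-3 * DH * 1e-9)
}

#' DLS scattering vector
#'
#' \eqn{q = (4\pi n / \lambda)\sin(\theta/2)} in \eqn{m^{-1}}.
#'
#' @param wavelength laser wavelength, nm.
#' @param angle scattering angle, degrees.
#' @param refractiveIndex solvent refractive index.
#' @export
dlsQ <- function(wavelength = 532, angle = 90, refractiveIndex = 1.33) {
  4 * pi * refractiveIndex * sin(angle * pi / 360) / (wavelength * 1e-9)
}

#' Invert a DLS autocorrelation trace
#'
#' Recovers the field correlation from the Siegert relation
#' \eqn{g_2 = 1 + \beta |g_1|^2}, with the coherence factor \eqn{\beta}
#' estimated from the first three lag points, then inverts either by
#' second-order cumulant expansion (\eqn{\ln g_1 = -\Gamma\tau +
#' \mu_2\tau^2/2}; \eqn{D = \Gamma/q^2}, \eqn{PDI = \mu_2/\Gamma^2}) or by
#' non-negative least squares on a log-spaced decay-rate grid. The
#' hydrodynamic diameter follows from Stokes-Einstein at the trace's
#' temperature and viscosity.
#'
#' @param trace a [DLSTrace-class].
#' @param method \code{"cumulant"} or \code{"nnls"}.
#' @param diameterGrid optional diameter grid for the NNLS method, nm; by
#'   default 60 log-spaced decay rates per decade spanned by the lag window.
#' @param regularization Tikhonov smoothing weight for NNLS (0 = plain NNLS,
#'   the default).
#' @param betaPoints number of initial lag points used for the intercept.
#' @param decayFloor fraction of \eqn{\beta} below which the correlogram is
#'   considered decayed into the baseline and excluded from the fit.
#' @return A [HydroResult-class].
#' @examples
#' tr <- makeDlsTrace(300, viscosity = 2.5, noise = noNoise())
#' hydroDiameter(dlsAnalyze(tr$trace))
#' @export
dlsAnalyze <- function(trace, method = c("cumulant", "nnls"),
                       diameterGrid = NULL, regularization = 0,
                       betaPoints = 3, decayFloor = 0.05) {
  stopifnot(is(trace, "DLSTrace"))
  validObject(trace)
  method <- match.arg(method)
  tau <- trace@tau
  y <- trace@g2 - 1
  setup <- trace@setup
  q <- dlsQ(setup$wavelength, setup$angle, setup$refractiveIndex)

  if (any(y[seq_len(betaPoints)] <= 0))
    stop("negative correlation amplitude at short lags; cannot estimate beta")
  ## intercept from the geometric mean of the first lags; a slope fit over
  ## three nearly-coincident lag times only amplifies noise, and any small
  ## residual offset is absorbed by the intercept of the cumulant fit
  i0 <- seq_len(betaPoints)
  beta <- exp(mean(log(y[i0])))
  if (!is.finite(beta) || beta <= 0) stop("negative or undefined beta")

  keep <- which(y > decayFloor * beta & y <= beta * (1 + 0.5))
  if (length(keep) < 5L) stop("no usable decay in the lag window")
  if (max(y[keep]) - min(y[keep]) < 0.1 * beta)
    stop("no decay in the lag window")
  g1 <- sqrt(pmax(y[keep], 0) / beta)
  tk <- tau[keep]

  if (method == "cumulant") {
    lg <- log(g1)
    fit <- stats::lm(lg ~ tk + I(tk^2))
    cf <- stats::coef(fit)
    gamma <- -unname(cf[2])
    mu2 <- 2 * unname(cf[3])
    if (gamma <= 0) stop("no decay in the lag window")
    pdi <- max(mu2, 0) / gamma^2
    D <- gamma / q^2
    dist <- list()
  } else {
    ## decay-rate grid: 60 points per decade of the lag span
    if (is.null(diameterGrid)) {
      gMin <- 1 / (10 * max(tk)); gMax <- 10 / min(tk)
      nDec <- log10(gMax / gMin)
      gammaGrid <- 10^seq(log10(gMin), log10(gMax),
                          length.out = max(10, ceiling(60 * nDec)))
    } else {
      Dgrid <- inverseStokesEinstein(diameterGrid,
                                     temperature = setup$temperature,
                                     viscosity = setup$viscosity)
      gammaGrid <- sort(Dgrid * q^2)
    }
    K <- exp(-outer(tk, gammaGrid))
    if (regularization > 0) {
      K <- rbind(K, diag(regularization, length(gammaGrid)))
      g1fit <- c(g1, numeric(length(gammaGrid)))
    } else g1fit <- g1
    w <- pracma::lsqnonneg(K, g1fit)$x
    if (sum(w) <= 0) stop("NNLS returned an empty distribution")
    w <- w / sum(w)
    gamma <- sum(w * gammaGrid)
    mu2 <- sum(w * (gammaGrid - gamma)^2)
    pdi <- mu2 / gamma^2
    D <- gamma / q^2
    dWeights <- w[w > 0]
    dDiam <- stokesEinstein(gammaGrid[w > 0] / q^2,
                            temperature = setup$temperature,
                            viscosity = setup$viscosity)
    dist <- list(diameter = dDiam, weight = dWeights)
  }
  new("HydroResult", D = D,
      DH = stokesEinstein(D, temperature = setup$temperature,
                          viscosity = setup$viscosity),
      PDI = max(pdi, 0), beta = beta, method = method, distribution = dist)
}

#' Summarize repeated zeta-potential measurements
#'
#' Arithmetic mean and sample standard deviation of repeated electrophoretic
#' zeta-potential readings (values are consumed, not derived from mobility).
#'
#' @param measurements zeta values, mV; at least one.
#' @return A [ZetaSummary-class]. For a single value the standard deviation
#'   is reported as 0 with \code{singleValue = TRUE}.
#' @examples
#' summarizeZeta(c(-60, -61, -62, -61, -61))
#' @export
summarizeZeta <- function(measurements) {
  if (!length(measurements)) stop("empty measurement list")
  n <- length(measurements)
  new("ZetaSummary", mean = mean(measurements),
      sd = if (n > 1) stats::sd(measurements) else 0,
      n = n, singleValue = n == 1L)
}
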