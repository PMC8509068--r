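## internal helpers

.checkQGrid <- function(q) {
  if (length(q) == 0L) stop("empty q grid")
  if (any(!is.finite(q)) || any(q <= 0)) stop("q must be finite and > 0")
  if (length(q) > 1L && any(diff(q) <= 0)) stop("q must be strictly increasing")
  invisible(q)
}

## log-spaced grid, the package default SAXS window
#' Default synthetic SAXS q-grid
#'
#' 400 log-spaced points over \eqn{10^{-3}}--0.7 \eqn{\mathrm{\AA}^{-1}}; wide
#' enough at low q that a ~200 nm core is constrained by its Guinier regime.
#'
#' @param n number of points.
#' @param qMin,qMax grid limits, \eqn{\mathrm{\AA}^{-1}}.
#' @return numeric vector.
#' @export
defaultQGrid <- function(n = 400, qMin = 1e-3, qMax = 0.7) {
  exp(seq(log(qMin), log(qMax), length.out = n))
}

## log-log linear interpolation of a positive curve onto a new grid;
## scattering curves are locally power-law-like so this is the natural rule
.interpLogLog <- function(q, I, qOut, extrapolate = FALSE) {
  if (any(I <= 0)) {
    ## fall back to linear interpolation where intensities are not positive
    return(stats::approx(q, I, xout = qOut, rule = if (extrapolate) 2 else 1)$y)
  }
  rule <- if (extrapolate) 2 else 1
  exp(stats::approx(log(q), log(I), xout = log(qOut), rule = rule)$y)
}

## resample a ScatterCurve onto a target q grid (log-log); errors when the
## target extends beyond the source range
.resampleCurve <- function(curve, qOut, extrapolate = FALSE) {
  q <- curve@q
  if (!extrapolate && (min(qOut) < min(q) * (1 - 1e-9) ||
                       max(qOut) > max(q) * (1 + 1e-9)))
    stop("q grids not alignable by interpolation (target extends beyond source)")
  y <- .interpLogLog(q, curve@intensity, qOut, extrapolate = TRUE)
  ScatterCurve(qOut, y, meta = curve@meta)
}

## weighted linear fit returning slope/intercept/se/r2
.linfit <- function(x, y, w = NULL) {
  fit <- if (is.null(w)) stats::lm(y ~ x) else stats::lm(y ~ x, weights = w)
  cf <- stats::coef(fit)
  se <- tryCatch(suppressWarnings(sqrt(diag(stats::vcov(fit)))),
                 error = function(e) rep(NA_real_, 2))
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(intercept = unname(cf[1]), slope = unname(cf[2]),
       seIntercept = unname(se[1]), seSlope = unname(se[2]), r2 = r2,
       fit = fit)
}

## derive a reproducible child seed (< 2^31) from a base seed and a tag
.childSeed <- function(seed, k) {
  (as.numeric(seed) * 1103515245 + 12345 + 97 * as.numeric(k)) %% 2147483647
}

## evaluate an expression with a locally-set RNG seed, restoring RNG state
.withSeed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  expr
}
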