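# shared fixtures and independent oracles

# published NGI cut-off diameters at 15 L/min (configuration, not constants)
ngiCutoffs15 <- c(14.1, 8.61, 5.39, 3.30, 2.08, 1.36, 0.98)

# nanoparticle parameters of the reference formulation: 200 nm core
# (diameter), 1.5 nm shell, drug core SLD 11.8, polysaccharide shell 16,
# water solvent, all x1e-6 A^-2
referenceNp <- function(polydispersity = 0.1, scale = 1, background = 0) {
  CoreShellParams(coreRadius = 1000, shellThickness = 15, sldCore = 11.8,
                  sldShell = 16, sldSolvent = 9.47,
                  polydispersity = polydispersity, scale = scale,
                  background = background)
}

# independent brute-force oracle for the polydisperse core-shell intensity:
# dense trapezoid average over the Schulz distribution, >= 1e4 nodes
coreShellOracle <- function(p, q, n = 10000) {
  f <- function(x) ifelse(x < 1e-8, 1, 3 * (sin(x) - x * cos(x)) / x^3)
  dc <- (p@sldCore - p@sldShell) * 1e-6
  ds <- (p@sldShell - p@sldSolvent) * 1e-6
  amp <- function(r) {
    rt <- r + p@shellThickness
    (4 / 3 * pi * r^3) * dc * f(q * r) + (4 / 3 * pi * rt^3) * ds * f(q * rt)
  }
  if (p@polydispersity == 0) {
    F <- amp(p@coreRadius)
    return(1e7 * p@scale * F^2 / (4 / 3 * pi * p@coreRadius^3) +
             p@background)
  }
  shape <- 1 / p@polydispersity^2
  scl <- p@coreRadius * p@polydispersity^2
  r <- seq(qgamma(1e-8, shape, scale = scl),
           qgamma(1 - 1e-8, shape, scale = scl), length.out = n)
  w <- dgamma(r, shape, scale = scl)
  w <- w / sum(w)
  F <- vapply(r, amp, numeric(length(q)))
  mF2 <- drop(F^2 %*% w)
  mVc <- sum(w * 4 / 3 * pi * r^3)
  1e7 * p@scale * mF2 / mVc + p@background
}

# deterministic multiplicative jitter pattern around 1
jitterFactors <- function(n, amount, seed) {
  withr::with_seed(seed, 1 + amount * runif(n, -1, 1))
}
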