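---
title: "Methods: scattering and aerodynamic characterization of polymer-drug nanosuspensions"
author: "nanoscatter"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scattering and aerodynamic characterization of polymer-drug nanosuspensions}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nanoscatter)
```

# Scope and scientific setting

`nanoscatter` implements the physico-chemical characterization workflow for a
reconstituted polymer-drug nanosuspension: hyaluronic-acid (HYA) coated
dexamethasone (DEX) nanoparticles intended for pulmonary delivery. After a
spray-dried HYA-DEX powder (55:45 polymer:drug by mass) is redispersed in
water or in phosphate buffer (PB, pH 7.4, 138 mM), the questions a
formulator asks are:

* how large are the reconstituted particles (DLS), and is the apparent size
  corrected for the extra viscosity the dissolved polymer adds to the
  solution;
* how does the free polymer behave in each solvent (SAXS: correlation peak
  and its concentration scaling in salt-free water; Guinier radii and high-q
  conformation exponents in buffer);
* how much of the admixed polymer is complexed in the particles and how much
  stays free in solution (spectral decomposition);
* what is the internal particle structure (polydisperse core-shell
  form-factor fit; WAXS Bragg indexing of the crystalline drug core);
* is the structure stable against a mucus model (linear-combination
  reconstruction of mixture spectra with mucin);
* how does the nebulized suspension perform aerodynamically (cascade
  impactor: MMAD, GSD, emitted and fine-particle doses).

No public raw curves exist for this system, so every stage ships with a
seeded synthetic-data generator that produces inputs with known ground
truth; the test suite is built on recovery of those ground truths.

# Units

Momentum transfer `q` in Å⁻¹ and lengths in Å internally (nm only at
reporting boundaries), absolute intensity in mm⁻¹, scattering length
densities (SLD) in 10⁻⁶ Å⁻². Peak positions printed elsewhere as "0.47 Å"
are, dimensionally, Å⁻¹ and are treated as such throughout.

# Forward models

## Polyelectrolyte correlation peak

In salt-free water HYA behaves as a classical hydrophilic polyelectrolyte:
inter-chain repulsion produces a pseudo-periodic arrangement and a broad
correlation peak at \(q_{peak} = 2\pi/\xi\), with \(\xi\) the mean
inter-chain distance. Scaling theory (and the Koyama wormlike-chain picture)
predicts \(q_{peak} \propto \sqrt c\) and \(I(q_{peak}) \propto \sqrt c\).
Only the peak position and intensity laws are physically constrained; the
lineshape is an empirical choice. We use a Lorentzian of half-width \(w\)
centred at \(q_{peak}\), a flat background, and a high-q \(q^{-s}\) tail
*multiplied by an error-function crossover that cuts the tail off below the
peak*:

\[ I(q) = \frac{P}{1+(|q-q_{peak}|/w)^2}
  + A\left[\frac{\mathrm{erf}(3q/q_{peak}/\sqrt6)^3}{q}\right]^{s} + B. \]

An undamped \(q^{-s}\) term would diverge at low q and overtake the peak,
which contradicts both the measured spectra (low-q scattering is suppressed
in salt-free polyelectrolyte solutions) and the requirement that the profile
attain its maximum at \(q_{peak}\). Because the cutoff scale is tied to
\(q_{peak}\) the whole profile is self-similar in \(q/q_{peak}\) under the
\(\sqrt c\) laws; any small, lineshape-induced bias of a peak-position
estimator is then identical across concentrations and cancels exactly in
concentration ratios, which is what the decomposition stage consumes.

Generator defaults: \(w = 0.25\,q_{peak}\), tail fraction 0.3 of the peak
intensity at \(q_{peak}\), background \(10^{-4}\) mm⁻¹, peak-position
prefactor placing \(\xi = 270\) Å at 1.4 mg/mL, peak-intensity prefactor
\(J = 0.05\) mm⁻¹(mg/mL)\(^{-1/2}\), tail exponent \(s = 1.3\) (rod-like
chains). The \(\xi\) anchor and the exponents are the measured reference
conditions; the absolute intensity prefactor is a typical synchrotron-scale
value chosen once (the analysis never depends on it, only on its
concentration scaling).

## Buffered polymer and mucin: Guinier-Porod

With 138 mM salt the electrostatics are screened, the peak disappears, and
the chains form denser bead-like regions characterized by a gyration radius
\(R_g\) and a high-q exponent \(s\). We represent such peak-free spectra
with the monotone Guinier-Porod form — Guinier at low q, \(Dq^{-s}\) above
the crossover \(q_1 = \sqrt{3s/2}/R_g\), with \(D\) fixed by continuity.
A Beaucage-type additive crossover was rejected: its power-law term has an
interior maximum that masquerades as a correlation peak, and buffered
spectra must be peak-free. Guinier-Porod is linear in its amplitude, so
buffered intensity scales exactly linearly in concentration — which is also
the assumption the buffered decomposition route relies on.

Generator defaults: \(R_g = 98\) Å at 1.4 mg/mL shrinking as
\(c^{-0.287}\) (the power law through the measured 98 Å at 1.4 mg/mL and
54 Å at 11.2 mg/mL), \(s = 1.5\), amplitude 0.01 mm⁻¹ per mg/mL. Mucin
uses the same form with \(R_g = 150\) Å and \(s = 1.8\) as a synthetic
stand-in (mucin spectra are only cited, never printed, so these values are
plausible rather than measured; the stability test depends only on
linearity, not on the mucin shape).

## Polydisperse core-shell sphere

The particle model is a sphere with a homogeneous core (nanocrystalline DEX,
SLD 11.8) and a thin concentric shell (HYA, SLD 16) in water (SLD 9.47),
number-averaged over a Schulz distribution of core radii with fixed shell
thickness:

\[ I(q) = 10^7\,\frac{\phi}{\langle V_c\rangle}\,\langle|F(q)|^2\rangle + B,
\qquad F = V_c\Delta\rho_c f(qR_c) + V_t\Delta\rho_s f(qR_t), \]

with \(f(x) = 3(\sin x - x\cos x)/x^3\). Normalizing by the mean *core*
volume makes `scale` the volume fraction of drug material and gives an exact
reduction to the homogeneous sphere when the shell is contrast-matched
(\(\rho_{shell}=\rho_{solv}\)) — the identity the unit tests assert to
1e-10. The Schulz average uses Gauss-Legendre quadrature over the central
\(1-10^{-7}\) quantile range; since the integrand oscillates in \(r\) with
period \(\pi/q\), the node count grows as
\(\lceil 0.5\,\Delta r\,q_{max}\rceil\) (plus margin), which keeps the model
within 0.1% of a 10⁴-node brute-force average over the full tested parameter
range (core radius 300-1500 Å, polydispersity up to 0.3).

Interpretation note: the reference formulation's "core of about 200 nm" is
taken as a core *diameter* (radius 1000 Å), consistent with hydrodynamic
diameters of 170-300 nm for the whole particle; the parameter object stores
the radius, and reporting converts to nm diameter.

## Bragg positions

For the orthorhombic DEX cell (a = 10.36, b = 16.16, c = 23.20 Å),
\(q_{hkl} = 2\pi\sqrt{(h/a)^2+(k/b)^2+(l/c)^2}\); the two reflections that
fall in the SAXS window are (0,1,1) at 0.474 Å⁻¹ and (0,0,2) at 0.542 Å⁻¹.
The 2θ conversion requires an explicit wavelength — none is assumed, because
the reference 2θ axis never states one.

# Analysis stages

## Peak location

The correlation peak is found as the most prominent interior local maximum
of the median-smoothed log-intensity inside a search window (default
0.01-0.3 Å⁻¹, the polyelectrolyte regime, below the crystalline
reflections), then refined by a parabola fit to log-intensity over ±5 grid
points. Prominence is measured in log units against the higher of the two
flanking valleys, with a 0.1 (≈10%) floor: noise bumps on a monotone decay
are rejected, while a peak riding on the steep nanoparticle upturn is still
found. A curve without a qualifying maximum returns an explicit "no peak"
result — the expected outcome for every buffered sample. At high bound
fractions the free-polymer peak genuinely drowns under the particle signal;
the peak route then reports no peak and the intensity route must be used.

## Scaling, slope, Guinier

`fitScaling` is a log-log linear regression (exact on noise-free power
laws); `fitHighQSlope` the same above 0.25 Å⁻¹ by default (midpoint of the
conventional 0.2-0.3 Å⁻¹ onset). `fitGuinier` fits \(\ln I\) against
\(q^2\), iteratively shrinking the window until all points satisfy
\(qR_g \le 1.3\) (the conventional validity limit for globular scatterers;
no other cutoff is stated for this system). The initial window extends to
where the smoothed intensity has fallen to half its forward value
(\(qR_g \approx 1.4\)) — starting from a fixed number of low-q points is
unstable because the first points of a log grid are flat to within the
noise. A positive low-q slope (apparent \(R_g^2 < 0\)) is refused as an
aggregation signature. Fits are σ-weighted when uncertainties exist.

## Bound/unbound decomposition

The admixed polymer concentration of a mixture at total concentration
\(c_{tot}\) is \(c_{HYA} = 0.55\,c_{tot}\); the decomposition estimates the
free part \(c_{free}\) and reports unbound \(= c_{free}/c_{HYA}\) (clamped
to [0,1] with a flag). Four routes:

* **peak position** (water): invert the \(q_{peak}(c)\) calibration fitted
  on the reference dilution ladder, \(c_{free} = (q_{peak}/K)^{1/e}\) with
  the fitted exponent \(e\);
* **high-q intensity** (water) and **buffered discrepancy** (PB): a per-q
  log-log-in-c interpolation of the reference curves gives the expected
  free-polymer intensity \(I_{HYA}(q;c)\) in the window q > 0.06 Å⁻¹; the
  free concentration minimizes the weighted misfit
  \(I_{mix} - I_{HYA}(q;c) - Aq^{-4} - B\) with non-negative nuisance terms
  absorbing the residual particle Porod tail and flat background (1-D
  golden-section over \(c\), inner NNLS). Log-log is used for the water
  calibration because the self-similar tail scales as \(c^{(1+s)/2}\), not
  linearly; in buffer the scaling is exactly linear and log-log reproduces
  it;
* **subtraction** (two or more mixtures at different \(c_{tot}\)): scan the
  per-curve unbound fractions jointly (coarse grid, then bounded
  quasi-Newton) and minimize the mean squared log-difference of the
  concentration-normalized residual spectra — identical particles must leave
  residuals that coincide after rigid scaling. The congruence window is
  0.01-0.15 Å⁻¹: it must include the correlation-peak region, because in
  the far tail every free-polymer contribution has the same \(q^{-s}\) shape
  and the objective is flat along a family of wrong fraction pairs. A mild
  penalty on negative residuals discourages oversubtraction without
  punishing noise around an exact subtraction.

Reference rescaling across concentration uses the water self-similarity
(rigid log-log shift \(I_c(q) = \sqrt{c/c_0}\,I_{c_0}(q\sqrt{c_0/c})\)) and
linear amplitude scaling in buffer. Bound + unbound = 1 holds by
construction and is asserted by a validity method.

## Mucin stability

A mixture spectrum is regressed onto its component spectra by non-negative
least squares (σ-weighted; relative residuals otherwise, so each decade of
the spectrum counts comparably). The relative residual norm, overall and in
low/mid/high log-q thirds, is compared against a 5% threshold; incipient
interaction typically appears at low q only, so a localized low-q excess
also raises the flag.

## Core-shell fitting

Bounded Levenberg-Marquardt least squares with logarithmic residuals (or
σ-weighted linear residuals when uncertainties exist), restarted from five
deterministically jittered initial values because the form-factor objective
is oscillatory. SLDs default to fixed (known from composition); core
radius, shell thickness, polydispersity, scale and background are free.
Several curves can share one shape with per-curve scales — the model for
the same particles measured at different concentrations or solvents.
Parameters ending on a bound are flagged rather than silently accepted, and
a zero-contrast initialization is refused as unidentifiable.

## WAXS analysis

Peaks are residuals over a rolling-median background (window ≈ 8% of the
points), required to exceed 3× the robust residual scale (MAD), 20% of the
local background, and to be narrow (half-prominence width below 10% of the
position) — the width criterion is what keeps broad diffuse maxima, like the
correlation peak, from being mistaken for crystallinity. Detected peaks are
assigned to the nearest lattice reflection within tolerance (default
0.01 Å⁻¹), ties broken by lowest \(|h|+|k|+|l|\); multiple candidates within
tolerance are reported as ambiguous, never silently resolved. Given a
concentration series, per-peak heights are regressed against concentration
(a crystalline drug load scales linearly).

## DLS inversion

The Siegert relation \(g_2 = 1+\beta|g_1|^2\) is inverted with β estimated
by extrapolating \(\ln(g_2-1)\) from the first three lags to τ = 0. The
cumulant route fits \(\ln g_1 = -\Gamma\tau + \mu_2\tau^2/2\) over the lags
where the correlation amplitude still exceeds 5% of β;
\(D = \Gamma/q^2\), PDI \(= \mu_2/\Gamma^2\). The NNLS route solves for
non-negative weights on a log-spaced decay-rate grid (60 points per decade
of the lag span; optional Tikhonov smoothing, off by default to match plain
NNLS practice). Diameters follow from Stokes-Einstein
\(D_H = k_BT/(3\pi\eta D)\) with \(k_B = 1.380649\times10^{-23}\) J/K,
T = 298.15 K by default, and a *caller-supplied solution viscosity* — 2.5 cP
at 1 mg/mL and 1.2 cP at 0.5 mg/mL for this formulation, water's 0.89 cP
where no measured value exists (including the 0.125 and 0.25 mg/mL rows,
whose viscosities were never reported).

## Impactor aerodynamics

From a deposition table: ED = mass from induction port to MOC (the port and
its adaptor are grouped, as in the reference emitted-dose definition); EF% =
ED over total recovered; FPD = stage 3 to MOC (the verbatim fine-particle
rule); FPF% = FPD over ED. The cumulative undersize fraction of the sized
mass at each cut-off is probit-transformed and regressed on log₁₀(cut-off):
MMAD at probit 0, GSD from the diameters at ±1 probit. The "standard"
percentile pair is 84.13/15.87 — exactly ±1 sd, exact for a lognormal — with
a "rounded" 85/16 mode available since both conventions circulate. Cut-off
diameters are configuration, never hard-coded; the tests use the published
15 L/min values as their configuration. Cumulative fractions of exactly 0
or 1 are excluded; when all sized mass lies on one side of every cut-off the
median is only bracketed and is reported as NA with an extrapolation flag.

The synthetic impactor deposits a lognormal aerosol between consecutive
cut-offs by CDF differences, with an optional size-independent
induction-port bite; mass balances exactly without noise, and the probit
line is then exact (R² = 1), so MMAD/GSD recovery is a sharp test.

# What the generators do and do not emulate

The generators reproduce: the \(\sqrt c\) peak laws and high-q exponents;
peak-free buffered profiles with concentration-dependent \(R_g\);
mixture spectra whose components and composition are known exactly
(conservation: free + bound = admixed); Bragg peaks at the drug-lattice
positions with concentration-scaled heights; Siegert-consistent DLS traces;
lognormal aerosols deposited by cut-off. Default noise is 1% relative
Gaussian (typical synchrotron counting quality), seeded and bit-reproducible.

They do not emulate: instrument resolution smearing, multiple scattering or
detector geometry; inter-particle structure factors (dilute-limit
assumption); DLS afterpulsing or number fluctuations; impactor wall losses
or bounce. Passing recovery tests therefore demonstrates correctness of the
estimators under the stated models, not robustness to every instrumental
artifact of real data.

The default synthetic SAXS grid is 400 log-spaced points over
\(10^{-3}\)-0.7 Å⁻¹. The lower edge extends below a literal reading of the
stated experimental window (whose printed minimum of 7×10⁻² Å⁻¹ cannot
resolve a 200 nm core and is presumably 7×10⁻³): a ~200 nm particle needs
\(q_{min}R \lesssim 3\) for its size to be constrained, and the fitter warns
when that condition fails.

# Numerical choices and degenerate inputs

* Log-log linear interpolation between q grids (scattering curves are
  locally power-law-like); grids that would require extrapolation raise an
  error in profile subtraction.
* Negative differences in profile subtraction are floored at zero by
  default, with the count reported — a large count is the oversubtraction
  signature; a "keep" policy is available.
* Golden-section/`optimize` for 1-D concentration searches; coarse grid +
  L-BFGS-B for the subtraction fraction pair; Levenberg-Marquardt with ±10%
  multi-start jitter for form factors.
* Clamping of fractions to [0,1] always raises a flag; calibration
  extrapolation beyond the reference range warns.
* Degenerate guards: zero-contrast particles, all-zero mixture components,
  empty concentration lists, non-monotone cut-offs, non-physical viscosity
  or temperature, β ≤ 0.

# Test problem sizes

The suite exercises: 20 random parameter sets against the 10⁴-node
quadrature oracle; 5 noise-free plus 2 noisy core-shell recovery fits (150 q
points, 3 restarts); 50-seed averages for the Guinier and scaling-exponent
recoveries; 10-seed DLS recovery; a 12-point MMAD×GSD grid; and 20 fuzzed
impactor tables. These sizes were chosen to give stable averages at
interactive runtimes; all are one-line constants in the tests.

# Known limitations

* The peak-position decomposition needs a visible correlation peak; at high
  bound fraction or low concentration it correctly reports "no peak" and
  the intensity route takes over.
* The subtraction route assumes the particle spectrum scales rigidly with
  concentration between the paired samples.
* Cumulant PDI is accurate for modest polydispersity; strongly multimodal
  samples need the NNLS route, whose resolution is grid-limited.
* The core-shell model omits structure factors and resolution smearing, so
  fitted polydispersity absorbs any instrumental broadening of real data.
* WAXS indexing reports, but does not resolve, assignments that are
  ambiguous within the matching tolerance — orthorhombic reflections are
  dense above ~1.5 Å⁻¹.
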