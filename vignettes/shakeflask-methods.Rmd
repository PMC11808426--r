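---
title: "Methods: shake-flask characterization and snapshot post-processing"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: shake-flask characterization and snapshot post-processing}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shakeflask)
```

## Scope and assumptions

`shakeflask` computes process quantities for orbitally shaken,
unbaffled Erlenmeyer flasks along two routes: (i) bench correlations
that need only the operating point, and (ii) post-processing of
two-phase flow snapshots on uniform structured grids, as produced by
volume-of-fluid (VOF) solvers. The package does not solve any flow
equations itself: snapshots are inputs. The correlations assume an
unbaffled flask, a single liquid phase wetted to the wall, and — for
the power and shear correlations — in-phase operation; departures from
in-phase behavior are handled explicitly by the phase-number machinery
described below.

## Dimensionless state and the out-of-phase transition

The flask Reynolds number $Re = \rho n d^2/\eta$ uses the largest
inner flask diameter $d$ as the length scale. The film Reynolds
number rescales $Re$ by a film-geometry factor built from
$V_L^{1/3}/d$; the package evaluates it with the *outer bracket
squared*,

$$Re_{film} = Re\cdot\frac{\pi}{2}
\left[1-\sqrt{1-\frac{4}{\pi}\left(\frac{V_L^{1/3}}{d}\right)^2}\,\right]^2,$$

a reading we fixed deliberately: of the bracket placements the formula
admits, only this one reproduces the reference phase numbers 1.21 and
1.44 for the 16.7 mPa·s / 15 mL / 25 mm condition at 250 and 450 rpm
(the values the 250 mL preset is calibrated against). The argument of
the square root must be nonnegative, which bounds the filling volume
at construction time; `shaking_conditions()` rejects overfilled
geometries rather than propagating complex numbers.

The phase number $Ph = (d_0/d)(1 + 3\log_{10}Re_{film})$ classifies
operation: `in_phase` at $Ph \ge 1.26$, `out_of_phase` below $0.91$,
`transition` in between. The literature states the two critical values
without a boundary convention; we close the in-phase interval on the
left (a run *at* a critical value gets the more favorable label),
which only matters for exact-boundary inputs.

## Power input and its out-of-phase correction

In-phase power input uses
$Ne' = 70Re^{-1} + 25Re^{-0.6} + 1.5Re^{-0.2}$. The exponential
correction $y(Ph) = 1 - a e^{-bPh}$ with defaults $a = 3.43$,
$b = 2.02$ multiplies the correlation below the transition. Two
numerical points:

* $y$ turns negative below $Ph = \ln(a)/b \approx 0.610$, outside the
  range of the data behind the fit. `oophase_quotient()` reports the
  raw value *and* a clamped variant with a flag;
  `power_input_corrected()` uses the clamp and warns, so a deeply
  out-of-phase condition yields zero corrected power input rather
  than a negative one.
* `fit_correction()` re-estimates $(a, b)$ from user data by
  Levenberg–Marquardt least squares (`minpack.lm::nlsLM`) with start
  values from a log-linear regression of $1-y$; data with no decay
  signal (all quotients within $2\times10^{-3}$ of 1) is declared
  unidentifiable in $b$ instead of returning an arbitrary rate.

## Effective viscosity of shear-thinning broths

For a power-law fluid $(K, m)$ the loop
$\eta \to Re \to Ne' \to P/V_L \to \gamma_{eff} \to \eta = K\gamma_{eff}^{m-1}$
is iterated to a relative tolerance of $10^{-10}$ (cap 500
iterations), with under-relaxation factor 0.5 engaged only when the
iterate oscillates; near $m = 1$ the map is a mild contraction and
plain iteration converges in a handful of steps ($m = 1$ terminates
at $\eta = K$ exactly). The default loop uses the *uncorrected*
in-phase power input: the effective-shear correlation was derived for
in-phase operation, so feeding it the out-of-phase-corrected power
input would mix calibration domains. For the reference condition
(104 mPa·s^m, 0.956, 250 rpm, 25 mL) both variants round to the same
80 mPa·s, so the choice is not observable there; it is exposed as
`use_correction` for users who want the corrected loop.

## Diffusion coefficients

The Stokes–Einstein–Gierer–Wirtz estimate treats solute and solvent
as hard spheres with radii from molecular weight and an effective
density of 619 kg/m³. The radius-ratio orientation is
$\beta = (MW_{solute}/MW_{solvent})^{1/3}$; with it, oxygen in water
at 20 °C and 1 mPa·s gives $1.78\times10^{-9}$ m²/s and water
self-diffusion at 25 °C gives $2.17\times10^{-9}$ m²/s — both at the
accepted magnitudes, which is why this orientation (and not its
reciprocal) is the default. Temperature enters only through $k_BT$
and the supplied viscosity; no temperature-dependent viscosity model
is applied, and whether to evaluate at cultivation temperature or
20 °C is left to the caller.

## Snapshot operators

Velocity gradients use second-order central differences in the
interior and first-order one-sided stencils at the two boundary
layers; convergence statements therefore apply to interior cells (the
test suite checks the expected ~4× error reduction on halved spacing
for a smooth shear profile). The strain-rate norm is
$\|S\| = \sqrt{2S\!:\!S}$, and $\lambda_1$ comes from the closed-form
trigonometric solution of the symmetric 3×3 eigenproblem with the
cosine argument clamped to $[-1, 1]$ and the result floored at 0; the
dense eigensolver in base R serves as an independent oracle in the
tests, not as the implementation.

Liquid integrals are $\alpha$-weighted rather than thresholded: VOF
interfaces are diffuse, and weighting by the volume fraction is both
smoother and what the shear-averaging definition writes. The local
dissipation is $(\eta/\rho)\|S\|^2 + \beta^*\omega k$ with
$\beta^* = 0.09$; the turbulence term is simply dropped when the
snapshot carries no $k$/$\omega$ fields (laminar or unresolved
snapshots). The eddy-cell $k_L$ uses the *local per-cell* dissipation
— the integral defining $k_La$ is per-cell, so a domain-mean
dissipation would smear the very inhomogeneity the closure exploits.
The $k_La$ integral is normalized by the total domain volume as
written in its defining equation; because the bench correlation it is
compared against is liquid-referenced, a liquid-volume-normalized
variant is co-reported.

The iterative non-Newtonian shear estimator
$\gamma \leftarrow (2.5\lambda_1)^{1/m}\gamma^{(m-1)/m}$ is a per-cell
contraction with factor $|(m-1)/m|$; it requires $m > 0.5$ and its
fixed point is exactly $2.5\lambda_1$, which the implementation
asserts on exit (deviation beyond $10^{-8}$ relative raises a
warning). Cells with $\lambda_1 = 0$ short-circuit to zero.

Contact lines are sampled on cylinders at radius $R-\delta$ in 1°
azimuth bins by bilinear in-plane interpolation of $\alpha$, and the
*topmost* crossing of the iso level (default 0.5) defines the contact
height — so at small offsets a wall film reports its upper rim, which
is precisely the film/bulk separation the multi-offset extraction is
for. Azimuths with no crossing carry `NA` rather than an error: a
sampling circle entirely in gas is a legitimate observation.

## The synthetic-field generator

`synthetic_field()` stands in for a VOF solver in all tests. It
emulates: planar Couette shear and rigid rotation (closed-form strain
measures), diffuse planar and spherical interfaces (closed-form
areas), and an annulus — a rotating liquid ring against a cylindrical
wall of radius 40.65 mm with a thinner trailing wall film (default
1 mm, the film thickness observed at ~100 mPa·s) and a rigid-rotation
velocity field. Diffuse interfaces use a clipped linear ramp of
prescribed thickness (≥ 4 cells) because $\int|\nabla\alpha|$ across
any monotone ramp telescopes to the geometric area independent of the
profile. When a liquid volume is requested, the bulk surface height is
solved by bisection *on the discretized field*: the ramped surface
makes the discrete volume continuous and monotone in the height, so
the request is met to well below 1 % — solving the ring's inner radius
analytically instead would quantize on cell boundaries. Velocity
jitter, when requested, is seeded and the snapshot is bit-identical
for a given seed.

What the generator does *not* emulate: out-of-phase sloshing
dynamics, curved free-surface shapes, turbulence fields consistent
with a transport model, or mesh-boundary effects of body-fitted
flask geometries. Passing tests on these fields therefore validate
the *operators* (differencing, integration, interpolation,
eigenanalysis), not the physical fidelity of any particular CFD
model.

## Problem sizes and tolerances

The test suite runs grids of 16³–64³ cells (a 64³ snapshot is ~2.6
million cell values), 10³ random tensors for the eigen-oracle
equivalence at $10^{-10}$, and 100-point fits for noisy parameter
recovery at 5 % — sizes at which every closed-form reference is
resolved well inside its stated tolerance while the whole suite runs
in well under a minute. The fixed-point tolerance is $10^{-10}$
relative with initialization independence demonstrated to within ten
times that tolerance.

## Known limitations

* Only uniform structured grids; unstructured CFD meshes must be
  resampled upstream.
* Single-snapshot operators; temporal averaging over snapshot
  sequences is left to a driver loop.
* Rheology is Newtonian or power-law only (no Carreau or
  Herschel–Bulkley), and the power-law behavior index is restricted
  to $(0, 1.5]$, with $(0.5, 1.5]$ for the iterative shear estimator.
* The 250 mL flask preset's inner diameter is a calibrated nominal
  value, not a measured one; supply `d` explicitly for a real flask.
* The out-of-phase correction is an empirical fit; below
  $Ph \approx 0.61$ it has no predictive content and the package
  clamps rather than extrapolates.
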