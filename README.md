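# shakeflask

Engineering characterization of orbitally shaken Erlenmeyer flasks —
the workhorse vessel of small-scale bioprocess development — with a
focus on elevated, shear-thinning viscosity, where mixing and oxygen
transfer degrade and the liquid can fall "out of phase" with the
shaker.

The package serves two audiences:

* **bench scientists** who need, from nothing but the operating
  conditions (shaking frequency, shaking diameter, flask size, filling
  volume, fluid rheology), the dimensionless state of a run, its
  in-phase/out-of-phase classification, the volumetric power input,
  the kLa value and an effective shear rate / effective Newtonian
  viscosity for a shear-thinning broth;
* **CFD practitioners** who have two-phase (volume-of-fluid) flow
  snapshots of a shaken flask on a structured grid and want the same
  process quantities extracted from the resolved fields, plus liquid
  contact lines at wall-normal offsets.

## The models

**Dimensionless groups and regime.** With shaking frequency $n$,
largest inner flask diameter $d$, shaking diameter $d_0$, filling
volume $V_L$, density $\rho$ and dynamic viscosity $\eta$:

$$Re = \frac{\rho\,n\,d^2}{\eta},\qquad
Re_{film} = Re\cdot\frac{\pi}{2}\left[1-\sqrt{1-\frac{4}{\pi}
\left(\frac{V_L^{1/3}}{d}\right)^2}\,\right]^2,\qquad
Ph = \frac{d_0}{d}\left(1+3\log_{10}Re_{film}\right).$$

Operation is fully in phase for $Ph \ge 1.26$; below $0.91$ the bulk
liquid collapses to the flask bottom (out of phase); in between the
transition is gradual.

**Power input.** In-phase volumetric power input follows the modified
Newton number correlation
$Ne' = 70\,Re^{-1} + 25\,Re^{-0.6} + 1.5\,Re^{-0.2}$ with
$Ne' = P/(\rho n^3 d^4 V_L^{1/3})$. Near and below the critical phase
number the correlation overestimates; the exponential correction
$y(Ph) = 1 - 3.43\,e^{-2.02\,Ph}$ rescales it (clamped at 0 below
$Ph \approx 0.61$, where the fit extrapolates).

**Oxygen transfer.** The bench correlation
$k_La = 0.5\,d^{73/36} n\,d_0^{1/4} V_L^{-8/9} \nu^{-13/54} g^{-7/54}
D_L^{1/2}$, with the diffusion coefficient $D_L$ estimated by the
Stokes–Einstein–Gierer–Wirtz model from molecular weights alone.
From CFD fields, the eddy-cell closure
$k_L = 0.4\sqrt{D_L}\,(\varepsilon/\nu)^{1/4}$ is combined per cell
with the interfacial area density $a_i = |\nabla\alpha_i|$.

**Shear and rheology.** Power-law (Ostwald–de Waele) fluids
$\tau = K\gamma^m$; the effective shear rate
$\gamma_{eff} = [2.06\,(P/V_L)/K\,(V_L^{1/3}/d)^{-0.33}]^{1/(m+1)}$
maps a shear-thinning broth onto an equivalent Newtonian viscosity
$\eta_{eff} = K\gamma_{eff}^{m-1}$ through a self-consistent fixed
point. From CFD fields, two estimators are provided: the strain-rate
norm $\|S\| = \sqrt{2\,S\!:\!S}$ and $2.5\,\lambda_1(S)$ from the
largest strain-tensor eigenvalue, including the iterative
non-Newtonian variant.

## Worked example

```r
library(shakeflask)

cond  <- shaking_conditions(n = rpm_to_hz(250), d = flask_preset("250mL"),
                            d0 = mm_to_m(25), VL = mL_to_m3(15))
fluid <- fluid_spec(rho = 1000, eta = mPas_to_Pas(16.7))

dimensionless_groups(cond, fluid)
#> Re = 1649.12, Re_film = 9.45216, Ph = 1.2074

pc <- power_input_corrected(cond, fluid)
#> P/VL in-phase: 3517 W/m3, corrected: 2464 W/m3 (quotient 0.701)

DL <- diffusion_coefficient(gmol_to_kgmol(32), gmol_to_kgmol(18),
                            T = 293.15, eta = fluid$eta)
kla_correlation(cond, fluid, DL) * 3600
#> DL = 1.07e-10 m2/s, kLa = 38.7 1/h

fp <- effective_viscosity_fixed_point(
  shaking_conditions(rpm_to_hz(250), d = flask_preset("250mL"),
                     d0 = 0.025, VL = mL_to_m3(25)),
  fluid_spec(rho = 1000, K = 0.104, m = 0.956))
#> eta_eff = 79.6 mPa.s after 10 iterations (gamma_eff = 436 1/s)
```

The phase number 1.21 sits between the two critical values: first
deviations from in-phase behavior are expected, and the corrected
power input is ~30 % below the in-phase correlation. The 104 mPa·s^m /
0.956 power-law fluid is assigned an effective Newtonian viscosity of
about 80 mPa·s — the value a constant-viscosity flow simulation of
that broth should use.

Snapshot post-processing mirrors this from resolved fields:

```r
syn <- synthetic_field("couette", gamma0 = 10, resolution = 32)
postprocess_snapshot(syn$grid, fluid_spec(rho = 1000, eta = 0.1))
#> eps = 0.01 W/kg, P/VL = 10 W/m3, mean shear 10 (strain norm) /
#> 12.5 (eigen) 1/s
```

A shell interface wraps the same functions
(`inst/cli/shakeflask.R`): `characterize`, `postprocess`,
`contactline`, `synth` and `fit-correction` subcommands operate on
delimited condition tables and legacy-VTK or delimited snapshots.

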