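---
title: "From shear rheology to perceived thickness: the model behind mouthfeel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From shear rheology to perceived thickness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mouthfeel)
```

## The problem

When a trained sensory panel rates the "thickness" of a liquid food — a
bouillon, a soup, a gum solution — what physical quantity are they
reporting? Liquid foods are almost never Newtonian: their viscosity drops
by one to two orders of magnitude over the shear rates met in the mouth,
so "the" viscosity at some single representative shear rate is an
ill-posed stimulus. `mouthfeel` implements a mechanistic alternative: the
stimulus is the *total shear stress on the tongue* while the fluid is
squeezed between tongue and palate, computed from the full
shear-thinning flow curve and the measured biophysics of oral
processing, with no adjustable parameters. The perceived thickness is
then related to that stress through a psychophysical law.

## Rheology: the power-law fluid

Flow curves are modelled as an Ostwald–de Waele power law,

$$\sigma = \kappa\,\dot\gamma^{\,n},$$

with consistency $\kappa$ (Pa s$^n$) and flow index $n$ ($n<1$:
shear-thinning; $n=1$: Newtonian with viscosity $\kappa$).
`fit_power_law()` estimates $(\kappa, n)$ by ordinary least squares of
$\log\sigma$ on $\log\dot\gamma$. The log–log (rather than linear-space
nonlinear) fit is deliberate: flow curves span decades of shear rate, and
log-space OLS weights every decade equally instead of letting the
highest-rate points dominate. The log base is internal and cancels from
the estimates. No yield-stress (Herschel–Bulkley) term is offered:
yield-stress fluids violate the squeeze-flow model downstream and are out
of scope. Temperature is carried as metadata only; all shipped data were
measured at 40&nbsp;°C, mouth temperature.

The fit records the shear-rate window it was given (`rate_range`)
because the window used for the shipped $(\kappa, n)$ values is not
recorded with the data; the fitter deliberately fits whatever range the
input provides.

## Oral geometry: why two parallel plates

The model idealises the tongue–palate system as two rigid parallel
plates. That is defensible because the tongue
($E_{tongue}\sim 2.5\!-\!10$ kPa) is vastly softer than the palate
($E_{palate}\sim 30\!-\!50$ MPa): the tongue flattens against the palate
and all elastic compliance sits on one side. The indentation depth under
the lingual force follows the Hertz soft-contact relation

$$\delta = \left(\frac{9 F_N^2}{16\,R_{tongue} E_{tongue}^2}\right)^{1/3},$$

about 7 mm at the defaults — small compared with the tongue's
5 cm radius of curvature, so the geometry stays plate-like
(`parallel_plate_validity()` checks both this and the modulus ratio).
The implied Hertz contact radius $a=\sqrt{\delta R_{tongue}}\approx 2$ cm
agrees to one significant figure with the independently measured licking
radius of 2.5 cm; the contact-radius formula is our interpretation
(only the resulting number is published), and the flow model uses the
licking value $R = 2.5$ cm as its default without attempting to
reconcile the two.

### Default parameters

| parameter | default | units | meaning |
|---|---|---|---|
| `F_N` | 0.5 | N | lingual normal force |
| `V` | 0.15 | m/s | lateral tongue speed |
| `V0` | 4e-6 | m³ | bolus volume (one tablespoon) |
| `R` | 0.025 | m | contact-disk radius (licking test) |
| `h0` | `V0/(pi R^2)` ≈ 2.04e-3 | m | initial gap (derived) |
| `t_assess` | 1.2 | s | in-mouth assessment time |
| `R_tongue` | 0.05 | m | tongue radius of curvature |
| `E_tongue` | 3e3 | Pa | tongue Young's modulus |
| `E_palate` | 4e7 | Pa | palate Young's modulus |
| `theta` | 30 | deg | contact angle (metadata) |

`E_tongue = 3` kPa is our choice within the published 2.5–10 kPa soft
tissue range: it reproduces the published 7 mm deformation at nearest-mm
rounding, and the exact value used by the original analysis is not
stated. `h0` is derived from volume conservation
($h_0 \pi R^2 = V_0$) unless overridden, in which case the package warns
and skips the consistency invariant. The contact angle enters no
equation: similar wetting across samples is only the argument that all
products share the same initial configuration.

## Dynamic squeezing: gap and stress histories

The tongue translates at speed $V$ while pressing with constant force
$F_N$; the film thins, the shear rate $V/h(t)$ grows, and the stimulus
is the lateral viscous stress

$$\sigma(t) = \kappa\left(\frac{V}{h(t)}\right)^{n}.$$

Thin-film (lubrication) analysis of the power-law momentum balance, with
the flux from the tongue's drag motion equated to drag-plus-squeeze flux,
gives a parabolic excess pressure over the contact disk,

$$P(x,y) = \frac{6\kappa n \dot h}{h^{n+2}V^{1-n}}\,(R^2 - x^2 - y^2),$$

whose integral over the disk is the load
$F_N = 3\pi\kappa n \dot h R^4 / (h^{n+2}V^{1-n})$. Solving that load
balance for $h$ by separation of variables yields

$$h(t) = h_0\left(1 + \frac{(n+1)\,F_N h_0^{n+1} V^{1-n}}
  {c\,\pi n \kappa R^4}\,t\right)^{-1/(n+1)},$$

and $\sigma(t)$ follows by substitution. For $n = 1$ the $V$-dependence
cancels exactly — a Newtonian squeeze film does not care about lateral
sliding — and the package guarantees this *bitwise* (the code computes
$V^{1-n}$, which is exactly 1.0 in floating point when $n = 1$).

### The bracket-constant discrepancy (`variant`)

The two published forms of this result are mutually inconsistent: the
result-section expressions carry $2\pi n \kappa R^4$ in the bracket's
denominator while the derivation's final expression carries
$3\pi n \kappa R^4$ — a factor 2/3 that follows through to the stress.
Only the factor-3 form is consistent with the pressure-integral load
balance above. Rather than silently pick one, both are first-class:

* `variant = "derivation"` — the self-consistent form; the only variant
  checked against the numerical ODE oracle.
* `variant = "main_text"` (default) — the form printed alongside the
  published stress-vs-score analysis, hence the default for reproducing
  it.

For every input, `main_text` squeezes faster: gap(main_text) ≤
gap(derivation) and stress(main_text) ≥ stress(derivation). Over the 20
shipped samples at the assessment time the two differ by up to ~15% in
stress, which moves the fitted psychophysical intercept slightly and the
science not at all; the test suite asserts the ordering and both
variants' stress envelopes.

### Numerical choices

* **ODE oracle.** `integrate_gap_ode()` integrates
  $\dot h = -F_N h^{n+2} V^{1-n} / (3\pi\kappa n R^4)$ with an embedded
  Dormand–Prince 5(4) pair written in the package (no ODE-solver
  dependency), rtol 1e-8. The absolute tolerance is 1e-15 m: late-time
  films reach $\sim 10^{-7}$ m, and an absolute floor of 1e-12 m — a
  superficially reasonable "sub-nanometre" choice — would cap the
  achievable relative accuracy near 3e-6 and mask genuine closed-form
  errors. With 1e-15 the closed form and the integrator agree to better
  than 1e-8 relative across the randomised test suite.
* **Film floor.** The gap is floored at 1e-9 m with a warning; film
  rupture, surface roughness and papillae-scale contact below that
  thickness are not modelled.
* **Velocity profile.** The exact power-law Couette–Poiseuille profile
  has an integration constant $c_1$ fixed by the tongue-side no-slip
  condition; the published first-order value
  $c_1 \approx (n/(n+1))^n (V/\alpha)^n$ holds only when the drag flow
  dominates the squeeze outflow ($V \gg \alpha$). The package solves the
  boundary condition for $c_1$ exactly by 1-D root bracketing (Taylor
  value as the starting guess), so both no-slip conditions hold to
  1e-9 for any admissible gradient, and returns the Taylor value
  alongside for comparison. The two branches of the profile are mapped
  onto the gap coordinate $z \in [0, h]$, tongue at $z=0$, and the
  branch labels follow the *signed* pressure gradient so that the
  Newtonian limit reduces to the classical
  $u = V(1-z/h) - \frac{dP/dx}{2\kappa} z(h-z)$; the published branch
  labelling (which mixes a mid-plane and a wall-anchored coordinate
  convention) is adjusted accordingly.
* **Pressure quadrature.** The disk pressure field is evaluated on a
  201×201 Cartesian cell-centre grid masked to the disk, and the load by
  the masked midpoint rule; the integrand vanishes at the rim, so the
  boundary-cell error is benign (measured 1e-6 relative against the
  analytic $\int (R^2-r^2)\,dA = \pi R^4/2$). Resolutions are arguments.
* **Validity ratio.** `approximation_ratio()` evaluates
  $\alpha/V$ where the pressure gradient is largest — the rim along the
  direction of motion (the assessment location is not published; the rim
  maximises $|\partial P/\partial x|$ and is therefore conservative).
  Note the ratio *diverges* as $t \to 0$: a step load on a fresh film
  implies a large initial closing rate, so the model's algebra is not
  trustworthy in the first instants. The published validity claim — and
  our tests — concern the assessment time, where the worst ratio over
  the 20 shipped samples is 0.205.

## Psychophysics: Weber–Fechner vs Stevens

Two candidate laws link stress to score $S$ on the 0–15 category scale:

* Weber–Fechner (logarithmic, 2 parameters):
  $S = a + b \log_{10}\sigma$, fitted by OLS (`fit_weber_fechner()`,
  optional 1/SEM² weighting off by default — the published analysis
  fits mean scores, and no weighting scheme is stated).
* Stevens (power, 3 parameters): $S = c + k\sigma^{m}$, fitted by
  deterministic multi-start nonlinear least squares
  (`fit_stevens()`: starts $m \in \{0.1, 0.3, 0.5, 1.0\}$, $(c,k)$ by
  linearisation at each start, box-constrained quasi-Newton polish with
  $m \in [10^{-3}, 5]$, then a *local* 1-D refinement of the SSE
  profiled over $m$, with $(c,k)$ restored by OLS). Best SSE wins, ties
  to the smallest $m$. The additive offset $c$ is what makes Stevens
  the "one extra parameter" model relative to the log law.

A structural caveat the package documents rather than hides: the power
family contains the log law only as the degenerate boundary limit
$m \to 0$, $c \to -\infty$, $k \to +\infty$ with $km$ finite. On data
that are genuinely logarithmic the Stevens optimum sits on this ridge;
the profiled SSE approaches the Weber–Fechner SSE from above and never
strictly beats it. The optimiser deliberately refines only *locally*
around the multi-start winner, so it stalls partway along the ridge (at
$m \approx 0.02$ on the shipped training data, SSE 0.3% above the log
law's) instead of collapsing onto a numerically indistinguishable copy
of the log fit — which would make any train-set comparison of the two
laws meaningless. The test suite asserts both facts: the default fit's
SSE is within 1% of the log law's, and the ridge limit at $m=10^{-4}$
is within 1e-4 relative of it.

The decisive comparison is therefore *extrapolation*, not training fit:
`compare_fits()` fits both laws on the bouillon samples (sets 1 & 2,
stresses ≈ 2.9–8.7 Pa) and evaluates both, frozen, on the high-stress
xanthan set 3 (up to ≈ 89 Pa, a decade beyond the training range). The log law's held-out RMSE (0.845 score
units) beats the power law's (0.859): tongues, like eyes and ears, look
logarithmic. Residuals are reported raw (`chi`) plus RMSE;
SEM-standardised residuals are available since the published residual
definition is not.

`predict_thickness()` turns any fitted law plus a fluid's $(\kappa, n)$
into a score, clamped to the 0–15 scale with a warning.

## The synthetic-data generators: what a green test establishes

`generate_flow_curve()` applies multiplicative lognormal noise
(sdlog = `noise_sd_rel`) to an exact power law on a 30-point, 4-decade
rate grid — relative error being the natural rheometer error model.
`generate_panel_scores()` draws each panelist's score as the true law's
value at the product's model stress plus Normal(0, `panel_noise_sd`)
noise, clamped to 0–15. Defaults state the emulated world once: 12
panelists (a trained descriptive panel), score noise 0.8 (matching the
shipped SEM·√n magnitudes of ≈0.6–1.0), rheometer noise 5%. All
randomness flows from one integer seed (flow-curve stream = seed, panel
stream = seed + 1), and the generators restore the caller's RNG state.

What the generators do *not* emulate: panelist-specific bias and drift,
replicate-session effects, non-normal score distributions near the scale
ends, correlated rheometer errors, and any deviation of real fluids from
an exact power law. A green parameter-recovery test therefore
establishes that the estimators are correct and well-conditioned under
the stated noise model — not that real panel data are this kind.

## Known limitations

* Inertia, gravity, capillary rim effects, saliva dilution, particle
  content, viscoelasticity and yield stress are all outside the model;
  strongly elastic or yielding foods need different hydrodynamics.
* The early-time regime ($t \lesssim$ tens of ms) violates the
  $V \gg \alpha$ expansion (see above); quantities are meaningful at
  assessment-scale times.
* The two published equation variants cannot both be right; the package
  exposes the choice instead of resolving it.
* Set-3 scores are consumed as already converted to the 0–15 scale;
  the original category-scale conversion is not re-derived.
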