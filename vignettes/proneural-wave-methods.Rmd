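---
title: "Modelling the proneural wave: equations, parameters and estimator conventions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the proneural wave}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(pnwave)
```

`pnwave` simulates the proneural wave of the *Drosophila* optic lobe: a
travelling front of proneural gene expression that converts neuroepithelial
cells (NE) into neuroblasts (NB). This vignette is the package's own account
of the model hierarchy, of the reconstructed default parameter set and how
it was fixed, of the numerical scheme, and of every estimator convention
the observables use. Nothing here states an empirical result that the test
suite or `scripts/acceptance.R` does not itself compute.

## The model hierarchy

**Single-component EGFR front.** EGFR signalling (the EGFR/Rhomboid/Spitz
autocrine loop) is condensed into one diffusible, self-activating variable
$\phi_E$:

$$\partial_t \phi_E \;=\; \eta \nabla^2 \phi_E + \mu\, h(\phi_E) - k\,\phi_E,
\qquad h(\phi) = \frac{(\phi/a)^n}{1 + (\phi/a)^n}.$$

Time is measured in units of the EGFR decay time ($k = 1$) and position in
cell diameters. With $\mu/k = 4$, $n = 3$, $a = 1$ the kinetics is bistable
(stable roots $0$ and $\approx 3.935$, unstable threshold $\approx 0.537$;
`e_kinetic_roots()`), and the reaction-diffusion system carries a front
that invades the rest state.

**EGFR + L'sc pulse.** The proneural gene *l'sc* ($\phi_L$) is activated by
EGFR signalling and, by driving the fate transition, shuts the EGFR gain
down:

$$\partial_t \phi_E = \eta \nabla^2 \phi_E +
  \mu_E h(\phi_E)\,[1 - h(\phi_L)] - k_E \phi_E, \qquad
  \partial_t \phi_L = \mu_L h(\phi_E) - k_L \phi_L.$$

This indirect negative feedback converts the bistable front into an
excitable pulse: a localised band of signalling travels while the wake
returns to rest. Note that with the reference values ($\mu_L = 0.4$,
$k_L = 0.2$, all thresholds 1) the space-free system is excitable but not
globally monostable — it retains non-attracting fixed points at
$\phi_E \approx 0.56$ and exactly $(1, 1)$; the substantive property is the
stable rest state plus the large super-threshold excursion that returns to
it, which is what the tests assert.

**Integrated lattice model.** On a cell lattice (1D chain, hexagonal patch
or hexagonal disc; unit spacing; no-flux boundaries), per cell $i$ with
neighbour mean $\bar\phi_D = \mathrm{mean}_{j \sim i}\, \phi_{D,j}$:

$$\begin{aligned}
\partial_t \phi_E &= \eta \nabla^2 \phi_E +
  (1-\Omega)\bigl[\mu_E h_{EE}(\phi_E)(1 - h_{LE}(\phi_L)) +
  \sigma_N h_{NE}(\phi_N)\bigr] - k_E \phi_E\\
\partial_t \phi_L &= (1-\Omega)\, \mu_L\, h_{EL}(\phi_E)\,
  (1 - h_{NL}(\phi_N)) - k_L \phi_L\\
\partial_t \phi_D &= (1-\Omega)\, \mu_D\, h_{ED}(\phi_E)\,
  (1 - h_{ND}(\phi_N)) - k_D \phi_D\\
\partial_t \phi_N &= \bigl[\beta + \mu_N h_T(\bar\phi_D)\bigr]\,
  (1 - h_C(\phi_D))\,(1 - h_{LN}(\phi_L)) - k_N \phi_N\\
\partial_t \Omega &= k_\Omega (1-\Omega)\bigl[h_{L\Omega}(\phi_L) +
  h_{E\Omega}(\phi_E)(1 - h_{N\Omega}(\phi_N))\bigr]
\end{aligned}$$

Each Hill factor realises one regulatory arrow: EGFR autocatalysis
($h_{EE}$), L'sc shutdown of EGFR ($h_{LE}$), Notch upregulation of EGFR
signalling ($\sigma_N h_{NE}$), EGFR activation of L'sc and Delta
($h_{EL}$, $h_{ED}$), Notch repression of L'sc and Delta ($h_{NL}$,
$h_{ND}$), trans-activation of Notch by neighbour Delta ($h_T$),
cis-inhibition by the cell's own Delta ($h_C$), L'sc downregulation of
Notch ($h_{LN}$), and the two routes of the irreversible NE→NB transition:
L'sc-driven, and EGFR-driven when Notch is low. The factor $(1-\Omega)$
shuts transition-zone signalling down in completed neuroblasts; Notch
production itself is not gated, so Notch recovers to its basal level
$\beta/k_N$ in both NE and NB, with the trough confined to the zone. A cell
is classified NB when $\Omega \ge 1/2$.

The discrete Laplacian uses coefficient 1 on chains and $2/3$ on hexagonal
lattices, matching the continuum operator at unit spacing. Two open
structural choices were resolved as follows: Notch→EGFR upregulation enters
*additively* ($\sigma_N h_{NE}$; a multiplicative variant is available via
`model_params(notch_E = "multiplicative")`, but it cannot pre-elevate the
EGFR rest state and therefore cannot carry the wave at $\eta = 0.03$, see
below), and $\Omega$ is continuous and monotone rather than binary.

## The reconstructed default parameter set

The integrated model's reference values (see `model_params()`) are a
*reconstruction*: they were chosen, once, so that the documented qualitative
behaviours of the system hold simultaneously, and they are fully
overridable. The binding constraints, in the order they shaped the set:

* **Propagation at $\eta = 0.03$** (the 1D profile scenario, preset
  `"fig2e"`). At this diffusion constant a bare bistable front is pinned on
  a unit-spaced cell array. Propagation requires the Notch→EGFR term to
  pre-elevate the neuroepithelial EGFR rest state close to the excitation
  threshold: with $\sigma_N = 0.2$ and $h_{NE}$ half-activating at 5, the
  basal-Notch state $\phi_N = \beta/k_N = 10$ yields a rest state
  $\phi_E \approx 0.22$ against a threshold $\approx 0.35$, and the front
  creeps at $\approx 0.22$ cells per decay time. The same term makes basal
  Notch a genuine wave-speed regulator at all $\eta$. The excitation must
  also outlive the slow cell-to-cell ignition, which fixes slow L'sc
  kinetics ($\mu_L = 0.8$, $k_L = 0.25$): the L'sc rise, not the transition
  rate, times the shutdown of the pulse.
* **Two-cell lateral inhibition patterned at $\beta = 1$, suppressed at
  $\beta = 10$.** The Delta-Notch thresholds ($h_{ND}$ at 3, $h_C$ at 5,
  $h_T$ at 2) and gains ($\mu_D = 20$, $\mu_N = 12$) place the symmetric
  fixed point of the two-cell subsystem in the steep part of the Hill
  curves at low basal Notch (anti-symmetric eigenvalue $+0.8$ at
  $\beta = 1$) and in the oversaturated low-Delta regime at high basal
  Notch ($-0.3$ at $\beta = 10$, Delta level decreasing in $\beta$).
* **Wave timing on the 20×20 patch.** $\eta = 0.15$ puts the wavefront
  mid-tissue at $t = 25$ (speed $\approx 0.58$), keeps the $\beta = 1$
  tissue propagating (speed $\approx 0.3$ without the Notch boost), and
  leaves the transition zone $\approx 4$ cells wide.
* **Transition completion.** With $k_\Omega = 0.5$ and the L'sc gate at 1,
  the wake cell state saturates near $\Omega \approx 0.8$ (the drives decay
  before $\Omega$ reaches 1 exactly); NB classification at $\Omega \ge 1/2$
  is unambiguous, and the "ahead 0 / behind $\to$ 1" contrast is sharp. A
  faster $k_\Omega$ would push the wake closer to 1 but truncates the
  excitation and kills propagation in the slow-ignition regimes.

One documented behaviour is *not* reproduced by this reconstruction: a
basal-Notch-knockout clone ($\beta = 0$ inside the clone) classifies as
front-*delayed* (with a narrower, faster local transition) rather than
front-*advanced*. This is a direct consequence of the first constraint:
basal Notch upregulates EGFR signalling ahead of the front, so cells
lacking it carry the front more slowly, and the premature-differentiation
advance inside the clone does not fully compensate. The alternative
couplings we examined (multiplicative Notch→EGFR, transition-route
re-weightings, steeper or softer Notch-on-L'sc repression) either restore
this phenotype at the cost of $\eta = 0.03$ propagation or break the
two-cell phase diagram; the package keeps the reconstruction above and
reports the discrepancy openly (see the clone test).

## Stochastic integration

Time stepping is explicit forward Euler (Euler–Maruyama when noisy), with
the step validated against $dt \le 0.2/(k_{\max} + \eta c\,
\mathrm{deg}_{\max})$; the model is non-stiff at reference-scale
parameters, and halving $dt$ changes final states at first order. Noise
increments are independent Gaussians of standard deviation
$\gamma \sqrt{dt}$ added to a field's update, after which fields are
clipped at zero. At the documented strength $\gamma/\mu_E = 0.5$, noise on
$\phi_E$ ignites the bistable EGFR kinetics tissue-wide within about one
decay time and destroys the ordered wave entirely — for additive and for
$\sqrt{\phi}$-scaled increments alike — so the biochemical noise enters
the *Delta* equation (`noise_fields = "phi_D"` by default for the
integrated variant): fluctuations in ligand presentation are exactly what
seeds, or fails to seed, lateral-inhibition patterning, and this placement
leaves the wave intact and the Notch readout undiluted. The placement and
scaling are arguments of `integrate_model()`, not hard-wired.

## Estimator conventions

The observables attach numbers to features the model produces; none of
their definitions are canonical in the literature, so the conventions are
stated here and frozen in code:

* **Wavefront position**: furthest coordinate along the wave axis where
  the column-averaged transition indicator ($\Omega$, or normalised
  $\phi_E$ for the single-component model) crosses $1/2$, linearly
  interpolated between columns. **Speed** is the least-squares slope of
  front position over a window that drops the first 20% of the run; the
  fit $R^2$ is reported alongside.
* **Transition-zone width**: interpolated extent of the region where the
  L'sc column profile exceeds half of its instantaneous maximum,
  time-averaged over the central 60% of the run. L'sc, not EGFR, defines
  the zone.
* **Notch pre-peak**: a local maximum of the Notch column profile ahead of
  the zone centre (the L'sc maximum), exceeding both the neuroepithelial
  plateau and the zone-centre Notch level by a 2% margin. Because the
  discrete front advances cell by cell, instantaneous profiles lurch
  within each cell-crossing period; the detector therefore averages
  profiles in the co-moving frame over a configurable time window
  (averaging monotone profiles cannot fabricate a bump, so the smoothing
  is conservative).
* **Salt-and-pepper index**: mean over undirected neighbour pairs of the
  product of standardised deviations (population moments) of a field over
  a cell mask — a Moran-type autocorrelation that is $-1$ for an
  alternating two-colouring of a chain, about $-0.5$ for an ideal
  one-in-three hexagonal pattern (the triangular lattice is frustrated),
  and 0 in expectation for spatially random fields. The
  lateral-inhibition protocol (`pattern_index_behind_front()`) scores the
  Notch field over NE cells at or behind the front within 2.5 cell
  diameters of a transitioned cell — the conversion band where the
  laterally inhibited state is expressed before the transition consumes
  it — with the field averaged per cell over a ±2.5 time window to cancel
  the uncorrelated component of the biochemical noise. The package
  calibration constants for the two basal-Notch regimes (median index
  below $-0.2$ at $\beta = 1$, above $-0.05$ at $\beta = 10$, ≥10 seeds)
  are verified by the acceptance tests.
* **Clone phenotypes**: the classifier compares band-restricted front
  positions (the rows spanned by the clone) at the evaluation time;
  `advanced`/`delayed` requires at least one column of shift, and `lost`
  requires that fewer than 25% of clone cells have transitioned by the end
  of the run while the wildtype wave has passed. The default protocol uses
  a 6×10-cell clone placed ahead of the wavefront, evaluation at
  $t = 25$ ($t = 17.5$ for constitutively active EGFR or L'sc, which
  transition autonomously), and a run to $t = 60$ so that slow transitions
  are not misread as loss.

## Two-cell analysis

`lateral_inhibition_occurs()` finds the symmetric fixed point by a scalar
root scan (the smallest root — the one connected to the low-Delta rest
state), evaluates the Jacobian numerically, and projects it onto the
exchange-symmetric and anti-symmetric subspaces. Patterning is declared
when the state is stable to homogeneous perturbations but unstable to
anti-symmetric ones; with $\lambda = 0$ the two subspace Jacobians
coincide and the criterion is never met. The independent route
(`two_cell_pattern_sim()`) integrates from a 1% anti-symmetric perturbation
of the fixed point and declares patterning when the Delta difference
exceeds 10% of its mean; the acceptance test requires ≥95% agreement
between the two routes on a 10×10 grid, with disagreements tolerated only
near the stability boundary. The patterned $(\beta, \lambda)$ region is an
interval in $\beta$ at fixed $\lambda$ — bounded above by basal-Notch
oversaturation, and (for large $\lambda$) bounded below as well, where
trans-activated Notch itself saturates the system.

## Morris screening

`run_sensitivity()` screens $\eta$, $\mu_i$, $k_i$ ($i = E, L, D, N$) and
$\beta$ on a 4-level log-spaced grid with the standard jump
$\Delta = p/(2(p-1))$, measuring wave speed and zone width on a 70-cell
chain run to $t = 45$. Ranges default to ±20% of the reference values:
the travelling-wave regime occupies a finite band of parameter space
(fronts pin at low $\mu_E/k_E$ and $\eta$; the whole tissue ignites
spontaneously at high $\mu_E$), and at ±50% two thirds of sampled corners
are degenerate, starving the effect estimates. Degenerate runs — no front,
a stalling front, or a front fit with $R^2 < 0.9$ — are excluded and
counted, and trajectories are topped up deterministically until every
parameter has at least two valid effects. With the default plan the speed
ranking is $\eta > k_E > k_N \approx \mu_E \gg \mu_L, k_L$ and the width
responds positively to $\beta$ — the acceptance suite asserts exactly
these rank statements, not numeric index values.

## Problem sizes

The shipped tests and the acceptance script run at desk scale: chains of
80–400 cells, the 20×20 hexagonal patch, the radius-15 disc (823 cells),
10 stochastic replicates for the noise analysis, r = 20 Morris
trajectories, and a 10×10 phase-diagram grid. These sizes were chosen so
that every documented behaviour is resolved with margin; all of them are
ordinary function arguments and scale up directly.

## What the synthetic fixtures do and do not show

`make_fixture()` builds step fronts, Gaussian pulses, checkerboards and
seeded random fields with attached analytic ground truth; they validate
the estimators (front interpolation, half-maximum widths, index
normalisation) independently of the dynamics. Passing them shows the
observables measure what they claim on clean inputs — it does not validate
the biology. Conversely, the model tissue is a static lattice: no growth,
division or rearrangement, no additional signalling pathways, and
cell-state progression summarised in a single order parameter. Conclusions
about real neuroepithelium rest on the qualitative behaviours the tests
pin down, not on quantitative agreement with imaging data.
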