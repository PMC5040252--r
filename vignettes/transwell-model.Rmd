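---
title: "Modelling impedance-based transwell migration assays"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling impedance-based transwell migration assays}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The assay and the model

A transwell (Boyden-chamber style) migration assay places tumour cells in
the upper compartment of a two-chamber well separated by a porous
membrane; a chemoattractant — here fetal bovine serum (FBS) — may be
loaded in the lower compartment. Real-time impedance instruments read the
occupation of a sensor on the lower face of the membrane as a unitless
*Cell Index* (CI), which depends linearly on the number of cells that have
crossed, together with their adhesion and spreading.

`rtcasim` models one well as a one-dimensional domain $[0, 1.8]$ cm (the
axis points from the top lid down), with the membrane at $x_M = 0.9$ cm.
Two fields evolve: the cell line density $u(x,t)$ (cell/cm) and the serum
density $\varphi(x,t)$ (µl/cm):

$$
\partial_t u = D_u \partial_x^2 u
  - \partial_x\!\big(u\,\chi(\varphi)\,\partial_x \varphi\big)
  - \partial_x (V_{\mathrm{transp}} u) + g(u, \varphi),
\qquad
\partial_t \varphi = D_\varphi \partial_x^2 \varphi - \delta\, u\, \varphi .
$$

* **Chemotaxis** has the saturating sensitivity
  $\chi(\varphi) = \chi_1 \varphi/(\chi_2 + \varphi)$
  (`chemotactic_sensitivity()`). With the calibrated
  $\chi_2 \approx 5\times10^{-8}$ µl/cm the response is effectively
  saturated at any nonzero serum level: what matters dynamically is the
  serum *gradient* direction and $\chi_1$.
* **Spontaneous transport** at speed $V_{\mathrm{transp}}$ (top to
  bottom) captures basal migration through the pores in the absence of
  any gradient.
* **Adhesion/spreading**
  $g = \alpha_1 u (1 - u/\alpha_3)\,
  \frac{\varphi}{\alpha_2+\varphi}\,\frac{\alpha_2+\bar\varphi}{\bar\varphi}\,
  W(x)$ (`adhesion_spreading_rate()`) is a logistic increase of the
  sensed signal, promoted by serum and normalised so that the factor is 1
  at the proliferation-assay concentration $\bar\varphi$ — which is where
  $\alpha_1$ and $\alpha_3$ are estimated from logistic fits of
  proliferation curves (`fit_logistic_proliferation()`). The weight
  $W(x)$ (`spreading_weight()`) confines the effect to the membrane
  neighbourhood and the lower chamber: zero above
  $\bar x = x_M - $ `x_bar_offset`, a smooth bump ramp up to the
  membrane, one below it. `x_bar_offset` defaults to $4\times10^{-3}$ cm,
  about two 20 µm cell diameters; the exact diameter per line is not
  critical because $W$ only gates where spreading is credited.
* **Membrane transmission** is a Kedem–Katchalsky condition: the flux
  through the membrane is proportional to the jump of the one-sided
  traces. For serum the coefficient $k_\varphi$ is constant; for cells it
  is crowding-limited,
  $k_u = k_{u1}/(1 + k_{u2} u_T + k_{u3} N_B^{\,p})$
  (`membrane_transmission()`), with $N_B$ the cell number already in the
  lower chamber and $p = 2$ (exposed as `p_crowd`; quadratic crowding is
  what matches the data).
* The outer lids are no-flux for both fields.

Basal (serum-free) assays correspond to $\chi_1 = \alpha_1 = 0$
(`make_basal_parameters()`), which decouples the cell equation from the
serum equation. Built-in parameter sets for the chondrosarcoma
(`"sarc"`), fibrosarcoma (`"ht1080"`) and melanoma (`"a375"`) lines are
available from `preset_parameters()` and as YAML configs under
`inst/extdata/presets/`.

Initially the cells occupy a slab of the upper chamber at density $u_0$
and the serum fills the lower chamber at $\varphi_0$. The slab is placed
adjacent to the membrane (cells sediment onto it; the interval has length
$n_{\mathrm{total}}/u_0$, configurable through
`initial_conditions(omega_u = ...)`). The 60-minute pre-equilibration of
the media before seeding is not modelled.

## Discretisation

`build_mesh()` lays out a non-uniform mesh: coarse spacing `dx_coarse`
(default $10^{-2}$ cm) away from the membrane, refined to `dx_fine`
(default $10^{-6}$ cm) inside one coarse cell on each side, with the
membrane node *duplicated* into an upper and a lower trace that carry the
one-sided limits of the discontinuous fields.

Each time step (default $\Delta t = 10^{-3}$ h) advances serum first,
then cells, both reading the other field at the previous level:

* diffusion is implicit (central three-point stencil, the standard
  non-uniform generalisation at the coarse/fine junction);
* advection at the velocity
  $V = \chi(\varphi)\partial_x\varphi + V_{\mathrm{transp}}$ is explicit
  and centred, stabilised by a $|V|$-weighted artificial-viscosity second
  difference. The pair is implemented as a Rusanov-type numerical flux:
  on uniform spacing this is algebraically identical to the centred +
  viscosity form, and in flux form the interior update telescopes, so no
  mass is created or destroyed at the mesh-spacing changes;
* the reaction terms ($g$ and $-\delta u \varphi$) are explicit;
* the four constraint rows — second-order one-sided no-flux rows at the
  lids and the two membrane-flux rows — are assembled into the same
  banded linear system (solved by LAPACK's banded solver) with their
  nonlinear coefficients ($\chi$, the serum jump, $k_u$) frozen at the
  previous level. Writing the interface equations inside the implicit
  solve avoids an $O(\Delta t)$ splitting error at the membrane while
  keeping the explicit coefficient treatment.

At the membrane the advective flux uses the serum gradient implied by the
serum interface law, $\partial_x \varphi = k_\varphi
(\varphi_B - \varphi_T)/D_\varphi$, so the cell and serum conditions stay
mutually consistent.

### Why the fine membrane zone is not optional

The membrane rows balance the one-sided diffusive derivative
$D_u/(2\Delta x)$ against the advective trace terms. In migration mode
the chemotactic velocity at the membrane is of order 1 cm/h; with a
coarse spacing ($\Delta x = 10^{-2}$ cm, $D_u/(2\Delta x) = 0.05$ cm/h)
the trace system becomes near-singular and the traces swing negative.
With the default $10^{-6}$ cm refinement the diffusive coefficient is
500 cm/h and the system is well conditioned. Coarser refinements down to
about $10^{-4}$ cm remain usable and are what the test suite runs for
speed; the 12 h migrated-cell count moves by only ~0.5% between
$10^{-4}$ and $10^{-6}$.

### Non-negativity policy

Genuine instability makes the solution oscillate and blow up, and the
solver aborts rather than clipping, advising a smaller `dt`. The abort
threshold is `negativity_tol` (relative to the field maximum, default
$10^{-7}$): the second-order one-sided lid rows extrapolate a steep
exponential tail slightly negative while the diffusing front first
reaches a lid — a decaying, bounded artefact around $10^{-10}$ of the
maximum at the default mesh, orders of magnitude below any instability.
On deliberately coarse validation meshes the artefact grows (relative
$10^{-3}$ at $\Delta x = 0.05$ cm), and the oracle-comparison test passes
a looser tolerance explicitly.

### What is and is not conserved

The interior update is written in flux form and conserves cell mass
exactly; serum mass is conserved to solver round-off when $\delta = 0$
and decreases monotonically otherwise. The four constraint rows are
algebraic, not flux-balanced cells, and contribute two small mass errors
without growth terms: a one-off membrane transient while the trace
boundary layer forms (first step $\sim 10^{-5}$ relative, decaying within
a few steps) and a persistent lid term of order $D_u \Delta x\, u''$ once
the diffusive tail reaches the lids. Integrated over 12 h at the default
discretisation the net drift is about $10^{-4}$ relative — two cells out
of twenty thousand. This is inherent to the one-sided boundary rows; a
conservative finite-volume lid closure would remove it but would change
the boundary discretisation this package implements.

## Observables and comparison

`migrated_cell_number()` integrates the density over the whole lower
chamber (trapezoid, lower trace included) — cells that crossed remain
counted wherever they drift. `to_cell_index()` applies the linear CI map;
the slope/intercept for a given experiment come from a proliferation fit
with known seeding (`fit_logistic_proliferation()`), and all relative
quantities (sensitivity indices, relative MSE between proportionally
mapped curves) are independent of the slope, which is why the analysis
defaults to a proportional map.

Curves are compared by the relative mean-squared error
$\mathrm{MSE} = \sum_i (\hat c_i - c_i)^2 / \sum_i c_i^2$
(`relative_mse()`), with the simulated curve linearly interpolated onto
the experimental time grid and simulated samples outside that grid
dropped rather than extrapolated.

## Sensitivity analysis

`sensitivity_table()` perturbs one parameter at a time by
±`eps_fraction` (default 5%), reruns the full migration model and reports
the signed percentage change $\Delta f_{\mathrm{rel}}$ of the 12 h Cell
Index and the local index
$S = |\Delta f / f_0| \cdot (\varepsilon/p_0)^{-1}$. For the 5% default
the identity $S = |\Delta f_{\mathrm{rel}}|/5$ holds exactly by
construction. Interactions between parameters are deliberately ignored;
this is a first exploration of the parameter space, not a global
(Sobol/Morris) analysis. The table defaults to the chondrosarcoma set at
$2\times10^4$ cells/well, the line the assays characterise most fully.

## Staged calibration and identifiability

`calibrate_parameters()` follows the staged protocol:

1. **proliferation** — logistic fit of E-plate curves gives $\alpha_1$,
   the capacity and the CI map;
2. **basal** — with $\chi_1 = \alpha_1 = 0$, the non-chemotactic
   parameters ($D_u$, $V_{\mathrm{transp}}$, $k_{u1}$, $k_{u2}$,
   $k_{u3}$) are fitted to basal curves;
3. **migration** — the chemotactic/serum parameters ($\chi_1$, $\chi_2$,
   $\alpha_2$, $\delta$, $k_\varphi$) are fitted to the chemotactic
   curves with the earlier stages frozen.

The optimiser is a bounded Nelder–Mead simplex on log-parameters (all
free parameters are positive spanning decades), with penalty-enforced
boxes, a fixed-seed Latin-hypercube multi-start (5 by default) and, in
one dimension, golden-section search. When no CI map is fixed the
proportional slope is profiled out by least squares at every objective
evaluation, so only curve *shape* constrains the model parameters.

Not everything is identifiable from a single basal curve. At the
calibrated $k_{u1} = 2$ cm/h the membrane is far from rate-limiting
(its own sensitivity index is $\sim 10^{-3}$), so $k_{u1}$, $k_{u2}$ and
$k_{u3}$ span a near-flat ridge: very different crowding triples produce
visually identical curves. The identifiability guard reports free
parameters whose ±20% perturbation moves the objective by less than
$10^{-4}$ instead of returning them silently. The recovery tests
therefore assert exact recovery of the identifiable pair
($D_u$, $V_{\mathrm{transp}}$) on noiseless curves and of
$V_{\mathrm{transp}}$ under replicate noise, and check that the guard
flags the crowding ridge.

## Synthetic assay exports

`synthesize_experiment()` emulates the instrument's export pipeline: a
forward simulation is converted to CI, sampled at the recording cadence
(0.25 h by default — the instrument cadence is configurable), and each
replicate receives independent additive homoscedastic Gaussian noise;
each experiment is emitted as the mean of its quadruplicate with the
replicate SD, in the `time_h,ci_mean,ci_sd` layout `read_rtca_table()`
parses. This emulates replicate scatter and recording cadence, but not
drift, well-position effects, baseline subtraction artefacts or
heteroscedastic noise at high CI — so passing recovery tests on synthetic
data demonstrate correctness of the machinery, not robustness to every
feature of real instrument data.

## Problem sizes used by the tests

The packaged tests run the production discretisation
($\Delta x = 10^{-2}$ cm, $\Delta x_f = 10^{-6}$ cm,
$\Delta t = 10^{-3}$ h; 20 180 stored nodes) for the sensitivity table
and the conservation/convergence checks, and a reduced membrane
refinement ($\Delta x_f = 10^{-4}$ cm) with $\Delta t$ up to $10^{-2}$ h
for calibration and pipeline tests, where the 12 h migrated count differs
from the production mesh by well under a percent. The method-of-lines
cross-check integrates the identical semi-discretisation with an
adaptive ODE solver on a deliberately coarse mesh
($\Delta x = 0.05$ cm).

## Known limitations

* One spatial dimension; no radial effects, no multiple chemoattractant
  species, no enzymatic serum degradation.
* The CI map is treated as exactly linear; impedance physics beyond that
  is out of scope.
* The Kedem–Katchalsky trace values are constrained, not evolved, so
  global mass is conserved only up to the boundary-row error quantified
  above.
* Fixed time step; no adaptivity and no higher-order advection beyond
  the artificial-viscosity scheme.
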