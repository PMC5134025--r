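---
title: "A haemodynamics-based model of false-lumen thrombosis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A haemodynamics-based model of false-lumen thrombosis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

In type B aortic dissection, blood enters a false lumen (FL) formed
between the layers of the torn aortic wall.  Whether the FL thromboses
or stays patent is one of the strongest predictors of patient outcome.
Thrombosis in the FL is driven by haemodynamics: stagnant, low-shear
recirculating blood with long residence times favours coagulation and
platelet deposition, while well-washed high-shear regions stay clear.

`thromboflow` implements a computationally light, haemodynamics-based
model of this process in two-dimensional idealized geometries: a true
lumen (TL) and a false lumen connected through one or two tears in the
separating flap, plus a backward-facing step used for calibration of
the accelerated kinetics.  Instead of resolving coagulation
biochemistry, the model uses haemodynamic surrogates: a lumped
*coagulant* species released at low-shear walls, *resting* and
*activated platelets* (RP, AP), fluid *residence time* (RT), and a
*bound platelet* field (BP) that marks formed thrombus and feeds back
on the flow.

## Model

### Flow

Blood is incompressible and laminar with shear-thinning Quemada
rheology,

$$\mu(\dot\gamma) = \mu_p\left(1 - \tfrac12 k(\dot\gamma) H\right)^{-2},
\qquad
k = \frac{k_0 + k_\infty\sqrt{\dot\gamma/\dot\gamma_c}}
         {1 + \sqrt{\dot\gamma/\dot\gamma_c}},$$

with plasma viscosity $\mu_p = 1.2$ mPa s, haematocrit $H = 0.45$,
$k_0 = 4.33$, $k_\infty = 2.07$, $\dot\gamma_c = 1.88\,s^{-1}$
(standard literature constants for whole blood at this haematocrit).  Shear rates are floored at $0.05\,s^{-1}$ when evaluating
$\mu$, capping the low-shear viscosity at about 0.13 Pa s — the
measured low-shear plateau of whole blood.  The floor matters twice:
it keeps the constitutive law physical in stagnant zones, and it
bounds the explicit viscous stability limit of the solver (see
*Numerics*).

A growing clot acts on the flow as a porous medium.  The momentum
equation carries a porosity-scaled storage term and a Brinkman sink,

$$\frac{\rho}{\varepsilon}\frac{\partial \mathbf u}{\partial t}
 + \rho(\mathbf u\cdot\nabla)\mathbf u =
 -\nabla p + \nabla\cdot(\mu\nabla\mathbf u) - k_M\,\phi_{BP}\,\mathbf u,$$

with $k_M = 10^7\ \mathrm{kg\,m^{-3}\,s^{-1}}$ and
$\phi_{BP} = \mathrm{BP}^2/(\mathrm{BP}^2 + \mathrm{BP}_t^2)$.  Clot
porosity falls linearly from 1 (no thrombus) to 0.75 (complete clot)
as BP rises to the threshold $\mathrm{BP}_t = 20$ nmol/l.

### Thrombosis feedback loop

Per time step, in order: flow, shear fields, residence time,
platelets, coagulant, bound platelets, porosity/sink refresh.  The
time-averaged quantities that gate growth — the per-face time-averaged
wall shear stress (TAWSS) and the per-cell cycle-averaged shear rate
$\bar{\dot\gamma}$ — are refreshed only at cycle boundaries and always
lag one full cycle.

* **Coagulant (C).**  Released at wall faces as a flux of constant
  magnitude $\bar k_c = 20$ nmol/m/l/s wherever the previous-cycle
  TAWSS is below 0.2 Pa, shut off when the adjacent cell is completely
  thrombosed (BP > 200 nmol/l).  In the bulk, C is produced inside
  forming thrombus at low averaged shear
  ($k_c\,\phi_{BP}\,\phi_{\dot\gamma}^\downarrow$, $k_c = 200$
  nmol/l/s) and consumed at high shear
  ($k_c\,(C/C_t)\,\phi_{\dot\gamma}^\uparrow$), which prevents
  coagulant accumulating in well-washed regions.  Its diffusivity is
  the augmented value $f_{aug} D_c$ with $D_c = 10^{-8}$ m²/s and
  $f_{aug} = 150$; convective transport of C is suppressed by the
  factor $\phi_{\dot\gamma}^\uparrow$ in low-shear (diffusion-limited)
  zones, reflecting the region-simplified transport of the model.
* **Platelets.**  RP and AP advect and diffuse
  ($D_p = 10^{-9}$ m²/s) with inlet values equal to the physiological
  platelet concentration ($2.5\times10^8$ ml⁻¹, carried as the
  relative field RP = 1) and a 5% background activation level
  (AP = 0.05).
* **Bound platelets (BP).**  Immobile.
  $d\mathrm{BP}/dt = k_{BP}\,(\mathrm{AP}/\mathrm{AP_{inlet}})\,
  \phi_C^\uparrow\,\phi_{\dot\gamma}^\downarrow$, applied only on
  *eligible* cells: wall-adjacent cells whose previous-cycle TAWSS is
  below 0.2 Pa, bulk cells with $\bar{\dot\gamma} < 50\,s^{-1}$, or
  neighbours of existing thrombus (letting a clot expand
  contiguously).  At first deposition each cell records the gate value
  that admitted it, which the test-suite audits.
* **Residence time.**  $\partial_t RT + \nabla\cdot(\mathbf u RT) =
  \nabla\cdot(D_{RT}\nabla RT) + 1$ with RT = 0 at the inlet; reported
  in cardiac cycles.

All switching functions are quadratic saturation sigmoids
$\phi^\uparrow(x; x_t) = x^2/(x^2 + x_t^2)$,
$\phi^\downarrow = 1 - \phi^\uparrow$.  The exponent 2 is a package
choice: smooth gating that still switches within a factor of about 3
of the threshold.

### Free constants and how the package fixes them

Several constants are free parameters of the model; the package fixes
them once, as follows, and exposes every one in the configuration:

* **Coagulant switching scale** $C_t = 10$ nmol/l, order-of-magnitude
  consistent with $\mathrm{BP}_t$.
* **Bound-platelet kinetic constant** $k_{BP} = 2$ nmol/l/s (a free constant of the model).  The
  source saturates at $k_{BP}$, and platelet depletion (next item)
  caps the asymptote at $\mathrm{BP}_{complete} = 200$ nmol/l, so at
  full saturation $\mathrm{BP}(t) = 200\,(1 - e^{-t/100\,s})$ and the
  thrombus threshold $\mathrm{BP}_t = 20$ is crossed after about
  10.5 s ≈ 10 cardiac cycles.  This realizes the intended accelerated
  time scale (a low-shear pocket thromboses within tens of cycles)
  and was fixed by this arithmetic, not by simulation tuning.
* **Platelet depletion.**  Forming 1 nmol/l of BP consumes
  $\lambda_{dep} = \mathrm{AP_{inlet}}/\mathrm{BP}_{complete} =
  2.5\times10^{-4}$ relative platelet units, taken from the activated
  pool first, then resting.  The closure is chosen so that complete
  local thrombosis exhausts exactly the local background
  activated-platelet pool — it ties the platelet-count world (ml⁻¹) to
  the BP concentration world (nmol/l) without inventing a molar
  conversion, and preserves the linear proportionality of BP growth to
  AP levels.
* **Blood density** $\rho = 1060$ kg/m³.

### Platelet activation state (PAS)

Shear-induced mechanical activation along particle paths is quantified
by the Grigioni power-law cumulative load model with the in vivo
calibrated constants $a = 1.3198$, $b = 0.6256$, $C = 10^{-5}$:

$$\mathrm{PAS}(t) = C\left[(\mathrm{PAS}_0/C)^{1/a}
 + \int_0^t \tau(s)^{b/a}\,ds\right]^a .$$

For constant $\tau$ and $\mathrm{PAS}_0 = 0$ this factorizes to
$C\,\tau^b\,t^a$ — the package's quadrature is tested against that
closed form, and against exact piecewise-constant load histories.  The
scalar load is taken as $\tau = \mu\dot\gamma$, the viscous
shear-stress magnitude.  Particles are released at the inlet
at four phases of systole (fractions 0, 0.15, 0.30, 0.45 of the cycle, a
package choice) and traced
with RK4 through the periodically extended velocity record of the
final cycle.  PAS is used diagnostically only; it is not coupled back
into the Eulerian model, where it justifies the 5% background
activation.

## Geometries and study cases

All cases are uniform Cartesian staggered (MAC) grids with solid cells
embedded by masking.

* **Single-tear dissection analog** (`dissection_s1_case()`): a TL
  channel (10 mm) and a closed-end FL channel (4 mm) separated by a
  2 mm flap pierced by one 6 mm proximal tear; domain length 80 mm,
  cells 0.5 mm.  The inlet waveform is an analytic pulse with period
  1.054 s, peak systolic flow 3× the mean, a 20% retrograde lobe, and
  mean flow chosen (0.15 m/s TL mean velocity) so that TL walls sit
  well above the 0.2 Pa TAWSS threshold while the FL interior stays
  below it — the regime the model is built for.  The FL height is
  deliberately shallow so that when a second tear creates a
  through-flow, the between-tear wall shear stays below threshold
  (wall shear of pressure-driven flow scales as
  $\Delta p\,h/2L$).
* **Two-tear analog** (`dissection_s4_case()`): adds a middle tear at
  36 mm and the restart protocol: the proximal FL cap is marked as
  existing thrombus, wall cells are seeded with 1% of the maximum wall
  coagulant recorded in the single-tear run, and the coagulant
  production/consumption runs for two cycles before bound-platelet
  growth is enabled — allowing wall concentrations to relax to zero in
  non-thrombotic regions.
* **Backward-facing step** (`bfs_thrombosis_case()`): steady inflow,
  2.5 mm step, expansion ratio 2, hydraulic-diameter Reynolds number
  ≈ 265.  These dimensions are package assumptions, chosen so
  that the laminar reattachment point lies a few step heights
  downstream and the wall shear falls below 0.2 Pa only inside the
  recirculation bubble.  The default run length of 40 s with
  $f_{aug} = 150$ reproduces the time-scale calibration: simulated
  time × augmentation factor ≈ equivalent real time
  (`time_scale_estimate(40, 150)` = 6000 s ≈ the 90 min bench
  experiment), a steady-flow calibration that should not be
  extrapolated to pulsatile flow.

The run protocol everywhere is: two spin-up cycles with the thrombosis
model off (establishing a periodic flow, the first TAWSS field and the
first cycle-averaged shear), then the full feedback loop; 20 cycles is
the standard study length.

## Numerics

* **Flow solver**: fractional-step (Chorin) projection on the MAC
  grid.  Convection is explicit 2nd-order upwind (1st-order fallback
  at boundaries); viscous diffusion is explicit; the Brinkman sink is
  pointwise implicit (it is stiff: $k_M/\rho \approx 10^4\,s^{-1}$),
  which removes its stability limit.  The pressure Poisson equation
  (variable coefficient $\varepsilon/\rho$, Dirichlet $p = 0$ at the
  outlet face, Neumann elsewhere) is solved by conjugate gradients
  preconditioned with a cached banded Cholesky factorization of the
  dt-independent operator; the factorization is rebuilt when the
  porosity field drifts by more than $3\times10^{-3}$.  The default
  relative tolerance is $10^{-10}$, giving post-projection divergence
  at round-off level.
* **Scalars**: conservative finite-volume MUSCL advection (van Leer
  limiter) with explicit diffusion; inlet Dirichlet, outflow
  upwinded, zero-flux walls; wall coagulant flux enters wall-adjacent
  cells as flux × face length / cell area.  Negative concentrations
  are clipped to zero and the events counted.
* **Time step**: `cfl_dt()` = safety × min(convective, viscous,
  scalar-diffusive) limits; the explicit-sink limit is available but
  excluded by the coupler because the sink is integrated implicitly.
  The viscous limit is governed by the low-shear viscosity plateau;
  this is why the plateau floor doubles as a stability parameter.
* **Degenerate inputs**: closed boxes (no inlet/outlet) use the pure
  Neumann pressure problem with a mean-zero projection and a tiny
  diagonal shift in the preconditioner; zero-flow states are exact
  fixed points.
* **Determinism**: there is no randomness anywhere in the solver;
  reruns from one configuration are bit-identical, which the tests
  assert.

## What the verification shows — and what it does not

The analytic benchmarks (`validate_solver()`) pin the solver against
closed forms: plane Poiseuille flow (centerline and wall shear to
<0.5%/1% at 64 cells across the channel), oscillatory Womersley flow
at $\alpha = 5$ (<2% L2), residence-time accumulation in a stagnant
box (<0.1%), discrete mass conservation ($10^{-8}$), and the PAS
closed form ($10^{-3}$).  The growth tests are *qualitative analogs*:
thrombus confined to the FL with a patent TL in the single-tear case,
deposition starting between the tears and reduced FL residence time
with a second tear, and step-flow thrombus confined to the
recirculation bubble.

The test tier runs the dissection analogs at 0.8 mm cells for 10 full
cycles and the step case at 0.5 mm for 12 s — sizes chosen so the
whole suite runs on a laptop-class single core in minutes; the shipped
default configurations use 0.5 mm and 20 cycles.

One artifact of the 2D channel idealization is worth naming: a
channel centerline always has near-zero shear rate, so the bulk
eligibility gate (cycle-averaged shear below 50 s⁻¹) is open along the
true-lumen core, and trace amounts of bound platelets accumulate there
wherever a little coagulant leaks in.  Over the 10-cycle study tier
these traces stay below the thrombus threshold, and "thrombus"
(BP > BP_t) remains confined to the false lumen; a 3D vessel with
secondary flows would not hold a coherent zero-shear core.

Because the geometries are 2D idealizations, passing these tests shows
that the coupled model mechanics behave as designed — threshold
gating, feedback, confinement, time scales — not that the package
reproduces any patient's thrombus shape.  Real dissections add 3D
helical flow, branch vessels, flap motion and wall compliance, all
outside this model.  Two further limitations are inherent to this modelling approach: the high-shear (von Willebrand factor) thrombotic pathway is
not represented, and the mapping from accelerated simulation time to
physiological time is calibrated only under steady flow.
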