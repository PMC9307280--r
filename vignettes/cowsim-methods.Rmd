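---
title: "Modelling cerebral hyperperfusion risk: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling cerebral hyperperfusion risk: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models implemented in `cowsim`, the
assumptions behind them, the numerical choices, and the places where the
design was genuinely open and a decision had to be made. It states no
empirical results; all quantitative claims about the implementation are
made (and re-made at every run) by the test suite and by
`scripts/acceptance.R`.

## 1. The closed-loop 1D–0D model

### 1D arteries

Each large artery is a straight, axisymmetric, deformable tube carrying
the cross-sectional area $A(t,x)$ and volumetric flow $Q(t,x)$:

$$\partial_t A + \partial_x Q = 0, \qquad
\partial_t Q + \partial_x\!\left(\frac{Q^2}{A}\right)
 + \frac{A}{\rho}\,\partial_x P = -K_R \frac{Q}{A},$$

with blood density $\rho = 1060\ \mathrm{kg\,m^{-3}}$, viscosity
$\mu = 0.0047\ \mathrm{Pa\,s}$ and the friction parameter
$K_R = 22\pi\mu/\rho$ (a Poiseuille-type profile assumption). The system
closes with a tube law derived from Laplace's law,

$$P = P_0 + \frac{\sqrt{\pi}\,Eh}{(1-\sigma^2)\,A_0}
      \left(\sqrt{A} - \sqrt{A_0}\right),$$

with reference pressure $P_0 = 85$ mmHg, Poisson ratio $\sigma = 0.5$,
and the stiffness product $Eh$ assigned from the lumen radius through an
exponential-plus-constant empirical law
$Eh/r = k_1 e^{k_2 r} + k_3$ whose constants live in the network config
and can be overridden per segment. This law, and the piecewise-linear
age adjustment of aortic diameter and stiffness, are
*literature-informed defaults*: the sources that fix them are cited
compilations of arterial trees, not quantities this package derives.
The defaults were chosen once so that the default tree operates at a
physiological point (MAP near 90–95 mmHg, cardiac output near
4–5 L/min) and are not otherwise tuned.

### Stenosis model

A focal ICA stenosis is represented by an internal interface at the
middle of the host segment imposing the empirical pressure loss

$$\Delta P = R_v Q
 + K_t \frac{8\rho}{\pi^2 D_n^4}\left[\left(\tfrac{1}{1-SR}\right)^2 - 1\right]^2 Q|Q|
 + K_u \frac{4\rho L_s}{\pi D_n^2}\,\dot Q,$$

whose three terms account for viscous friction, flow separation, and
pulsatility. $R_v$ is the Poiseuille integral
$\int_0^{L_s} 128\mu/(\pi D(x)^4)\,dx$ of the narrowed lumen;
$SR = 1 - D_s/D_n$; $K_u = 1.2$ is held fixed, while $K_t$ (nominally
1.52) is treated as uncertain in $[1.0, 2.699]$. Because the stenosis
length $L_s$ is not an input of the surrogate interface (its effect is
carried by $R_v$, and the pulsatility term is comparatively negligible),
a stenosis specified only by $(R_v, D_n, SR)$ uses a nominal
$L_s = 20$ mm in the pulsatility term. An intact vessel
($R_v = SR = K_t = 0$, $D_n$ = host diameter) installs no interface at
all, so its pressure loss is identically zero.

### 0D circulation and heart

Peripheral arteries beyond each 1D terminal are a three-element
Windkessel (proximal resistance, compliance, distal resistance; the
*peripheral resistance* PR of an outlet is the sum of the two
resistances). Capillaries, venules and veins aggregate into upper- and
lower-body RLC compartments in series; their outputs meet a passive
atrium feeding a single time-varying-elastance ventricle
($P_{lv} = E(t)(V - V_0)$, piecewise-cosine activation, period fixed at
1 s) through diode valves, whose output is the inlet boundary condition
of the ascending aorta — a closed loop that conserves blood volume by
construction. The published description of this model family leaves the
chamber count and valve treatment open; the single-ventricle closed
loop with a passive atrium is this package's choice, adequate because
every quantity of interest is distal to the aortic valve.

### Numerics

* Interior 1D nodes: two-step (Richtmyer) Lax–Wendroff on the
  conservative form; the momentum flux of the square-root tube law is
  $\beta A^{3/2}/(3\rho A_0)$ per segment.
* Boundaries (junctions, stenosis interfaces, outlets, inlet): the
  outgoing Riemann invariants $W_\pm = u \pm 4c$,
  $c = \sqrt{\beta\sqrt{A}/(2\rho A_0)}$, are evaluated at the foot of
  the characteristic (linear interpolation, with the friction source
  $-K_R u/A$ integrated along the characteristic — omitting this source
  visibly biases cycle-averaged conservation) and frozen; the remaining
  unknowns (one area per connected end) solve conservation of mass plus
  equality of *total* pressure $P + \tfrac12\rho u^2$ (the stenosis
  interface subtracts $\Delta P$) by damped Newton–Raphson with an
  analytic Jacobian, tolerance $10^{-10}$ (solver units), at most 50
  iterations.
* 0D states advance by classical RK4 with the 1D boundary flows frozen
  over the step.
* Time step: adaptive, $\Delta t = \mathrm{CFL}\cdot
  \min_j \Delta x_j/(|u_j|+c_j)$ with CFL 0.9, clipped to land exactly
  on cycle boundaries. A user-forced $\Delta t$ above the stable limit
  raises an instability error rather than integrating on.
* Grid: odd node counts per segment (so an exact mid-node exists; all
  outputs are evaluated at mid-segment nodes), nominal spacing 2.5 mm
  (5 mm for the reduced network), minimum 3 nodes, minimum 5 on
  stenosis hosts.
* Periodicity: cycles repeat until the maximum relative change of any
  cycle-averaged output between consecutive cycles falls below
  $10^{-3}$ (defaults; at most 30 cycles), and outputs are the averages
  over the final cycle. The stopping rule is this package's decision —
  the underlying publications do not state one — and the grid-convergence
  and conservation properties in the test suite are its guard.
* Cold start: all areas at $A_0$, zero flow, 0D states at reference
  pressures. Initial venous/compartment pressures set the total blood
  volume of the closed loop and hence the operating point.

## 2. The 60-in / 45-out interface

The surrogate interface is a fixed, named slot order: 22
carotid/cerebral diameters and 22 lengths (in a fixed artery order),
the 6 CoW outlet PRs, the total-PR scaling factor, age, the left and
right stenosis triplets $(R_v, D_n, SR)$ and the two $K_t$ values.
Outputs are the 22 cycle-averaged mid-segment flows (mL/min), the 22
pressures (mmHg) and MAP — the cycle-averaged pressure at the middle of
the left subclavian artery. Sampling ranges follow the published
physiological table; possibly-absent collaterals (ACoA, PCoAs, ACA I,
PCA I) have a 0.1 mm lower diameter bound so that a missing artery is an
extremely narrow one, keeping the network topology fixed. The upper
bound of $R_v$ grows with $SR$ as
$128\mu L_{s,\max}/(\pi D_{n,\min}^4 (1-SR)^4)$
($L_{s,\max} = 40$ mm, $D_{n,\min} = 2.9$ mm) and is capped at
500 mmHg s mL⁻¹. Open PR intervals are implemented as
$[1, \text{upper}]$ mmHg s mL⁻¹ and $SR \in [0, 0.99]$. Draws are
independent across slots; on an intact side
$R_v = SR = K_t = 0$ and $D_n$ equals that side's sampled ICA diameter.
Because the intact-side $D_n$ slot carries a host diameter, its declared
interval is the union of the stenosis range and the host diameter
range.

Samples whose simulated outputs contain a negative pressure, a negative
cycle-averaged flow in an outlet-bearing artery, non-finite values, or a
non-periodic run are rejected and redrawn; a sustained rejection rate
above 90 % aborts with a configuration error. Datasets split 6:2:2 into
train/validation/test by scenario-stratified seeded shuffling, remainder
to train.

## 3. The surrogate

A fully connected network: input layer, $N_{layer}$ hidden layers of
$N_{node}$ nodes (linear map, then batch normalization, then ReLU), and
a linear output layer. Inputs are scaled so the *declared* bounds (not
the data extremes) map to $[-1, 1]$; outputs are standardized by
training-set mean and SD, and validation/test data always reuse the
training statistics. Training minimizes the mean squared error
$L = \frac{1}{N_{sample} N_{out}}\sum_s \lVert y^{(s)} - \hat
y^{(s)}\rVert^2$ with Adam (framework-typical constants
$\beta_1 = 0.9$, $\beta_2 = 0.999$, $\epsilon = 10^{-8}$), seeded
He-normal initialization and seeded shuffling. The pooled validation
$R^2 = 1 - \sum\lVert y - \hat y\rVert^2 / \sum\lVert y - \bar
y\rVert^2$ is computed every epoch; every `window` (default 100) epochs
the trailing-window mean is compared against the best window so far and
training stops after three non-improving evaluations, restoring the
weights of the single best epoch. Whether the early-stopping $R^2$ is
pooled or per-output averaged was an open point; pooled is implemented.
The reported weight-and-bias count
$\sum_{l} (N^l N^{l-1} + N^l)$ excludes the batch-norm scale/shift
parameters (which the checkpoint still stores), so the reference
7×200 architecture on 60 inputs / 45 outputs counts 262 445.

The desk-scale proxy of the full build runs on the 5-segment reduced
network: 2 000 solver samples (two scenarios), 6:2:2 split, and a
*single* hidden layer of 48 nodes (batch 256, lr $10^{-2.5}$, up to
2 000 epochs). At this training-set size small capacity generalizes
best — the same inverted-U of accuracy versus parameter count that
motivates the grid search at full scale, approached from the
under-parameterized side.

## 4. Calibration

Patient measurements enter as per-outlet flows (rescaled to the
measured total CoW inflow at fixed distribution ratios), plus MAP.
The 6 CoW outlet PRs update multiplicatively,
$PR_i \leftarrow PR_i (\bar Q_i^{pred}/\bar Q_i^{target})^{0.8}$
(justified by the near-inverse-proportional PR→flow response), the
scaling factor updates by a secant step on MAP (multiplicative damped
fallback on the first iteration), and the loop stops when all outlet
flows match within 0.5 % and MAP within 1 mmHg (defaults; at most 200
iterations — the reference description cites its adjustment procedure
without formulas or tolerances, so these are package decisions exposed
as arguments). PRs clamp to their declared bounds; targets requiring
out-of-bound PRs therefore end non-converged with residuals reported,
which is exactly the signal the UQ loop uses to reject a realization.

## 5. Monte Carlo UQ

Per realization: draw uncertain quantities (diameters uniform in
measured ±2 px intersected with slot bounds; one shared ±2 px offset
applied to the whole stenosis profile, from which $R_v$, $D_n$, $SR$
are recomputed — lumen and reference move together; $K_t$ uniform;
per-outlet flows ±16 %, total inflow ±16 % PC-MRI / ±35 % ultrasound;
a flagged possibly-absent ACoA uses [0.1, 2.6] mm outright), rebuild
the flow targets from the drawn flows, calibrate (reject on
non-convergence), record the preoperative prediction, stent virtually
($R_v = 0$, $SR = 0$, $K_t = 0$, $D_n$ = sampled ICA diameter) *keeping
the adjusted PRs*, predict again, and accumulate
$\Delta\bar Q_i$. The sample count grows in increments (default 10 000)
until the mean and variance of every outlet's $\Delta\bar Q$ change by
less than 0.1 % — the degenerate zero-uncertainty case passes this at
the first check with zero variance. Reported statistics: mean,
variance, min–max, mode (centre of the densest Freedman–Diaconis
histogram bin), and $P(\Delta\bar Q > 100\,\%)$, the cerebral
hyperperfusion probability. MAP measurement error is not varied, and
all draws are independent — no correlation structure is asserted
between uncertain quantities.

## 6. Sobol sensitivity analysis

Saltelli's radial design: two independent $N \times D$ uniform
matrices $A, B$ plus the $D$ matrices $A_B^{(i)}$, i.e. $N(D+2)$
evaluations (second-order indices are not computed). Jansen-type
estimators give the first-order and total indices; 95 % percentile
bootstrap intervals resample evaluation rows jointly (size 1000 by
default). The model function for patient-level SA is the full
calibrate→stent→predict chain with the postoperative flow increase at
the focal outlet as output; design rows whose calibration fails are
imputed from the nearest accepted row in design order and counted. The
estimators are validated against closed-form decompositions (additive
models and the Ishigami function) in the test suite.

## 7. What the reduced network does and does not show

The 5-segment network preserves every structural element of the full
chain — a bifurcating elastic tree, one stenosis host with the full
pressure-loss model, Windkessel outlets whose PRs are calibration
targets, a closed 0D loop, the same input/output manifest machinery —
so it exercises the identical code paths at a fraction of the cost
(problem sizes used throughout: 2 000 samples for the surrogate proxy,
$N = 2^{14}$ for Sobol benchmarks, a few thousand Monte Carlo
realizations against analytic predictors). What it cannot show is the
anatomy-specific physics of the circle of Willis — ring collaterals,
left/right compensation, the ACoA diameter threshold — or the accuracy
of a surrogate trained on production-scale (10⁵-sample) data; those
claims would need the full tree, large datasets, and clinical
measurements, and are deliberately out of scope of the automated
checks. Patient records handled here are synthetic by construction.

## 8. Known limitations

* The default 83-segment geometry and all 0D/heart constants are
  literature-informed defaults, not a reproduction of any specific
  published parameter table.
* Vessel walls are purely elastic (no viscoelasticity), segments are
  uniform (no taper), and cerebral autoregulation is not simulated —
  consistent with predicting the circulation *immediately* after
  surgery, before regulation and remodelling respond.
* The characteristic-based boundary closure is first-order accurate;
  its conservation defect is monitored by tests rather than eliminated
  by construction.
* Uniform uncertainty distributions are an explicit modelling choice;
  distribution shape mainly affects the interior of the
  $\Delta\bar Q$ distribution, less so the exceedance probability the
  package reports.
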