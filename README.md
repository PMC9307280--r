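# cowsim

Closed-loop cerebral hemodynamics, surrogate modelling and uncertainty
quantification in R.

## The problem

Patients with internal carotid artery (ICA) stenosis face a risk of
*cerebral hyperperfusion* (CH) after surgical dilation of the stenosis:
if the collateral pathways of the circle of Willis (CoW) are weak, the
middle cerebral artery downstream of the stenosis can see its
cycle-averaged flow more than double (ΔQ̄ > 100 %) immediately after
surgery. Whether that happens depends on quantities that are only
uncertainly known from routine imaging — small collateral diameters near
the CT resolution limit, stenosis geometry, and flow measurements whose
error is 16–35 % depending on modality. Assessing CH risk therefore
requires propagating those uncertainties through a whole-body
hemodynamic model, which is far too slow to do directly with a PDE
solver.

`cowsim` implements the full chain needed for that assessment:

1. **1D–0D closed-loop solver** — large arteries as 1D deformable tubes
   (mass + momentum, tube law `P = P0 + √π·Eh/((1−σ²)A0)·(√A − √A0)`),
   solved with a two-step Lax–Wendroff scheme; junctions couple segments
   by conservation of mass and total pressure via Newton–Raphson;
   three-element Windkessel (RCR) outlets, RLC body compartments and a
   time-varying-elastance heart close the loop; an empirical stenosis
   model adds the pressure loss
   `ΔP = Rv·Q + Kt·(8ρ/π²Dn⁴)·((1−SR)⁻²−1)²·Q|Q| + Ku·(4ρLs/πDn²)·Q̇`.
   The default tree has 83 segments, 22 of them carotid/cerebral, with
   the CoW's 3 inlets and 6 outlets.
2. **Experiment design** — uniform sampling of a 60-component input
   vector (22 diameters, 22 lengths, 6 CoW outlet peripheral
   resistances, a total-PR scaling factor, age, and left/right stenosis
   parameters {Rv, Dn, SR, Kt}) over published physiological ranges,
   under four stenosis scenarios, with rejection of unphysical results
   (negative pressures, reversed terminal flows).
3. **Neural-network surrogate** — a fully connected network
   (linear → batch norm → ReLU per hidden layer, linear output) trained
   with Adam on simulator data to map the 60 inputs to 45 cycle-averaged
   outputs (22 flows, 22 pressures, MAP), with the windowed
   early-stopping rule and grid search over
   `N_layer × N_node × N_batch × lr`.
4. **Calibration** — iterative adjustment of the 6 CoW outlet PRs to
   match measured (SPECT-derived, inflow-corrected) outlet flows
   `Q̄ᵢ^target = Q̄_total·Q̄ᵢ^SPECT/ΣQ̄ⱼ^SPECT`, and of the total-PR
   scaling factor to match measured arm pressure.
5. **Monte Carlo UQ** — per patient record: draw uncertain inputs
   (diameters ±2 px, stenosis geometry ±2 px, Kt ∈ [1.0, 2.699], flows
   ±16 %/±35 % by modality), calibrate, virtually stent
   (`Rv = 0, SR = 0, Kt = 0, Dn = D_ICA`), predict, and accumulate
   `ΔQ̄ᵢ = (Q̄ᵢ^post − Q̄ᵢ^pre)/Q̄ᵢ^pre × 100 %` until its mean and
   variance stabilize; report mean, mode, range and P(ΔQ̄ > 100 %).
6. **Sobol sensitivity analysis** — Saltelli sampling (N·(D+2) model
   evaluations), first-order (`Sₙ = V[E[y|xₙ]]/V[y]`) and total
   (`S_T,ₙ = 1 − V[E[y|x₋ₙ]]/V[y]`) indices with percentile-bootstrap
   confidence intervals.

## A worked example

```r
library(cowsim)

net <- build_default_network(age = 65)   # 83-segment tree
x <- network_input_vector(net)
x[["sten_L.Rv"]] <- 11.3                  # severe left ICA stenosis
x[["sten_L.SR"]] <- 0.83
x[["sten_L.Dn"]] <- 4.8
x[["kt_L"]]      <- 1.52

r <- simulate_output_vector(x, net, solver_settings(target_dx_mm = 5),
                            full = TRUE)
r
#> <cycle_averages> cycles: 6 (periodic)
#>   cardiac output: 4356.5 mL/min; MAP: 91.8 mmHg
round(r$outputs[c("qbar.L_int_carotid_I", "qbar.R_int_carotid_I",
                  "qbar.Ant_comm_", "map")], 1)
#> qbar.L_int_carotid_I qbar.R_int_carotid_I       qbar.Ant_comm_
#>                 30.9                267.7                 89.2
#>                  map
#>                 91.8
```

The severely stenosed left ICA carries a fraction of the intact right
ICA's flow, and the anterior communicating artery carries a large
compensating collateral flow (positive in the right-to-left direction)
— the CoW redistributing the contralateral inflow toward the starved
side; the mean arterial pressure is the cycle-averaged pressure at the
middle of the left subclavian artery. All flows are cycle-averaged
mL/min at mid-segment nodes, pressures are mmHg.

On top of this, `generate_dataset()` + `train_surrogate()` build a
surrogate, `calibrate()` matches a patient's measured flows, and
`run_uq()` / `run_sa()` produce the CH-risk statistics and Sobol
indices. A thin command-line front end with subcommands
`simulate | generate | train | calibrate | uq | sa` is in
`inst/cli/cowsim.R`.

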