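---
title: "The stenosis susceptibility index: model, assumptions and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The stenosis susceptibility index: model, assumptions and numerical choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ssindex)
```

## The index and the virtual stenosis method

Plaque deposition in coronary arteries concentrates where wall shear
stress (WSS) remains low; shear beyond a critical level triggers
endothelium-mediated vasodilation that protects the site. The stenosis
susceptibility index (SSI) quantifies how quickly a site's shear
environment responds as stenosis develops there. At a candidate site we
insert virtual lesions of 0, 25 and 50% diameter stenosis, solve the
hemodynamics at each severity, and record the fractional flow reserve
(FFR) just distal to the site and the maximum wall shear stress (WSSmax)
at the lesion throat. Across the severity grid WSSmax is very nearly
linear in FFR, and the magnitude of the ordinary-least-squares slope of
WSSmax on FFR is the site's SSI (`ssi_from_sweep()`). A one-point
shortcut, `ssi_simplified()`, uses WSSmax/(1 − FFR) of a single stenosed
state after normalizing the healthy state to WSSmax = 0 and FFR = 1; on a
two-point sweep with exactly that baseline the two definitions coincide.

Within one patient, the site with the *minimum* SSI needs the most
severe stenosis before shear reaches the protective level, so it is
ranked the most plaque-susceptible location (`rank_sites()`); agreement
of that prediction with where PCI was later performed is scored by
`concordance_report()`.

## Outlet boundary model

Each terminal vessel drains through a lumped microvascular resistance to
a venous reference pressure. Resistances are calibrated from vessel
lengths on the physiological ground that longer epicardial vessels feed
more muscle mass and therefore see lower downstream resistance. With
`l` the per-artery summed length of segments whose proximal diameter
exceeds a qualification threshold, the left coronary arteries get
`R_LAD = k/l_LAD` and `R_LCX = k/l_LCX`. The RCA feeds two territories
with unequal demand per unit length, so its qualifying length is split
into an RV-feeding and an LV-feeding part and its resistance is the
series sum `R_RCA = α·k/l_RV + k/l_LV`, with `α > 1` discounting the
RV-feeding length. The constant `k` follows from requiring that the three
arteries in parallel under the aorta-to-vein pressure difference ΔP carry
exactly the total hyperemic flow Q:

    k = (ΔP/Q) · [ l_LAD + l_LCX + l_RV·l_LV / (l_RV + α·l_LV) ]

This closure is exact by construction and is verified to ~1e-16 relative
error over randomized draws in the test suite. We note one modeling
commitment made here: the RCA term is implemented as the series RV/LV
combination above because that is the unique reading under which the `k`
expression closes the total flow balance exactly; treating the two terms
as anything else breaks closure.

Within an artery, the allocated resistance is distributed to terminal
outlets by recursively splitting conductance at every bifurcation in
proportion to downstream subtree length (`distribute_to_outlets()`) —
the same length principle again, chosen over Murray-law splitting to keep
a single consistent rule; the parallel combination of outlet resistances
reproduces the artery resistance to ~1e-12. An artery with no qualifying
length receives an infinite-resistance sentinel rather than being
dropped, so network assembly is uniform.

Collateral circulation is an optional on–off switch: when an outlet's
distal pressure falls below a threshold, a collateral resistance opens in
parallel (`collateral_adjust()`). Defaults (off; threshold 30 mmHg;
collateral resistance 10× the outlet's) are conventions, re-evaluated at
every solver iteration when enabled.

### Parameters

| parameter | default | units | role |
|---|---|---|---|
| `delta_P` | 90 | mmHg | aorta-to-vein driving pressure |
| `Q_total` | 14 | mL/s | total hyperemic coronary flow |
| `alpha` | 3.45 | — | RV-length discount (typical LV/RV muscle volume ratio) |
| `mu` | 0.0035 | Pa·s | blood viscosity |
| `rho` | 1060 | kg/m³ | blood density |
| `venous_pressure` | 0 | mmHg | outlet reference |
| `diameter_threshold` | 1.5 | mm | strict `>` qualification on proximal diameter |

ΔP, Q, μ and ρ are literature-typical hyperemic values and are exposed in
the JSON config; the diameter threshold is likewise configuration — the
length-based calibration needs *some* cut below which vessels stop
counting toward perfused length, and 1.5 mm is a conventional lower bound
for segmentable coronary branches. FFR is defined under hyperemia, which
is why `Q_total` is the hyperemic flow.

## Reduced-order solver

The hemodynamics are solved on a 0D resistive network rather than a 3D
finite-element model: each segment contributes a Poiseuille resistance
`128 μ L / (π d⁴)` at its mean diameter, and a lesion replaces the
Poiseuille contribution of its own length with a Young-type loss

    ΔP = K_v (μ/d_ref) V + K_t (ρ/2) (A_ref/A_min − 1)² V|V|,
    K_v = 32 (L/d_ref)(A_ref/A_min)²,  K_t = 1.52,

where V is the mean velocity at the reference area. The viscous term
reduces algebraically to `(d_ref/d_min)⁴` times the lesion-length
Poiseuille resistance, so a 0% lesion is *exactly* null — the test suite
holds this to 1e-12 relative. The quadratic term makes the system
nonlinear; the junction mass-balance equations in the distal nodal
pressures are solved by damped Newton iteration with an analytic
Jacobian (per-segment flow inverted from the pressure drop in closed
form). Consequences of the reduced-order choice: absolute SSI magnitudes
are not comparable to 3D CFD values for real anatomies, and all
acceptance checking is property- and fixture-based (monotone severity
response, flow closure, solver-oracle agreement, and the printed pilot
table for ranking/reporting logic).

WSSmax is the Poiseuille wall shear at the minimal lumen,
`32 μ |q| / (π d_min³)`, reported in Pa and dyn/cm² (SSI defaults to
dyn/cm² per FFR unit). FFR is `(P_distal − P_v)/(P_inlet − P_v)` at the
lesion segment's distal node. Pulsatile runs are quasi-static — one
steady solve per waveform sample — because the network is purely
resistive (no compliance or inertance, matching the resistive outlet
model); FFR then uses cycle-averaged pressures and WSSmax is the
spatiotemporal maximum over cycle samples (the time-averaged variant can
be formed from the per-sample states).

### Numerical choices

- Convergence: maximum junction flow residual below `1e-10` relative to
  max(1, total outlet flow); at most 100 Newton iterations; step damping
  halved while the residual increases. Non-convergence is an error that
  reports the last residual, never a silently degraded state.
- Initialization at the inlet pressure everywhere; for a lesion-free
  (linear) network the first Newton step is the exact solution.
- Units: mmHg / mL / s / mm at every interface, SI inside the physics;
  1 mmHg = 133.322 Pa.
- Severity is percent *diameter* reduction of a symmetric axisymmetric
  lesion; default lesion length 10 mm (clipped to the segment length).
  These are conventions of this implementation.
- Outlet boundary conditions are calibrated once from the lesion-free
  tree and held fixed across a severity sweep: vessel lengths do not
  change when a virtual lesion is inserted, and freezing the boundaries
  isolates the lesion's own hemodynamic effect.
- Ranking tie-breaks: equal SSI resolves by artery order RCA, LAD, LCX,
  then proximal-most position, with an explicit tie flag.
- Degenerate inputs fail loudly: all-zero summed lengths, all-infinite
  outlets, constant-FFR sweeps (zero variance), and concordance tables
  with no treated vessels (rate reported as undefined, not 0).

## Candidate sites

How many sites to evaluate per patient is a user decision;
`default_sites()` provides a deterministic convention: on each artery's
main trunk (the root-to-deepest path by cumulative length), sites at 25,
50 and 75% of trunk length — proximal, mid and distal representatives of
the vessel regions a reader would naturally compare. Arbitrary
`candidate_site()` lists are accepted everywhere.

## What the synthetic generator does and does not emulate

`generate_tree()` produces seed-reproducible three-artery trees: a
tapering trunk of 1–6 chained segments per artery (total trunk length
40–120 mm, root diameter 2.5–4.5 mm, root-to-tip taper ratio 0.6–0.9)
with one side branch per interior junction (20–60 mm, 75% of the local
trunk diameter). RCA territories follow the trunk: segments are
RV-feeding while their cumulative trunk midpoint lies within
`rca_rv_fraction` (default 0.55) of the trunk length and LV-feeding
after — mirroring the anatomy of proximal acute-marginal RV branches and
a distal PDA/PLV supplying the LV — and side branches inherit the
territory of their junction. This rule guarantees both territories
contain trunk-calibre (qualifying) vessels whenever the trunk has more
than one segment, so the RCA always perfuses; with a single-segment RCA
trunk the LV territory is empty and the RCA is sentinel-blocked, a
documented degenerate configuration.

The generator emulates what the method consumes — per-artery length
budgets, tapering calibres, branching topology, territory split — and
nothing else: no bifurcation angles, no curvature or eccentric lumens, no
anatomical variants (left dominance, ramus intermedius), no inter-artery
anastomoses, and lengths/diameters are rounded to 1 µm so the JSON round
trip is exact. Passing tests on these trees therefore demonstrate the
*method's* correctness and qualitative behavior (flow closure, monotone
severity response, near-linear sweeps), not anatomical realism or
clinical accuracy on real CT-derived geometries.

Problem sizes used by the shipped tests and the acceptance script: 100
generated trees × 9 sites × 3 severities for the monotonicity property,
20 lesioned trees for solver-oracle agreement, 1000 draws for flow
closure, 20 trees end-to-end for sweep linearity (every fitted r² ≥ 0.90
there; the worked example's fits sit near 0.98–0.996).

## The encoded pilot table

The seven-patient observation fixture (`table1_fixture()`, also shipped
as `extdata/table1_observations.csv`) encodes per-artery minimum SSI
values, MI flags, and PCI match marks: treated-and-matched,
treated-and-mismatched, not treated, or not evaluated (one vessel carries
no value at all and is excluded rather than zeroed). Its SSI values
originate from 3D simulations in the source pilot study and are used here
as unitless labels for ranking and reporting logic only. The per-patient
match rule counts a patient as matched only when *every* treated vessel
matches; on this table an any-vessel rule yields the same 5/7, so the
choice is an interpretation, and we fixed the stricter one. A patient
with no treated vessels counts as unmatched rather than vacuously
matched. Display rounding is one decimal (71.4, 77.8); internal rates are
unrounded.

## Known limitations

- The 0D solver has no secondary flow, no recirculation, and no spatial
  WSS field — the low-WSS *mechanism* behind the index is summarized by a
  single throat value, and SSI magnitudes are not transferable to 3D CFD
  studies.
- One lesion per sweep; serial stenosis interaction is out of scope, as
  are eccentric plaques and fluid–structure interaction.
- Newtonian rheology; the quasi-static pulsatile mode omits compliance
  and inertance, so waveform-shape effects beyond the pressure mean are
  not represented.
- No MI risk cut-off is estimated: the index ranks sites; thresholding it
  against infarction risk would need clinical calibration data this
  package does not contain.
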