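---
title: "Methods: 1D coronary hemodynamics, in-silico FFR, and input-uncertainty analysis"
author: "coroflow"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: 1D coronary hemodynamics, in-silico FFR, and input-uncertainty analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The model

`coroflow` computes fractional flow reserve (FFR) — the ratio of
time-averaged pressure distal to a coronary stenosis to the time-averaged
ostial pressure under maximal (hyperemic) flow — by simulating pulsatile
blood flow through a branching coronary tree with a one-dimensional
distributed model.

## Governing equations

Each vessel segment carries cross-sectional area $A(x,t)$, flow
$Q(x,t)$ and pressure $P(x,t)$, governed by the 1D mass and momentum
balances

$$\partial_t A + \partial_x Q = 0, \qquad
\partial_t Q + \partial_x\!\left(\alpha \frac{Q^2}{A}\right)
  + \frac{A}{\rho}\,\partial_x P = -C_f \frac{Q}{A},$$

closed by the algebraic tube law

$$P = P_\mathrm{ext} + \beta(A_0)\left(\sqrt{A} - \sqrt{A_0}\right),
\qquad \beta = \frac{\sqrt{\pi}\,h\,E}{(1-\nu^2)\,A_0}.$$

Blood is incompressible and Newtonian with density
$\rho = 1060\ \mathrm{kg/m^3}$; its dynamic viscosity is derived from the
patient's hematocrit fraction $\phi$ through the empirical relation
$\mu = \mu_0/(1-\phi)$ with plasma viscosity $\mu_0 = 1.2$ cP, so the
cohort-average hematocrit of 39.2% gives 1.97 cP. The friction
coefficient is taken in the kinematic form $C_f = 22\pi\mu/\rho$
(m²/s) — the form the dimensional analysis of the momentum equation
requires — and $\alpha = 1.1$ is the momentum-flux correction consistent
with the blunt polynomial velocity profile that produces $22\pi\nu$
friction. Both are configuration-exposed; FFR is a pressure *ratio* and
is insensitive to $\alpha$ within the plausible $[1.0, 1.33]$ range.

The wall parameters default to $h = 0.945$ mm, $E = 1.41$ MPa,
$\nu = 0.5$: a quasi-rigid regime in which mean area deformations on
synthetic trees at hyperemic coronary pressures stay below 2%
(typically ~1.6%; the deformation is reported with every run so the
regime can be checked). An optional stiffness multiplier hardens the wall
further for rigid-limit verification studies.

## Numerical scheme

The interior of every vessel is advanced with a MacCormack
predictor–corrector (forward-space differences in the predictor,
backward-space in the corrector; second order in space and time for
smooth solutions). Defaults follow grid- and cycle-convergence practice
for this model class: 500 µm grid spacing, $10^{-5}$ s time step, up to
20 cardiac cycles, stopping when the relative $L^2$ change of the distal
pressure waveform between consecutive cycles falls below $10^{-3}$. The
CFL number is checked at startup and at every step; with automatic
stepping (`dt_s = NULL`) the step is chosen from the CFL bound using a
wave speed evaluated at the *anticipated peak* systolic pressure
(Windkessel swing plus the stenotic loss at peak flow), and a mid-run
violation triggers one retry with a smaller step. Fixed user-supplied
steps are never second-guessed.

Boundary nodes are closed with characteristic couplings solved by damped
Newton iteration each step. A subtlety worth recording: along tapered
vessels the textbook Riemann quantities $u \pm 4c$ are *not* invariant —
the reference wave speed $c_0(x) = c(A_0(x))$ varies with the taper — and
using them verbatim biases every coupling, which we observed as spurious
steady pressure gradients. All couplings therefore transport the
relative invariants $u \pm 4\,(c - c_0(x))$, which are conserved to
truncation error near physiological states. With this choice the steady
pressure drop in a uniform rigid-limit tube matches the closed form
$\Delta P = 22\pi\mu L Q/A^2$ within 2%, and cycle-averaged flow is
conserved through bifurcations to well under 1%.

* **Inlet**: prescribed flow $Q(t)$, area from the incoming
  characteristic.
* **Bifurcations**: conservation of mass plus continuity of total
  pressure $P + \tfrac12 \rho (Q/A)^2$ across the three ends; with flows
  eliminated through the characteristic relations this is a 3-unknown
  system in the end areas, solved with an analytic Jacobian to a scaled
  residual of $10^{-10}$.
* **Stenoses** are zero-length internal interfaces (meshing the throat
  would double-count the losses the element already integrates): flow is
  continuous and total pressure jumps by
  $$\Delta P_s = \frac{\mu K_v}{2\pi r_u^3} Q
    + \frac{\rho K_t}{2 A_u^2}\left(\frac{A_u}{A_s}-1\right)^2 |Q|\,Q
    + \frac{\rho K_u L_s}{A_u} \frac{\partial Q}{\partial t},$$
  with $K_v = 32\,(0.83 L_s + 1.64 D_s)(A_u/A_s)^2/D_u$, $K_t = 1.52$,
  $K_u = 1.2$, and $\partial_t Q$ by first-order backward difference.
  The stenosis degree is the percent radius reduction
  $(1 - r_s/r_u)\times 100\%$; any two of $\{$degree, $r_s$, $r_u\}$
  determine the third.
* **Terminals**: two-element Windkessel models $Q = P/R_p + C\,dP/dt$
  integrated with implicit Euler ($C = 9\times10^{-11}$ m³/Pa per
  terminal, i.e. 9 µcm⁴·s²/g). Resistances follow the cube-radius rule
  $R_i = (P_\mathrm{mean}/Q_\mathrm{ostial})\,\sum_j r_j^3 / r_i^3$,
  whose parallel combination equals $P_\mathrm{mean}/Q_\mathrm{ostial}$
  identically.

The state is initialized at the mean perfusion pressure implied by the
outlets with conductance-split flows, which shortens the startup
transient to a few cycles.

## Personalization and hyperemia

The inlet waveform is a unit-mean shape rescaled in time to the period
$60/\mathrm{HR}$ and in amplitude so its mean equals the ostial flow:
cardiac output × coronary fraction × dominance split. The coronary
fraction of cardiac output is not a published constant; we default to 4%
with dominance splits 70:30 (right-dominant), 80:20 (left-dominant) and
75:25 (co-dominant), all configuration-exposed. Hyperemia multiplies the
left inflow by 4 and the right by 3, and every terminal resistance by
0.22; both scalings are applied simultaneously, as both are part of the
hyperemia model. These two prescriptions over-determine a closed loop
(inlet pressure is then an *output*), which is intentional: Pa is read
from the simulation, mirroring the invasive Pd/Pa measurement (a
configuration flag substitutes clinical MAP instead).

FFR is the ratio of cycle-mean pressures at the distal probe and the
ostium, with FFR ≤ 0.80 flagged ischemic. The distal probe is placed by
walking the labeled distance downstream from the stenosis distal end,
following the larger-radius child at bifurcations (the main-branch
continuation a cardiologist would interrogate).

# Synthetic data

No patient geometries ship with the package; every input is generated:

* **Trees** are strictly bifurcating with Murray's law
  $r_p^3 = r_\mathrm{major}^3 + r_\mathrm{minor}^3$ (asymmetry
  configurable), a 3.9 mm default ostial diameter, segment lengths
  proportional to radius (ratio 22 by default, log-normally jittered),
  and branches pruned below 0.5 mm radius, emulating the >1 mm
  reconstruction limit of angiography.
* **Stenoses** are focal, centered at 40% of the arc length of the
  root's *major child* — a non-terminal branch (for depth ≥ 3), so flow
  can redistribute to the sibling as it does around a real branch
  lesion, and enough arc length (~42 mm+) remains downstream for
  clinical distal locations. Degrees sample N(55.6, 17.2)% truncated to
  [20, 95].
* **Cohort scalars** follow the aggregated characteristics of an
  angiographic coronary-disease population: CO N(4.5, 1.5) L/min, HR
  N(70.8, 13.7) bpm, SBP/DBP N(125.8, 25.8)/N(67.1, 12.7) mmHg with
  MAP = (SBP + 2·DBP)/3 (the standard clinical formula; its mean, 86.7
  mmHg, sits next to the 87.3 mmHg generalized value), hematocrit
  around 39.2% with a 4.5-point SD (a typical adult spread; no SD is
  published for this cohort), dominance 79.6/12.2/8.2%
  right/left/co-dominant, and distal locations uniform on [5, 65] mm
  clipped to the reachable arc length of the generated tree.
* **Waveforms**: the population canonical left/right shapes are not
  published as data, so analytic stand-ins are used — a baseline plus
  raised-cosine systolic and diastolic pulses, diastolic-dominant on the
  left, balanced on the right, unit mean by construction. Only the mean
  flow and the gross systolic/diastolic partition influence
  *time-averaged* pressures, so the stand-in shape is not critical; any
  sampled waveform can replace it.

What the generator does **not** emulate: tortuosity, eccentric or
diffuse plaque, serial lesions, ostial/bifurcation stenoses,
intramyocardial systolic compression, autoregulation. Passing tests on
synthetic cohorts therefore demonstrate the *mechanics* of the pipeline
(conservation, convergence, monotonicity, correct uncertainty
propagation), not clinical accuracy on real angiograms.

# Uncertainty quantification

Four clinical inputs carry uncertainty: distal location (replaced by
N(30.0, 3.5) mm draws), cardiac output (multiplied by N(1, 0.153)),
stenosis degree (shifted by N(0, 16.9) percentage points) and MAP
(multiplied by N(1, 0.056)). The cardiac-output factor perturbs only the
resistance distribution — the inlet waveform keeps the baseline cardiac
output, which mirrors treating inlet flow shape as patient-generalized.
A perturbed degree holds the imaged minimal luminal radius $r_s$ fixed
and re-derives the reference radius $r_u$, because degree is the
physician-labeled quantity from which $r_u$ is estimated. Perturbed
degrees are clipped to [0, 99.5]% and factors to ≥ 0.05 (normal tails
produce non-physical values; clips are counted and reported).

Sampling uses a second-order Saltelli design of $n(2k+2)$ rows: base
blocks A and B and radial blocks $AB_i$, $BA_i$. The base sample is a
seeded Latin hypercube mapped through each marginal's inverse CDF (a
Sobol' low-discrepancy generator is not among the package's
dependencies; the LHS base reaches the same estimator accuracy at these
$n$ within the reported bootstrap CIs). First-order indices use the
Saltelli-2010 estimator, total-order the Jansen estimator, and
second-order the $BA_i \times AB_j$ cross-block estimator. Percentile
bootstrap CIs resample the $n$ base rows (B = 1000 by default; the exact
resample count is a free choice). Indices are "converged" when every CI
width is under 10% of the largest index, and inputs with total effect
above 0.05 are significant. Estimator correctness is pinned to analytic
oracles in the test suite: the additive Gaussian model (exact indices
0.2/0.8), the Ishigami function (closed-form indices, a = 7, b = 0.1) and
a brute-force double-loop Monte-Carlo cross-check.

Cohort aggregation follows the "aggregate of all FFR values"
convention: outputs of all cases are pooled per design row, so the
estimator numerators average over cases while the variance in the
denominator includes the between-case spread.

The reclassification study re-samples only cardiac output and stenosis
degree with standard deviations inflated by a multiplier (distal
location and MAP stay at baseline), using *nested* draws — one set of
standard-normal deviates scaled by each multiplier — and reports the
mean within-case FFR range and the reclassification proportion: the
fraction of cases whose ≤ 0.80 classification flips for at least one
draw.

# Diagnostic evaluation

Model variants are compared with confusion metrics at the 0.80
threshold (ties classify ischemic, following the "≤ 0.80 is ischemic"
convention), Clopper–Pearson exact 95% CIs (computed by
`stats::binom.test`; the CI method is not prescribed and exact intervals
are the defensible choice at these counts), Pearson correlation,
Bland–Altman mean difference ± 1.96 SD limits, an empirical ROC with
trapezoid AUC, and threshold recovery: the operating point maximizing
Youden's J, reported as the *interval* between adjacent cutpoints, since
any threshold between two observed values classifies identically.

Three model configurations mirror the streamlining idea: `baseline`
(all inputs patient-specific), `semi-streamlined` (generalized MAP 87.3
mmHg, HR 70.8 bpm, hematocrit 39.2%, inlet CO 4.5 L/min, waveform shape
and ostial diameter; patient-specific resistance CO, stenosis, tree and
distal location) and `streamlined` (additionally a generalized 30 mm
distal location). The generalized ostial diameter enters only where
waveforms are supplied as velocities and must be converted to flow; with
the default flow-based scaling it is inert and kept for interface
completeness.

# Problem sizes and numerical choices in the test suite

The shipped tests and acceptance checks run on deliberately small
configurations chosen as the package's own demonstration sizes: depth-2
or depth-3 Murray trees (3–7 segments), a 2 mm (demonstration) or
0.5–1 mm (verification) grid, CFL-chosen time steps near 5×10⁻⁵ s at
the 2 mm spacing, cohorts of 2–4 cases for pipeline checks and 200 for
moment checks, Saltelli bases of n = 64 for the solver-in-the-loop
study and n = 4096–8192 for the analytic estimator oracles. Because
time-averaged pressures dominate FFR and the stenosis is an interface
element, coarsening the grid from 0.5 mm to 2 mm changes mean distal
pressure well under 1% on these trees (the refinement test asserts
< 0.5% between 1 mm and 0.5 mm), while cutting cost by an order of
magnitude. Sweeping a full >10⁶-simulation campaign is out of scope for
a desk run; the pipeline exposes `n`, the cohort and the controls so the
same code scales up unchanged.

Degenerate and edge regimes worth knowing about:

* A degree-90+ stenosis placed on the *root* segment forces the entire
  hyperemic ostial inflow through a ~0.2 mm throat; the implied
  pressures (tens of MPa) steepen the characteristics until no periodic
  solution exists and the junction coupling reports failure. This is a
  physically meaningless configuration under prescribed inflow — the
  cohort generator avoids it by placing stenoses on branch vessels, and
  the full degree range [0, 95] then simulates cleanly.
* Extreme (but solvable) stenotic pressures push total-pressure
  cancellation toward double-precision limits; couplings therefore
  accept a stalled Newton iterate when its scaled residual is still
  below 10⁻⁵ (sub-pascal at physiological scales).
* At zero flow and uniform pressure the discretization is well-balanced:
  the rest state is preserved to machine precision, taper included.

# Limitations

The solver is 1D: no secondary flows, no post-stenotic recirculation
beyond what the loss element integrates, no fluid–structure interaction
beyond the algebraic tube law, no non-Newtonian rheology, no
autoregulation or intramyocardial pump. Hyperemia uses population
scaling factors, not per-patient adenosine response. The clinical
validation numbers reported for this model family (correlations, AUC
against invasive FFR) require real angiographic cohorts and are not
reproducible from synthetic data; nothing in this package claims them.
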