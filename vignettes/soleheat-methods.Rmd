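---
title: "Methods: bioheat modelling and sensor calibration in soleheat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: bioheat modelling and sensor calibration in soleheat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(soleheat)
```

# The thermal model

`soleheat` solves the steady-state Pennes bioheat equation,

$$\nabla \cdot (k \nabla T) \;+\; \rho_b C_{p,b}\,\omega_b\,(T_b - T) \;+\; Q_{met} \;=\; 0,$$

on a layered slab representing the plantar tissue column, an instrumented
insole, and a shoe sole. The perfusion term is a linear sink pulling tissue
toward the arterial blood temperature $T_b$ at a rate set by
$\rho_b C_{p,b} \omega_b$ (W/m³/K); metabolism adds a constant volumetric
source. Steady state is appropriate because the application reads slowly
varying temperature maps, not transients, and the model is linear in $T$,
which several package invariants exploit (uniform anchor shifts translate
the solution exactly; lesion-minus-healthy differences are perturbation
fields).

Assumptions worth stating explicitly:

* **Slab geometry.** The anatomical foot outline is replaced by a
  rectangular footprint (default 0.26 m × 0.09 m) over which every layer
  extends uniformly. The layer stack and the lesion depth — not the outline
  — drive the vertical heat transfer that the sensor array measures. The
  consequences of this idealisation are discussed under *Limitations*.
* **Boundary conditions.** Convection (default h = 5 W/m²/K, 20 °C) acts
  only on the floor face below the shoe. Lateral faces are adiabatic. The
  top (deep/proximal) face is adiabatic by default: muscle perfusion anchors
  deep tissue near $T_b + Q_{met}/(\rho_b C_{p,b}\omega_b) \approx 37.07$ °C
  on its own, reproducing a uniform deep-muscle temperature without imposing
  one. A fixed top temperature is available as an option.
* **The sock.** The published sock parameter, "thermal resistance of
  0.02 W/mK", carries conductivity units. We interpret it as an
  area-specific contact resistance of 0.02 m²K/W — the magnitude of a thin
  worn sock, and the only reading that slots into a series-resistance
  interface model. It enters the face conductance across the skin–insole
  interface as $1/(L_1/2k_1 + R_{sock} + L_2/2k_2)$.
* **Blood properties.** $\rho_b$ = 1050 kg/m³ and $C_{p,b}$ = 3617 J/kg/K,
  standard human-blood values, are package defaults because the source
  tables do not list them. They matter: the zero-flux muscle equilibrium
  shifts by $Q_{met}/(\rho_b C_{p,b}\omega_b)$, about 0.07 °C for muscle.
  Both are configurable through `blood_props()`.
* **Lesions.** The published lesion is "irregular" with height 0.25 cm and
  volume 1.5 cm³; an irregular outline is not reproducible, so we use an
  oblate ellipsoid matching both printed constraints exactly (vertical
  semi-axis 1.25 mm, lateral semi-axes ≈ 16.9 mm). Depth is measured from
  the plantar skin surface to the lesion *centre*. The lesion is embedded by
  reassigning cells whose centres fall inside the ellipsoid — never by
  re-meshing — so lesion and healthy cases share an identical grid and their
  difference is free of discretization noise.
* **Sensor read plane.** Sensors read the top cell of the upper insole
  layer at their (x, y). The via under each sensing pad is filled with
  conductive paste that thermally shorts the pad to the insole contact
  surface, which makes the insole top — not the kapton plane one
  polyurethane layer down — the natural read plane. Nearest-cell lookup is
  deterministic with ties broken toward the lower cell index.

# Discretization and numerics

The finite-volume scheme uses a structured grid with grid planes placed
exactly on every layer interface, so material extents reproduce configured
thicknesses to machine precision. Face conductances combine half-cell
resistances in series (the harmonic mean for equal spacing), which handles
the five-orders-of-magnitude conductivity contrast between copper and
polyurethane without special casing.

Vertical resolution is per layer, at least 3 cells each (epidermis cells
≈ 0.15 mm). The muscle layer uses a geometrically graded grid (12 cells,
ratio 0.78) finest at its distal face, where the deepest lesions sit and
where the perfusion boundary layer (length scale
$\sqrt{k/\rho_b C_{p,b}\omega_b} \approx 7$ mm) must be resolved. The
default lateral cell is 2 mm, giving ≈ 263k cells for the full footprint.
`z_refine` splits every vertical cell evenly for convergence studies; the
test suite verifies ~4× error reduction per refinement against the
closed-form 1-D solution (second order) and a maximum deviation below
0.01 °C at the default grid.

The symmetric positive-definite system is solved by CHOLMOD sparse
Cholesky (via `Matrix`), followed by one step of iterative refinement:
with the extreme copper/polyurethane contrast, a single backsolve leaves a
normwise residual above round-off. Convergence is reported as the normwise
backward error $\|Ax-b\|/(\|A\|\|x\|+\|b\|)$, the quantity that can
actually reach round-off under such contrasts; the default tolerance is
1e-10 and typical converged values are below 1e-15. Inside
`run_depth_sweep()` the symbolic factorization is computed once and reused
across all 26 cases. A Jacobi-preconditioned conjugate-gradient route
exists for cross-checking the direct solver.

Every solve is audited: an energy balance (boundary outflow versus net
volumetric sources, normalised by the larger of the net source and the
gross boundary throughput so that source-free conduction problems are
still meaningfully scored) and a discrete maximum principle (the solution
must lie between the coldest and warmest anchors: boundary temperatures
and the zero-flux equilibria of the perfused materials present). Degenerate
configurations — all faces adiabatic with no perfusion anywhere — are
rejected with an explicit error naming the missing temperature anchor.

The 1-D verification oracle writes each perfused layer as
$T_{eq} + A e^{-m\zeta} + B e^{-m(L-\zeta)}$ in a local coordinate — a
scaled exponential pair bounded by 1 on the layer, so large $mL$ cannot
overflow — and unperfused layers as quadratics; interface
temperature/flux continuity (with the sock's resistance jump) closes a
small dense linear system. The oracle is itself cross-checked in the test
suite against an independently written 10⁴-node finite-difference solve.

# The sensor array and the detection rule

Eight sensors (hallux, three metatarsal heads, lateral midfoot, medial
arch, two heel points) are placed at fractional positions scaled linearly
with foot length; the published layout is schematic, so these coordinates
are approximations and are fully overridable. The lesion is laterally
centred on sensor S4 by default. A deviation is *detectable* when
$|T_{lesion} - T_{healthy}| \ge$ 0.1 °C at a sensor, the resolution of the
readout device; the comparison is inclusive, reading "limit of detection"
as the smallest detectable change. Whether the six published lesion depths
were chosen as layer midpoints is not stated anywhere; they are treated as
given values.

# Synthetic data generators

The generators provide the statistical structure the calibration analyses
assume, not device physics:

* `gen_charge_force()`: evenly spaced forces over 0–4 N, charge =
  slope·force + intercept + Gaussian noise (defaults: slope 4.5 pC/N,
  σ = 0.5 pC, n = 50) — the quasi-static piezoelectric test.
* `gen_cv_trace()`: the triangular CV potential program (start +0.5 V,
  vertices +1.0/−1.2 V, 4 scans, 0.1 V/s), a linear baseline, and a
  Gaussian anodic oxidation peak at +0.72 V (σ = 0.05 V) whose height is
  gain × a piecewise-linear saturating response — linear to 6 mM, flat from
  6 to 10 mM, linear again from 10 mM. The breakpoints are fixed at 6 and
  10 mM so that linear-range detection is exercised against exactly the
  published two-range structure. Defaults: gain 2 µA/mM, noise 0.01 µA.
* `perturb_tissue_params()`: multiplies each positive thermophysical
  parameter by an independent factor uniform in [1−f, 1+f]; zeros are
  preserved exactly (the unperfused epidermis stays unperfused) and the
  arterial temperature is held fixed, since jittering the anchor would
  conflate boundary-condition changes with material uncertainty.

Everything is reproducible down to the written decimal text under a fixed
seed, and every generator writes to the same delimited-text format the
calibration readers consume.

What the generators deliberately do **not** emulate: electrochemical
kinetics (Butler–Volmer, diffusion), enzyme saturation curves, drift,
electrode aging, capacitive currents, or temperature cross-sensitivity.
Passing calibration tests therefore demonstrates that the analysis
pipeline recovers known structure from noisy data of the assumed form —
not that it would be robust to every artefact of a real potentiostat
trace.

# Calibration conventions

* **Peak extraction** reads the final anodic sweep (conditioning sweeps are
  discarded), anchors a straight baseline on the mean of the outer 5 % of
  window samples at each edge, and returns the maximum corrected current in
  the window. Correction by a straight line through two edge anchors is
  *exactly* invariant to any global linear baseline. The default window
  (0.3 V ≈ 6 peak widths) recovers known peak heights within 2 %; the
  residual bias is the Gaussian tail under the baseline anchors, and an
  8-width window reduces it to ~0.2 %. A window maximum that lands on the
  window edge is flagged and warned about.
* **Blank replicates** are read at the nominal peak potential, not as a
  window maximum: the maximum of pure noise over ~150 samples is an
  extreme-value statistic whose spread is roughly half the per-point noise,
  which would silently deflate the limit of detection. With fixed-potential
  reads, the blank standard deviation estimates the generator noise and
  LOD = 3.3 σ/S matches the closed form (verified across resampled blank
  batches in the tests).
* **The IUPAC multiplier** is fixed at 3.3 by default (the common
  3σ-with-slope-uncertainty convention); the published text cites the IUPAC
  formula without printing the constant, so the multiplier is an explicit
  argument.
* **Linear-range search** grows windows greedily from the low-concentration
  end, requiring at least 4 points and OLS r² ≥ 0.99 (configurable); after
  a window closes, the search restarts from the next point. On the
  structured generator this yields one window ending at 6 mM and one
  spanning 10–24 mM. A window of identical responses has no variance and is
  scored r² = 0 rather than fitting "perfectly"; a plateau therefore never
  qualifies as a linear range.
* **Units.** Concentrations are mol/L internally; reports convert with
  1 mM glucose = 18.016 mg/dL. Sensitivity is slope/area with the electrode
  area supplied in cm², matching the conventional µA/mM/cm² form. The
  published bench values (d33 = 4.5 ± 0.3 pC/N, LOD 3.27 µM, sensitivity
  21 µA/mM·cm²) are *context* for the synthetic studies, not reproduction
  targets: the raw bench data and the electrode area were never published,
  and the peak-normalisation used in the published calibration plots is
  unspecified. Responses can be normalised by the maximum in-series peak
  when dimensionless calibrations are wanted.

One printed-value tension is worth recording: at the published
d31 = 0.7 C/m² and εᵣ = 10.55, the figure-of-merit formula d31²/(ε₀εᵣ)
evaluates to ≈ 5.25 GPa, while the text prints 4.7 ± 1 GPa — the formula
value lies inside the printed uncertainty, and the package implements the
formula. Likewise 4 N on the 3.8 mm electrode gives ≈ 353 kPa against a
printed 358 kPa (implied diameter ≈ 3.77 mm); the package implements the
geometric conversion.

# Problem sizes used by the test suite

The acceptance tests solve the healthy baseline at the full default
resolution (2 mm lateral, ≈ 263k cells) and run the complete 26-case
detectability sweep at 4 mm lateral resolution with the default vertical
grid — sizes chosen so the entire suite completes in a few minutes while
the quantities asserted (region means, per-sensor deviations of order
0.01–0.5 °C, detectability flags) are insensitive to the lateral
refinement at well below threshold level. Oracle comparisons and
perturbation sweeps use narrow laterally uniform columns of the full
stack, which are exactly equivalent to the full footprint for laterally
uniform configurations.

# Limitations, and which published observations the slab cannot reproduce

The slab idealisation routes *all* metabolic heat through the insole: with
adiabatic top and lateral faces, the only exit is the floor. An anatomical
foot sheds most of its heat through the dorsal surface and sides, and its
insole is only partly covered by the foot. Three consequences, all visible
in the package's own acceptance checks and deliberately left as honest
discrepancies:

1. **The insole surface runs warm.** The published thermal maps show a
   deep-muscle temperature of 36.4 °C and an insole contact surface around
   24 °C. The slab reproduces the muscle value closely (≈ 0.6 °C high) but
   puts the insole top near 35 °C: a 1-D path from a 37 °C perfusion anchor
   through ≈ 0.45 m²K/W of stack resistance to a 20 °C floor cannot produce
   a 12 °C drop between skin and insole while sustaining the deep-muscle
   temperature. The published 24 °C is a 3-D geometry effect (dorsal heat
   loss, partly covered insole), not reachable under the slab assumptions
   with any physical sock or blood parameter.
2. **Deep-lesion detectability categories shift.** The slab carries ~4×
   the plantar heat flux implied by the published insole temperature. An
   ischemic lesion is strongly insulating (k = 0.1 W/m/K), and in a
   high-flux column its dominant surface signature is a *flux-blocking
   shadow* that barely decays with depth — so barefoot ischemia remains
   detectable deeper than published, and its |ΔT| is not monotone in depth
   (the package asserts depth-monotonicity for inflammation only). The
   inflammation signature, by contrast, is a perfusion/metabolism *source*
   anomaly that decays quickly against the perfusion screening length, and
   at 8–10 mm depth it falls below the 0.1 °C resolution, whereas the
   published model still detects it. Both shifts trace to the same
   geometric simplification, not to the discretization (the solver matches
   the closed-form oracle to < 0.01 °C).
3. **The sock slightly amplifies remote sensors.** Added contact
   resistance attenuates the lesion signal at the sensors above it (S4 and
   its neighbours) but redistributes a tiny part of the perturbation
   laterally through the tissue, so remote sensors can see |ΔT| *increase*
   by up to ~0.002 °C — 50× below threshold, but a sign-consistent effect,
   not noise.

Within its stated scope — vertical heat transport, lesion-depth trends at
the near sensors, sock attenuation of the detection signal, solver
correctness, and the calibration mathematics — the slab model is verified
against closed forms, conservation audits, comparison principles and
generator ground truth. Extending the geometry (partial foot coverage,
dorsal convection, a foot-shaped footprint) would be the natural next step
for closing the remaining categorical gaps.
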