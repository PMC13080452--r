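---
title: "Modelling centrifugal-disc EV assays: flow, washing and analytics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling centrifugal-disc EV assays: flow, washing and analytics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(discassay)
```

`discassay` models a centrifugal microfluidic bead assay for
extracellular-vesicle (EV) surface proteins: a disc spinning at constant
rate ω carries an assay chamber at radius `r_a` whose floor is a porous
membrane filter. Capture beads sit on the membrane; sample and wash buffers
enter the chamber from the rotation-center side and waste leaves through
the membrane into a sub-membrane cavity that drains at the near-side
reference point X0. This vignette describes the models, their assumptions,
the tunable parameters, what the synthetic-data generators do and do not
emulate, and the numerical choices, in the package's own terms.

## Rotating-frame flow model

In the co-rotating frame the steady incompressible Navier-Stokes equations
acquire two apparent body forces: the centrifugal force density
`f_cen = ρω²(x, y, 0)` (radially outward from the rotation axis z) and the
Coriolis force density `f_cor = −2ρ Ω × u`, perpendicular to both the
velocity and the axis. Gravity `(0, 0, −ρg)` is available but disabled by
default: at assay speeds it is orders of magnitude below the rotational
forces. The Euler force is identically zero at constant spin and is not
modelled. The disc turns clockwise as seen from +z, encoded as
`Ω = −ω ẑ`; with this convention radially outward flow deflects toward +y,
which is the orientation convention used throughout (and pinned by a unit
test on the force components).

The driving flow rate through the feed channel follows from the
Hagen-Poiseuille law under the centrifugally induced pressure head
`ΔP = ρω² r̄ Δr` of the fluid column (mean radius `r̄`, radial extent
`Δr`):

    Q = d_H² A ρ ω² r̄ Δr / (32 μ L).

`Q` therefore scales as ω² and 1/μ, and the implementation is cross-checked
in the tests against an independent pressure-over-resistance evaluation.

Two dimensionless groups organise the behaviour. The Ekman number
`E_k = ν/(ωH²)` measures viscous relative to Coriolis effects over the
chamber fluid height H; rescaling `(μ, ω) → (kμ, kω)` leaves `E_k` — and,
in this model, the whole normalized flow pattern — invariant, which the
test suite verifies as a pattern correlation above 0.99. The bead Stokes
number `Stk = ρ_p d_p² ω/(18μ)` is ~3×10⁻⁴ for a 5-µm polystyrene bead at
1800 rpm: beads are strongly overdamped and follow the fluid. Exact
literature definitions of both numbers vary by factors of order unity; the
package fixes the two forms above and relies only on similarity and
order-of-magnitude statements, which such factors do not affect.

## Chamber geometry

The chamber geometry is not something a desk model can take from a
datasheet, so `chamber_domain()` uses device-plausible defaults chosen
once: a square-footprint chamber of side D = 13 mm (the membrane diameter),
upper fluid height H = 0.3 mm, sub-membrane cavity h = 0.5 mm, chamber
center at `r_a` = 40 mm, inlet window (2 mm wide) entering the upper layer
on the rotation-center side, and the outlet draining the cavity on the same
side. H = 0.3 mm matches the 30–120 µL working volumes of such assays and
places the device in the regime where the flow is mirror-symmetric at
10 rpm and strongly Coriolis-deflected at 1800 rpm — the qualitative
behaviour the device exhibits. With H ≈ 1 mm the Ekman number at 10 rpm
would be of order one and even slow rotation would visibly deflect the
flow. Only trend-level claims depend on these defaults.

An `outlet_level = "upper"` variant places both ports in the upper layer
(offset to either side of the midline) above a closed cavity. It exists to
quantify how much of the through-flow dips into the protected sub-membrane
compartment — the `membrane_flux_fraction()` diagnostic — which is
identically ~1 in the default geometry, where all waste must cross the
membrane.

## Numerical scheme

The solver marches the momentum equations in pseudo-time on a staggered
(MAC) grid until the velocity field stops changing (relative maximum change
below `tol`, default 10⁻⁶ per step), with:

- **Chorin projection**: an explicit provisional momentum step followed by
  an exact pressure solve (sparse Cholesky of the fixed Poisson matrix via
  the Matrix package), so every iterate is discretely divergence-free to
  round-off. Global mass balance closes to ~10⁻¹⁰ relative in the tests.
- **Reduced pressure**: the centrifugal force is conservative
  (`ρω²(x, y, 0) = ∇(ρω²r²/2)`), so by default it is absorbed into the
  pressure. This is not merely cosmetic: an open boundary held at a uniform
  *raw* pressure would otherwise drive a spurious jet against the
  centrifugal head. With reduced pressure, open boundaries are referenced
  to the local centrifugal head, as a feed channel physically is. An
  `"explicit"` mode retains the raw force for comparison.
- **Exact Coriolis rotation**: the explicit Coriolis term has amplification
  `√(1 + (2ωΔt)²) > 1` and destabilizes the march at high rpm, so the
  solver applies the rotation `du/dt = 2Ω_z v, dv/dt = −2Ω_z u` exactly
  over each step as a split sub-step (unconditionally stable).
- **Brinkman membrane layer**: the physical membrane (~10 µm) is thinner
  than a grid layer, so the membrane occupies one layer with an effective
  permeability `κ_eff = κ · Δz / t` that preserves the layer's total
  hydraulic resistance. The Darcy drag `−(μ/κ_eff)u` is implicit, and the
  projection uses drag-consistent face transmissibilities
  `1/(1 + Δt μ/(ρκ_eff))` so the divergence-free property holds inside the
  membrane too.
- **First-order upwind advection** by default (`"central"` available): the
  chamber Reynolds number is of order 1–10, so accuracy is dominated by
  geometry rather than the advection scheme.
- **Open boundaries** carry a full momentum update with a zero-gradient
  ghost and a half-cell Dirichlet pressure; this matters quantitatively —
  without it the effective channel length is short by one cell and
  benchmarks miss by 1/(N−1).
- **Boundary orientation**: the rotation-driven flow rate is prescribed at
  the *outlet* with an open (fixed-pressure) *inlet* — the narrow inlet
  channel suppresses backflow, making the open condition appropriate
  there — with a `bc_orientation = "inlet_flow"` switch to the conventional
  scheme for robustness checks.
- **Determinism**: no randomness anywhere in the solver; fixed iteration
  order; identical inputs give bit-identical fields.

The time step is chosen automatically from the viscous and advective
stability limits (Coriolis no longer constrains it). Two benchmarks pin the
discretization: plane Poiseuille flow at 32 cells across the gap (within
5%; measured ~0.1%) and the Hele-Shaw depth-averaged closed form (within
2%). Halving the cell size changes the X1 edge-speed diagnostic by less
than 25% at the default resolution (verified in the tests; the diagnostic
is used only for monotone comparisons at fixed resolution).

The 2D depth-averaged mode solves the in-plane momentum equations with
Hele-Shaw drag `−12μu/H²` and, where a membrane is present, an additional
Brinkman drag over its footprint. It is a fast surrogate used for the
symmetric and similarity properties; the vertical redirection mechanism
only exists in 3D mode.

## Flow diagnostics

- `edge_region_speed()`: mean speed over upper-chamber cells within 10% of
  the chamber diameter of the X1 (far +x) or Y1 (far +y) wall — "upper
  chamber" meaning strictly above the membrane layer.
- `asymmetry_index()`: `‖u − M(u)‖/(‖u‖ + ‖M(u)‖)` with M the mirror about
  the x-z plane (y-velocity negated); 0 for symmetric fields, and checked
  to grow monotonically over the 10/300/1800 rpm sweep.
- `bypass_fraction()`: massless tracers seeded quasi-uniformly across the
  inlet (stratum centers with a 5%-of-stratum seeded jitter, which keeps
  the estimate stable to ±1/n across seeds), advected by fixed-arclength
  midpoint steps (¼ of the minimum cell size, capped at 10⁵ steps; stalled
  tracers count as retained). A tracer "bypasses" if it exits the outlet
  without ever crossing the chamber-center plane in x. The far-half
  criterion is this package's definition; no standard quantitative bypass
  metric exists for these devices.
- `membrane_flux_fraction()`: gross downward flux across the membrane top
  relative to the inlet flux.

One genuine behaviour worth stating plainly: in the default geometry the
membrane-redirection effect *saturates*. Once the membrane's resistance
dominates the lateral Hele-Shaw resistance of the upper layer — i.e. once
the spreading length `λ = √(H³t/12κ)` exceeds the chamber size — the
crossing-flux profile is uniform and further resistance increases change
the pattern only marginally. All track-etched membranes (20 nm–800 nm
pores) sit deep in that saturated regime. Resistance sweeps intended to
resolve the transition therefore include low-resistance mesh-type filters
(pore scale 4–60 µm); the monotone trends (edge speeds up, bypass down,
washing better with R_h) are asserted across that resolved range.

## Washing and retention models

The washing model is a deliberately simple two-compartment surrogate, not a
transport simulation: a swept compartment (chamber volume `V_cham`) diluted
per cycle by `exp(−η V_w/V_cham)` with sweep efficiency
`η = 1 − bypass_fraction`, and a dead compartment (sub-membrane cavity
volume `V_sub`) untouched within a cycle; between cycles both relax halfway
toward the volume-weighted mixture (exchange fraction 0.5, configurable —
no measurement constrains it). The residual after n cycles is the
volume-weighted mean concentration. The model is monotone in the directions
that matter — residual falls with η, wash volume and cycles, rises with the
cavity height — and is invariant under joint rescaling of all volumes.
Its acceptance surface is trend reproduction only; no attempt is made to
fit measured residual-dye magnitudes, which depend on dye adsorption and
optics outside this model.

Fluid retention above the membrane during spinning is a quasi-static level
balance: drainage `Q_mem = ρω² r_a · level / R_h` against the wash inflow
`Q_in`, giving `retention = min(Q_in R_h / (ρω² r_a H), 1)`. It rises with
membrane resistance and inflow, falls with ω², and reproduces the ordering
that the 200-nm filter retains fluid better than the 800-nm filter (their
R_h ratio is 16 at equal porosity). The ~50%/~90% retention levels observed
experimentally for such filters are treated as an ordering constraint, not
a calibration target.

## Assay statistics

Per-sample marker intensity is the median fluorescence intensity (MFI) of
the recorded bead events (5000 by default; even counts use the midpoint
convention). Marker signals are background-corrected against the isotype
control, `ΔI_M = I_M − I_IgG`, and normalized to EV abundance through the
reference marker CD63, `ξ_M = ΔI_M/ΔI_CD63` — a ratio invariant to detector
gain, which the generator tests verify exactly. `ξ` is flagged undefined
(never silently zeroed) when `ΔI_CD63 ≤ 0`.

The detection limit is the concentration where the mean titration response
first crosses `mean(blank) + 3·sd(blank)` — the 3σ rule is the field
convention — located by linear interpolation in log₁₀ concentration between
the bracketing tested concentrations. A zero-spread blank panel makes the
crossing unlocalizable, so that degenerate case returns the lowest
concentration whose response exceeds the blank mean. Detection limits in
EVs/mL convert to molarity as `c · 1000 · copies_per_EV / N_A`.

Classification follows the standard small-cohort workflow: features are
log-transformed ξ values (`cohort_features()`; fluorescence ratios have
multiplicative within-group scatter, so the log is variance-stabilizing)
z-scored to zero mean and unit sample SD. A logistic risk score (maximum
likelihood; a small ridge penalty replaces the fit when the classes
separate, flagged in the result) with rank-based (Mann-Whitney, half-credit
ties) AUC handles two-group contrasts; the default panel is
CLDN3/CLDN4/EpCAM when present, and whether a full-panel score is wanted
instead is a single argument. Four-group discrimination uses Gaussian LDA
with pooled covariance and *empirical* class priors (the cohort's 28/16/19/19
imbalance is informative; equal priors would discard it), with diagonal
loading `10⁻⁶·trace/p` on singularity, flagged. Generalization is assessed
by leave-one-out cross-validation (folds that lose a class below the
fittable minimum are flagged and predicted from the remaining classes) and
uncertainty by a stratified bootstrap (resampling within groups preserves
the design imbalance; 1000 iterations by default, deterministic under the
seed).

## Synthetic-data generators

The generators provide every input the pipeline needs, with planted ground
truth; they define the study conditions for the tests.

- `generate_bead_events()`: log-normal per-event intensities (fluorescence
  noise is multiplicative) with a planted median; defaults echo the scale
  of amplified CD63 signals (~3200) for realism.
- `generate_titration()`: mean response flat at the blank baseline below a
  planted onset and rising log-linearly above it, with the onset placed so
  the blank + 3σ crossing sits exactly at the planted detection limit
  (default 4.6×10⁵ EVs/mL on a 10⁴–10⁹ EVs/mL quarter-decade grid,
  triplicates, 6% CV). The blank panel is drawn with exact sample mean and
  SD so the planted threshold is the series' true threshold; replicate
  noise still enters through the CV. In the noiseless limit the estimator
  recovers the planted crossing to interpolation accuracy.
- `generate_cohort()`: 82 samples in groups HD 28 / ES 16 / PS 19 / PR 19
  with raw channels (nine markers, CD63, IgG) constructed so the derived ξ
  values follow a planted per-group log-normal structure. The default
  pattern elevates CLDN3/CLDN4/EpCAM in all cancer groups (the diagnostic
  panel), adds CA125/STn in late-stage disease, and shifts IL6R between
  platinum-sensitive and platinum-resistant groups (the resistance signal).
  `effect_size` scales the pattern in within-group SD units; 0 gives a null
  cohort on which the pipeline performs at chance.

What the generators deliberately do **not** emulate: plasma-matrix and
batch effects, inter-site variability, heavy-tailed outlier samples,
marker-marker correlations beyond those induced by shared CD63/IgG
channels, and any *clinical* effect size — the planted separations are
chosen for controlled power analysis, not to mimic patient data. Passing
tests therefore demonstrate that the pipeline recovers known structure at
stated signal-to-noise, not that comparable performance would be achieved
on clinical samples; published clinical figures (e.g. AUC 0.980,
LOOCV accuracy 0.77) are not reproduction targets, as the underlying
patient data are not public.

## Problem sizes and tolerances

The validation suite runs on deliberately modest problem sizes: the 3D
chamber at 26×26×12 cells (18×18×8 for unit tests), the Poiseuille
benchmark at 24×32, titrations with 21 concentrations × 3 replicates, and
the 82-sample cohort. Solver convergence is 10⁻⁶ relative velocity change
per step; mass balance and mirror antisymmetry are checked at 10⁻⁶
relative; the low-rotation symmetry threshold is an asymmetry index below
0.02 at 10 rpm; planted-truth recovery bars are ±30% for the detection
limit, AUC ≥ 0.95 and LOOCV accuracy ≥ 0.90 at a 2-SD planted separation.

## Known limitations

- The chamber is a square-footprint voxel model with axis-aligned walls;
  no body-fitted or cylindrical geometry.
- Steady state only: the oscillatory mixing mode of such devices (rocking
  at ±120°/s) involves the Euler force and transients, both out of scope.
- Single-phase, filled chamber: filling/emptying dynamics and air-liquid
  interfaces are not simulated (retention uses the quasi-static balance
  instead).
- The membrane is a uniform Brinkman layer; pore-scale effects, fouling and
  bead-membrane interactions are not modelled.
- The washing model is a compartment surrogate whose absolute residuals are
  not calibrated to dye measurements; only its monotone structure is used.
- Edge-speed magnitudes depend on the geometric defaults; only monotone
  trends across sweeps are asserted.
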