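# discassay

Modelling and analytics for centrifugal (lab-on-a-disc) bead assays of
extracellular-vesicle (EV) surface proteins.

In these devices a spinning polymer disc drives sample and wash buffers
through an assay chamber whose floor is a porous membrane filter. The filter
retains antibody-coated capture beads while waste drains through it, and the
interplay of the rotating-frame body forces — the centrifugal force
`f_cen = ρω²(x, y, 0)` and the Coriolis force `f_cor = −2ρ Ω × u` — with the
membrane's hydraulic resistance `R_h = μt/(κA)` redirects the wash flow
laterally across the chamber. That lateral sweep is what makes enzymatic
signal amplification usable on-disc: stringent washing keeps the background
low enough for tyramide-amplified fluorescence readout of EV markers on
individual beads. `discassay` is for microfluidics and assay developers who
want to reason quantitatively about that mechanism, and for analysts running
the downstream statistics of such assays.

The package provides:

- **Rotating-frame physics** (closed form): body-force densities,
  centrifugally driven channel flow `Q = d_H²A · ρω² r̄ Δr / (32 μ L)`
  (Hagen–Poiseuille under the centrifugal pressure head), Ekman number
  `E_k = ν/(ωH²)`, bead Stokes number `Stk = ρ_p d_p² ω / (18μ)`, and
  cylindrical-pore membrane hydraulics `κ = φ d_pore²/32`.
- **A steady incompressible flow solver** in the co-rotating frame on a
  staggered (MAC) grid — pressure-projection pseudo-time marching with an
  exact split-step Coriolis rotation and a Brinkman drag term `−(μ/κ)u` in
  the membrane layer; a coarse 3D mode and a fast depth-averaged 2D
  (Hele-Shaw) mode.
- **Flow diagnostics**: mean speeds in the X1/Y1 edge bands, a mirror
  asymmetry index, a tracer-based inlet→outlet bypass fraction, and the
  membrane flux fraction.
- **Washing models**: a two-compartment dilution model of residual
  contaminant and a quasi-static drainage balance for fluid retention above
  the membrane.
- **Assay statistics**: median bead intensities (MFI), the background- and
  EV-abundance-normalized marker metric `ξ_M = (I_M − I_IgG)/(I_CD63 −
  I_IgG)`, target-to-background ratios, blank + 3σ detection limits with
  log-linear interpolation, EV-to-molar conversion, z-scoring, logistic risk
  scores with rank-based ROC/AUC, pooled-covariance LDA, leave-one-out
  cross-validation, and stratified bootstrap standard errors.
- **Synthetic-data generators** with planted ground truth: bead-event
  tables, titration series with a planted detection limit, and an 82-sample
  four-group cohort (healthy donors n = 28, early-stage ovarian cancer
  n = 16, platinum-sensitive n = 19, platinum-resistant n = 19; nine cancer
  markers plus CD63 and IgG channels).

## Worked example

```r
library(discassay)

# signal contrast of the amplified vs two-step protocol
target_to_background(3195, 778)
#> [1] 3.106684
target_to_background(1796, 749)
#> [1] 1.397864

# detection limit recovered from a synthetic titration with a planted
# blank + 3 sigma crossing at 4.6e5 EVs/mL
ts <- generate_titration(titration_recipe(planted_lod = 4.6e5, cv = 0.06, seed = 7))
estimate_lod(ts)
#> LOD = 4.569e+05 EVs/mL (threshold 175, ok)
ev_concentration_to_molar(4.6e5, 12)
#> [1] 9.166177e-15

# synthetic 82-sample cohort -> three-marker risk score and 4-group LOOCV
co <- generate_cohort(cohort_recipe(effect_size = 2, seed = 1))
z  <- zscore_standardize(cohort_features(co))
sel <- co$group %in% c("HD", "ES")
fit_risk_score(z$X[sel, ], droplevels(co$group[sel]))
#> Logistic risk score on {CLDN3, CLDN4, EpCAM}: AUC = 0.962
loocv(z$X, co$group)
#> LOOCV: accuracy 0.927, weighted F1 0.926, weighted recall 0.927 (82 folds)

# rotating-frame flow in the membrane chamber at 1800 rpm
dom <- chamber_domain()   # 13-mm chamber, 200-nm track-etched membrane
f <- solve_steady_flow(dom, rotating_frame(rpm = 1800), fluid(1000, 1e-3))
flow_diagnostics(f)
#>    rpm          R_h            Q   speed_X1    speed_Y1 asymmetry bypass
#> 1 1800 1.205434e+12 1.043711e-08 0.00159175 0.002346382 0.6841633   0.25
#>   membrane_fraction mass_imbalance
#> 1                 1   7.889956e-11
```

The first block reproduces the published signal-contrast arithmetic: the
amplified protocol raises the target-to-background ratio from 1.4 to 3.1.
The titration block shows the blank + 3σ estimator recovering a planted
detection limit of 4.6×10⁵ EVs/mL (about 9 fM of CD63 at ~12 copies per
EV). The cohort block runs the classification workflow on synthetic data
with strong planted group structure. The flow block solves the chamber at
1800 rpm: with the 200-nm membrane in place only a quarter of the inlet
flow short-circuits to the outlet (`bypass`), the Coriolis deflection is
pronounced (`asymmetry` 0.68), and mass balance closes to round-off.

A longer account of the models, their assumptions and the numerical choices
is in `vignettes/disc-assay-modelling.Rmd`.

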