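---
title: "A desk-scale virtual model of power-controlled irrigated RF ablation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A desk-scale virtual model of power-controlled irrigated RF ablation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

`rfablate` simulates a single power-controlled, saline-irrigated
radiofrequency (RF) application of an ablation catheter pressed
perpendicularly into cardiac tissue, and the study-level analyses built on
top of it (factorial safety sweeps, protocol comparisons,
repeated-application sequences). The geometry is reduced to the
axisymmetric (r, z) half-plane: a tissue slab of the chamber's wall
thickness below the endocardial datum z = 0 (6 mm atrium, 12 mm
ventricle), a blood pool above it, and a 7 Fr metal tip (spherical or
cylindrical, 3.5 mm of metal) inserted to a contact-force-dependent depth,
with an insulating catheter shaft above. All lesion depths are measured
from the undeformed surface z = 0 regardless of indentation.

Two fields are evolved:

* **Electric potential** (quasi-static at RF frequency):
  `div(sigma(T) grad V) = 0` on tissue and blood, with the metal tip as an
  equipotential surface and the dispersive return on the far radial
  boundary of the blood pool. Joule heating `q = sigma |grad V|^2` couples
  into the thermal problem. The generator model is pure power control: at
  every step the field is rescaled by `sqrt(P_set / P_raw)` so the
  dissipated power equals the setpoint exactly, with no temperature limit.
  The fixed 120 Ohm impedance is used only for generator-style V/I
  reporting.
* **Temperature** (Pennes-type bioheat without perfusion or metabolic
  terms): `rho c(T) dT/dt = div(k(T) grad T) + q - q_sink`, advanced by
  backward Euler with lagged (Picard) coefficient evaluation, iterated to
  a relative tolerance of 1e-4. Backward Euler is unconditionally stable,
  which lets the cool-down phase run at a ten-fold larger step than the
  heating transient.

Material properties are linear in temperature: electrical conductivity
+0.15 %/°C, thermal conductivity -0.05 %/°C, and specific heat with an
absolute slope of -0.42 J/(kg K) per °C. The specific-heat figure is
stated without a percent sign in the source literature, unlike the other
two coefficients; we read it as an absolute slope, and the reading is
configurable through the material parameters. Default myocardium, blood,
platinum-iridium and polyurethane values are literature stand-ins in the
style of the IT'IS database at RF frequencies, shipped in
`inst/extdata/materials.yaml` and overridable from any run configuration.

Lesions are the region of tissue whose running maximum temperature
reached 50 °C, extracted by linear interpolation along element edges (no
smoothing): maximum depth D, maximum diameter W, depth of the maximum
diameter DW, and the axisymmetric volume. The lesion is measured twice —
at power-off and after the cool-down — so the thermal-latency
contribution is visible; the reported lesion is the post-cool-down one.
Safety monitors run at every powered step: a steam pop is declared when
any tissue node reaches 97 °C, charring when any blood node in a 0.3 mm
shell around the blood-exposed electrode surface and shaft junction
reaches 80 °C. The first event ends the application (power to zero, the
simulation continues through cool-down so the partial lesion is still
measured), precluding the other, and ties within one step resolve to the
larger overshoot.

## Reduced cooling and current-shunting models

The hydrodynamics of blood flow and saline irrigation are not solved.
They are replaced by a small set of parametric reduced models, which is
where all empirical calibration lives (`cooling_calibration()`):

| Term | Form | Default | Acts on |
|---|---|---|---|
| Irrigation film | `h_irr = 1200 Q^0.8` W/(m²K), saline at 25 °C | `Q` in ml/min | distal 75 % of the blood-exposed tip |
| Junction film | `0.25 h_irr` | — | uncooled band at the metal/shaft junction |
| Saline-cloud shunt | `sigma_blood * (1 + 1.232 Q^0.25)` | within 8 mm of the tip | electrical conductivity of the peri-electrode pool |
| Blood transport | `k_blood * (1 + 25 v^0.8)` | `v` in m/s | blood-region conduction |
| Blood sink | `w = 250 v` 1/s towards 37 °C | — | blood-region relaxation |
| Endocardial film | `4000 v^0.8` W/(m²K) | — | tissue surface |
| Substrate film | `h = 20` W/(m²K) to 37 °C | — | far face of the tissue wall |
| Plate contact | `g = 0` S/m² (off) | — | electrical Robin contact to a grounded plate under the tissue |

Three of these deserve comment, because they are structural choices and
not just coefficients:

* **The saline cloud.** The irrigation jets keep a saline-rich,
  highly conductive pool around the tip. Without it, the potential field
  of an inserted equipotential tip concentrates so strongly that no
  boundary cooling can keep a standard 30 W/30 s application below the
  pop threshold — the near-field Joule density sits an order of magnitude
  above what a safe 5.3 mm lesion implies. Modeling the pool as a
  conductivity multiplier on blood within 8 mm of the tip, growing with
  the flushing rate and collapsing to 1 at Q = 0, spreads the
  current-emitting surface the way the physical saline column does. The
  strengthening with Q is also what lets high-power short-duration (HPSD)
  applications at 60 ml/min complete safely while the same protocols pop
  at low irrigation.
* **The substrate film.** The reference experiments rest the tissue on a
  holder in a thermostated bath. A hard 37 °C clamp at the far face of a
  6 mm atrial wall forbids the published 5.31 mm standard lesion depth
  (the 50 °C front would have to live 0.7 mm from a clamped boundary),
  while a perfectly insulated face makes every atrial lesion transmural.
  A finite film (default 20 W/(m²K)) is the honest in-between and is the
  main stage-1 calibration degree of freedom for atrial depth.
* **The return path.** The dispersive electrode is placed on the far
  radial boundary of the blood pool, i.e. the remote bath return.
  Grounding the bottom of the tissue slab instead (the naive reading of
  an electrode-under-the-sample rig) funnels the current axially through
  the thin wall; measured on this model it raises the on-axis sub-tip
  Joule density by 2.3x and makes every standard application pop, so the
  far-field-placement sensitivity claim that motivated it does not
  survive contact with the discretized problem. A finite plate contact
  (`plate_conductance`) is retained as an explicit rig parameter, off by
  default; see Limitations for why.

## Contact force and tip geometry

The elastic contact problem is replaced by monotone piecewise-linear
tables mapping contact force to insertion depth, one per tip shape
(`default_contact_model()`): 0.4/0.7/1.0/1.3 mm at 5/10/15/20 g for the
cylindrical tip, and a deeper table for the spherical tip fixed so that
the closed-form tissue-contact areas of the two tips — spherical cap
`2 pi R d` versus base-plus-band `pi R^2 + 2 pi R d` — cross exactly at
10 g: below it the spherical tip touches less tissue, above it more.
Indentation is geometric: the tissue conforms to the tip over the
indented footprint and returns to the datum immediately outside it
(zero-width fillet); the displaced-tissue bulge is not modeled.

## Numerics

The mesh is a structured, graded axisymmetric triangulation: uniform
spacing `h_min` in a window around the electrode and the prospective
lesion, geometric coarsening to `h_max` at the far field (40 mm radial,
20 mm of blood). Grid lines are snapped to the electrode radius, datum,
tip apex and metal/shaft junction, so cylindrical interfaces are
mesh-conforming; the spherical cap is resolved at `h_min`. Assembly is
P1 with one-point (centroid) quadrature and lumped mass; linear systems
are solved by sparse Cholesky with the symbolic factorization reused
across steps, which is what makes 432-run sweeps tractable on one CPU.

Three presets bundle the accuracy/cost trade-off (`numerics_config()`):

| preset | h_min | h_max | dt heat | dt cool | typical mesh | use |
|---|---|---|---|---|---|---|
| desk | 0.12 mm | 2.5 mm | 0.02 s | 0.25 s | ~7000 nodes | single-run studies |
| coarse | 0.2 mm | 3 mm | 0.05 s | 0.5 s | ~3000 nodes | calibration, protocol comparisons |
| sweep | 0.3 mm | 4 mm | 0.1 s | 1 s | ~1700 nodes | factorial sweeps |

These sizes were chosen so that a standard 30 W/30 s application runs in
seconds and the full 432-configuration sweep in a few minutes; halving
the heating step changes the lesion depth of an HPSD run by well under
1 %, and the electrode-window grading keeps the metrics stable under
refinement (both are asserted in the test suite). Cool-down (default
60 s, covering the 45-60 s thermal-latency window) terminates early once
every tissue node is below the lesion isotherm, since the cumulative
maximum field can no longer change.

## Stage-1 calibration

`calibrate_cooling()` fits a chosen subset of the reduced-model
parameters (default: the substrate film) by deterministic least squares
on the relative depth/width errors of reference lesions. The shipped
stage-1 references are the two standard 30 W/30 s rows — atrium
5.31/7.59 mm, ventricle 4.53/6.49 mm, both at CF 10 g, 17 ml/min, low
blood flow — and nothing else: HPSD rows are predictions of the
calibrated model, never fitting targets. With the shipped defaults the
atrial reference is reproduced within about 2 % in depth and width; the
ventricular reference is about +10 % deep and +20 % wide (see
Limitations), which trips the documented 5 % residual ceiling and flags
the calibration object accordingly.

## Verification

Every numerical stage has an independent oracle, sharing no code with
the path it checks (`verification_fixtures`):

* potential solve and power integral against the closed-form conductance
  `4 pi sigma a b / (b - a)` of a concentric-spheres shell on a polar
  mesh (1 %);
* implicit stepping against the linear steady slab profile and a
  single-step discrete enthalpy/flux balance (round-off);
* lesion metrics against closed-form hemisphere and half-ellipsoid
  isotherms and against a dense-voxel enumeration oracle on randomized
  smooth fields (1 % volume, 0.05 mm in D and W);
* a global per-run energy audit: delivered energy equals enthalpy change
  plus film, sink, boundary and dispersive-return losses to within 2 %.

What the synthetic fixtures do not exercise is as important: they are
smooth, single-peaked fields on clean rectangles, so passing them says
nothing about contact-edge singularities, the charring shell, or the
adequacy of the reduced cooling models — those are constrained only by
the study-level reproductions (standard lesion sizes after calibration,
held-out HPSD depths, the repeated-application volume gain, and the
factorial safety rates).

## Limitations

* **No hydrodynamics, no elasticity.** Saline jets, blood flow and
  tissue deformation enter only through the reduced models above. The
  power-law forms are this package's modeling choice; they are recorded
  in every run manifest and have no counterpart in the full CFD model
  they stand in for.
* **Ventricular standard lesion runs large.** The model reproduces the
  atrial standard reference to within a few percent but overshoots the
  ventricular one (about +10 % depth, +20 % width). The chambers differ
  only by wall thickness here, which is evidently not the whole story.
* **Chamber ordering of complication rates is inverted.** The reference
  study finds more complications in the thin-walled atrium than in the
  ventricle. In this model the thin-wall excess heating appears only
  when current is forced axially through the wall (the plate-contact
  return); any plate conductance strong enough to produce it also makes
  the calibrated standard and HPSD applications pop, so the shipped
  default keeps the bath return. Consequently the overall complication
  rate (within a point of the reference 79 %), the low-irrigation
  charring rate and the charring-onset timing (< 1 s) are reproduced,
  but the atrium/ventricle split is not — the corresponding check is
  expected to fail and is left failing deliberately.
* **Isotropic conduction**, a single catheter orientation
  (perpendicular), homogeneous tissue, and no impedance feedback are
  inherited simplifications of the scope.
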