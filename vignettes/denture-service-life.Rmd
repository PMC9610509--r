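---
title: "Stress and service-life analysis of removable complete denture bases"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stress and service-life analysis of removable complete denture bases}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A removable complete denture (RCD) for an edentulous mandible is a
horseshoe-shaped acrylic base carrying artificial tooth blocks, resting on
the mucosa of the alveolar ridge with no implant or clasp fixation. Its
typical failure mode is not single-overload fracture but fatigue: every
mastication cycle loads the base through the teeth, and stress
concentrations — at the midline, at technological cutouts for reinforcement
strands, at tooth/base transitions — slowly grow an opening-mode crack.
Where the artificial tooth blocks sit (displaced vestibulo-orally, or
inclined about their mesio-distal axis) changes those concentrations and
can shift the expected service life by orders of magnitude. This package
provides the computational side of that design question: generate a
parametric denture geometry, solve the elastic problem for per-block
occlusal loads, and map the stress field to cycles-to-failure and years of
service, so that arrangement variants can be compared before a denture is
made.

## Geometry: a parametric stand-in for a scanned denture

Real analyses start from a 3D scan of a patient's denture. No such scan
ships with this package; `generate_denture()` builds a parametric
mirror-symmetric substitute:

* an elliptical arch centerline swept with a cross-section carrying an
  alveolar-ridge saddle on the intaglio (tissue-facing) side and dropping
  to flange depth at the vestibular/oral edges;
* four tooth blocks per side — I incisors, II canines, III premolars,
  IV molars — as conforming prism columns bonded node-to-node to the base
  (ideal adhesion; the dentition is chemically bonded in practice, so no
  contact interface is modelled);
* labeled functional regions on the boundary: eight occlusal patches, four
  intaglio mucosa-contact segments per side, a peripheral border-seal
  band, two posterior retention ellipses, and the cutout faces.

"Technological cutouts for strands" are realized as element-removal
notches on the vestibular side of the upper base layers, one across the
anterior midline and one per side between blocks II and III. Their depth
and width are parameters; the re-entrant corners they create are the
stress raisers the analysis is interested in. The mesh is generated for
one side and mirrored about the midsagittal plane, so symmetry is exact by
construction; Freudenthal subdivision of the structured hex grid yields
conforming tetrahedra, quadratic (tet10) by default with a linear (tet4)
option for fast runs.

What the generator does **not** emulate: patient-specific intaglio relief,
cuspal occlusal anatomy, scanned thickness variation, or the maxillary
(torus-supported) geometry. Peak stresses on this smooth stand-in are
therefore lower than on a scanned denture at the same load, and all
life-related conclusions the tests verify are *directional* (orderings,
ratios, zone counts), not clinical magnitudes.

## Elastic model

Small-strain isotropic linear elasticity, static and isothermal, in a
consistent mm–N–MPa system. Default materials are the two denture
acrylics: base `E = 1000` MPa, tooth `E = 2000` MPa, Poisson ratio 0.3 for
both, density carried but unused. Tetrahedra are straight-sided, so the
tet10 map is affine; stiffness uses the 4-point degree-2 simplex rule
(exact here), and element strains are linear, evaluated at corners with
midedge values as endpoint averages. Nodal stresses are arithmetic
averages over adjacent elements; both the raw element maximum and the
smoother nodal-averaged maximum are reported, the nodal-averaged value
being the default headline number.

The mucosa is a Winkler elastic foundation: on each intaglio segment a
normal traction `k_n (u . n)` opposes the local normal displacement, with
an independent stiffness per segment (MPa/mm). The border seal adds a
weaker normal stiffness along the periphery; the retention zones act as
tangential springs, a linear stand-in for the friction-like forces of base
shrinkage (Coulomb friction is deliberately not modelled). An optional
compliance law `c(u_n) = c0 + c1 u_n` — soft tissue stiffening/softening
with displacement as blood is displaced from the contact zone — makes the
problem mildly nonlinear; it is solved by a secant fixed-point iteration
(solve, update `k = 1/c`, re-solve) capped at 5 passes. The default is the
pure linear model (`c1 = 0`), matching a single linear-elasticity solve.

Loads: a mastication event applies a total force `F0` (default 100 N, an
average jaw muscular compression force) to selected tooth blocks as a
vertical pressure `P_k = F0 / S_k`. On a curved occlusal surface the
pressure is weighted by the vertical projection `sin(beta)` of each facet,
so the integrated vertical force equals `F0` exactly whatever the surface
shape. "Symmetric" loading splits `F0` across both sides' blocks in
proportion to their projected areas (F0/2 per side for equal blocks);
"asymmetric" concentrates the full `F0` on one side. This convention keeps
the total force identical across cases, which is what makes
symmetric/asymmetric stress ratios meaningful.

## Balance calibration

The denture has no kinematic fixation, so an unbalanced foundation lets
the base pitch and roll as a quasi-rigid body, polluting the strain
analysis. `calibrate_foundation()` reproduces the standard balancing step:
under the uniform all-teeth load it adjusts the four per-segment stiffness
multipliers (applied to both sides, preserving symmetry) by Nelder-Mead on
the log-multipliers, bounded to 1e-2–1e2 times the initial values, until
`|pitch|` and `|roll|` fall below 0.01 degrees and the vertical
displacement range over the base stays within 0.02 mm. Rigid motion is
measured by a least-squares fit of `u = t + omega x x` over the base
nodes. The objective `pitch^2 + roll^2 + 100 max(0, range/target - 0.95)^2`
is deterministic (fixed solver ordering, fixed start at unit multipliers),
and a spec that already meets the tolerances is returned unchanged, making
calibration idempotent. Initial segment stiffnesses default to 3 MPa/mm —
a millimetre-scale mucosa layer of a few MPa modulus — with 1 MPa/mm on
the seal and 2 MPa/mm tangential in the retention zones; the calibration
targets, not these starting values, fix the final stiffnesses.

## Fatigue-life mapping

High-cycle durability follows a Basquin-type S–N curve,

\[ \sigma_{eq} = \sigma_f + \sigma_L N^{-\beta}, \]

anchored so that the curve passes through the yield point at $10^3$
cycles, which fixes the amplitude coefficient
$\sigma_L = 10^{3\beta} (\sigma_{0.2} - \sigma_f)$. Below the fatigue
limit $\sigma_f$ the life is capped at $N_{max} = 10^9$ cycles — beyond a
human lifetime of mastication — and classified non-hazardous; at or below
$10^3$ cycles a node is classified red (cracking within a thousand
maximum-effort cycles); everything between is intermediate.

Multi-axial stress states use the Smith–Watson–Topper criterion,

\[ \sqrt{\langle\sigma_1^{max}\rangle\,\Delta\sigma_1/2}
   = \tilde\sigma_u + \sigma_V N^{-\beta_{VH}}, \]

whose Macaulay bracket gates out compressive maximum principal stresses:
only tension drives an opening-mode crack. The grouping of the left side
(the square root over the product, i.e. the classic SWT stress) is a
documented interpretation choice, isolated in `swt_equivalent()` so an
alternative grouping is a one-function change. For a fully reversed cycle
of amplitude $s$ the SWT stress reduces to $s$, consistent with uniaxial
S–N calibration. The default cycle model is *pulsating* — the maximum
muscle effort is applied and fully removed each mastication event, so
$\Delta\sigma_1 = \sigma_1^{max}$ — with a fully-reversed option for
sensitivity studies.

Cycles convert to years through a mastication schedule: 3 meals per day
times 1000 chewing cycles per thorough mastication of a meal, i.e. about
$1.1\times10^6$ cycles per year, chosen so a one-year service life sits at
the $10^6$-cycle scale. Both numbers are parameters and are logged in
every report.

**Fatigue constants are placeholders.** Measured S–N constants for denture
acrylics are material- and process-specific and are not shipped. The
default set ties the yield point to the 60 MPa ultimate compressive
strength of the base acrylic, the fatigue limit to 40% of it (the level at
which gradual degradation of the acrylic sets in), and uses an exponent of
0.1; the SWT curve reuses the same triple. `fatigue_params()` flags this
set as a placeholder unless `confirmed = TRUE`, and every report records
the flag. One consequence at the default demonstration scale: the smooth
synthetic geometry keeps peak tensile stresses below the placeholder
endurance term, so life fields saturate at $N_{max}$ and variant
comparisons rank by stress and hazard-zone structure rather than by
finite life numbers. Supplying measured constants (or a sharper geometry)
produces finite life maps through exactly the same code path.

## Numerical choices

* Sparse symmetric Cholesky (CHOLMOD) with one iterative-refinement step;
  relative residual checked against 1e-8; fixed ordering for determinism.
  A factorization is computed once per scenario and reused across all
  load cases.
* Equilibrium is enforced per solve: foundation reactions must balance
  the applied load within 0.1% or the pipeline aborts naming the stage.
* Degenerate inputs: `ridge_height = 0` yields a valid flat-intaglio
  mesh; meshing failures (oversized footprints, too-coarse mesh for a
  block, self-intersecting sweep) raise errors naming the offending
  parameter; inverted elements are rejected by `validate_mesh()`.
* Mesh interchange: gmsh v2.2 `.msh` with physical groups is the
  label-preserving volume format; legacy VTK carries fields for
  visualization (normalized von Mises with 10% isoline levels as
  metadata); STL is surface-only and label loss is reported.
* Arrangement transforms blend linearly from zero at the tooth/base
  interface to full at the occlusal surface, keeping the bonded mesh
  conforming; the occlusal patch centroid therefore moves by exactly the
  requested displacement.
* The generator accepts a seed and records it; the current generator is
  fully deterministic (the seed is reserved for stochastic mesh jitter).

## Problem sizes

The default geometry (`mesh_size = 2.2` mm, quadratic elements) meshes to
roughly 8000 nodes / 4500 tet10 — fine enough to resolve all eight blocks,
the four intaglio segments per side and the notches, and small enough that
a full eight-case scenario, including foundation calibration, completes in
minutes on one CPU. The test suite mostly uses a coarse profile
(`mesh_size = 3`, linear elements, ~700 nodes) where solver-level
properties are resolution-independent; the directional stress orderings
across blocks are asserted at the default resolution, since very coarse
meshes can scramble the close anterior-block ordering. A convergence sweep
(patch tests exact at any resolution; cantilever and probe-point
Cauchy convergence) backs up the discretization.

## Known limitations

* The geometry is a smooth parametric stand-in; absolute stress and life
  values do not transfer to scanned patient geometries.
* Linear elasticity only: no plasticity, no Coulomb friction or contact
  separation, no thermal or moisture effects.
* No crack propagation or damage accumulation; the life map is a
  crack-initiation estimate under constant-amplitude maximum-effort
  cycles (a lower-bound style assumption: everyday mastication is
  gentler).
* Mandibular model only; the maxillary (torus-supported) variant would
  need its own foundation layout.
* Fatigue constants are placeholders pending material testing.
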