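# rcdlife

Finite-element stress and fatigue service-life analysis of removable
complete denture (RCD) bases.

## The problem

A removable complete denture for an edentulous mandible is an acrylic
horseshoe base carrying artificial tooth blocks (I incisors, II canines,
III premolars, IV molars per side), supported only by the mucosa of the
alveolar ridge. Its dominant failure mode is fatigue: each mastication
cycle loads the base through the teeth, and stress concentrations at the
midline, at the technological cutouts for reinforcement strands and at
tooth/base transitions slowly grow an opening-mode crack. Deviations of
the tooth arrangement from the normal occlusal scheme — vestibulo-oral
displacement or inclination of a block — amplify those concentrations and
can shorten the service life drastically. `rcdlife` is aimed at the
prosthodontic-design side of this problem: it quantifies how arrangement
variants change stress and predicted life *before* a denture is
manufactured.

## What the package computes

1. **Geometry.** `generate_denture()` builds a parametric,
   mirror-symmetric denture base (elliptical arch, ridge-saddle intaglio,
   bonded tooth prisms, strand cutouts) meshed into 4- or 10-node
   tetrahedra, with labeled patches: 8 occlusal blocks, 8 intaglio mucosa
   segments, border seal, 2 retention zones.
2. **Elasticity.** Small-strain isotropic linear elasticity
   (base E = 1000 MPa, teeth E = 2000 MPa, nu = 0.3) with a Winkler
   elastic-foundation mucosa model: normal stiffness per intaglio segment,
   seal stiffness along the periphery, tangential (friction-like) springs
   in the retention zones.
3. **Loads.** A load case applies a total force `F0` (default 100 N) to
   chosen blocks as an occlusal pressure `P_k = F0 / S_k`, projection-
   weighted so the integrated vertical force equals `F0` on any surface
   shape; symmetric, asymmetric and uniform-all-teeth cases.
4. **Balance calibration.** `calibrate_foundation()` tunes the per-segment
   stiffnesses until the uniform all-teeth case shows vanishing rigid-body
   pitch and roll (|angle| < 0.01 deg) and a vertical movement range
   within 0.02 mm.
5. **Fatigue life.** Nodewise mapping of the static maximum-effort stress
   field through the Basquin S–N curve
   `sigma_eq = sigma_f + sigma_L N^(-beta)` with
   `sigma_L = 10^(3 beta) (sigma_0.2 - sigma_f)` (yield point at 10^3
   cycles), and the Smith–Watson–Topper criterion
   `sqrt(<sigma1_max> Delta_sigma1 / 2) = sigma_u~ + sigma_V N^(-beta_VH)`
   (tension-gated, opening-mode cracking). Cycles convert to years via a
   mastication schedule (3 meals x 1000 chews per day by default). Nodes
   are classed red (N <= 10^3), intermediate, or non-hazardous
   (N >= 10^9).
6. **Scenario comparison.** `run_scenario()` and `compare_arrangements()`
   execute the canonical 8 load cases per arrangement variant (normal /
   displaced / inclined), rank variants by minimum predicted life and
   count disjoint hazard zones; `render_report()` writes VTK fields
   (normalized von Mises with 10% isolines), CSV max-stress tables and a
   JSON summary of every assumption.

## Worked example

```r
library(rcdlife)
params <- arch_parameters(mesh_size = 3, element_order = 1)  # coarse demo profile
mesh <- generate_denture(params)
print(mesh)
cal <- calibrate_foundation(mesh, material_set(), foundation_spec())
rep <- attr(cal, "report")
cat(sprintf("balance: pitch %.5f deg, roll %.5f deg, range %.4f mm\n",
            rep$after$pitch, rep$after$roll, rep$after$range_z))
sc <- scenario(params = params, foundation = cal, calibrate = FALSE)
res <- run_scenario(sc)
print(res$summary[, c("case", "pressure", "max_nodal_mises", "min_years")],
      digits = 3)
```

prints

```
<labeled_mesh> tet4: 674 nodes, 2040 elements, 1116 boundary facets
  materials: base (1512), tooth (528)
  patches: 21
balance: pitch -0.00012 deg, roll 0.00000 deg, range 0.0111 mm
      case pressure max_nodal_mises min_years
1    I_sym    1.131            2.26       913
2   I_asym    2.261            3.40       913
3   II_sym    3.393            3.46       913
4  II_asym    6.787            6.97       913
5  III_sym    1.698            2.05       913
6 III_asym    3.396            4.06       913
7   IV_sym    0.679            1.04       913
8  IV_asym    1.359            1.97       913
```

Reading this: after calibration the denture sits balanced (pitch and roll
are numerically zero, the whole base moves less than 0.02 mm under the
uniform 100 N bite). Per-block pressures span the physiological ~1–10 MPa
band — the canines (block II), with the smallest occlusal area, see the
highest pressure. Asymmetric (one-sided) loading roughly doubles the peak
von Mises stress of the matching symmetric case for every block. On this
smooth demonstration geometry all stresses stay below the (placeholder)
fatigue limit, so every node sits at the 10^9-cycle cap — 913 years at
3 x 1000 chews/day, i.e. "non-hazardous"; the default-resolution
quadratic mesh sharpens the concentrations at the cutouts, and supplying
measured acrylic fatigue constants to `fatigue_params()` turns the map
into finite lives through the same pipeline.

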