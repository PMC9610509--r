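Package: rcdlife
Title: Service-Life Analysis of Removable Complete Denture Bases by
    Finite-Element Stress and Fatigue Mapping
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to assess the mechanical durability of the acrylic base of
    a removable complete denture (RCD) for an edentulous mandible. The package
    generates parametric, mirror-symmetric horseshoe denture geometries with
    labeled functional regions (occlusal tooth blocks, segmented intaglio
    mucosa contact, border seal, posterior retention zones, technological
    cutouts), solves small-strain isotropic linear elasticity on 4- or
    10-node tetrahedra with Winkler elastic-foundation boundary terms,
    calibrates per-segment mucosal stiffnesses to null rigid-body pitch and
    roll under a uniform occlusal load, and maps the resulting stress fields
    to cycles-to-failure and years of service via a Basquin S-N curve
    anchored at the yield point and the Smith-Watson-Topper multi-axial
    criterion. Scenario comparison across tooth-arrangement variants
    (normal, displaced, inclined blocks) supports occlusal-scheme planning.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Matrix,
    stats,
    utils,
    tools,
    yaml,
    jsonlite,
    igraph
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
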