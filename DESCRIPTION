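Package: hullprof
Title: Intrinsic Density Profiles of Molecular Aggregates via Convex-Hull
    and Alpha-Shape Interfaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Characterizes the interface of arbitrarily shaped molecular
    aggregates (spherical, elongated, bent, hollow) in molecular dynamics
    trajectories. Builds a per-frame convex hull or three-dimensional
    alpha shape over a selected set of structure atoms, computes signed
    distances from points to the triangulated interface, and derives
    intrinsic number-density profiles, interface volume and surface area,
    counts of solubilized molecules, and periodic-boundary-aware cluster
    identification and centering. Includes readers and writers for GRO,
    PDB and XYZ trajectories, a compact atom-selection language, and
    deterministic synthetic point-assembly generators (lattice-filled
    sphere, cylinder, bent rod, hollow shell, solvent bath) for
    validation against assemblies of known density and volume.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    graphics,
    utils,
    tools,
    parallel
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
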