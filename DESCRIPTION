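Package: aquaopes
Title: Enhanced Sampling, Unbinding Kinetics and Trapped-Water Analysis at Desk Scale
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A desk-scale toolkit for the methods used in modern
    ligand-unbinding studies: on-the-fly probability enhanced sampling (OPES)
    with a well-tempered kernel bias, its flooding variant for physical
    residence times via hyperdynamics time rescaling, machine-learned
    collective variables (linear discriminant and time-lagged independent
    component analysis, plus their neural-network extensions), a convex-hull /
    residence-filter / k-means pipeline for locating long-lived hydration
    spots, and funnel-corrected absolute binding free energies with
    multi-temperature enthalpy-entropy decomposition. Ships analytic toy
    potentials, an overdamped Langevin integrator and seeded synthetic-data
    generators so that every stage can be exercised and validated without
    access to large molecular-dynamics trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    stats,
    utils,
    grDevices,
    jsonlite,
    yaml,
    MASS,
    bio3d
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
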