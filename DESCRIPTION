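Package: assemblyyield
Title: Equilibrium Self-Assembly Yields of Rigid Heterogeneous Clusters
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Predicts equilibrium self-assembly yields for clusters built from
    rigid heterogeneous building blocks (spheres plus typed interaction
    patches). Per-cluster configurational partition functions are computed by
    Laplace's approximation around the energy minimum using closed-form
    analytic Hessians, with the rotational contribution obtained either by
    Monte Carlo integration of the coordinate-change Jacobian over uniformly
    sampled orientations or, for isotropic blocks, from the moments of
    inertia. Yields follow from a self-consistent grand-canonical mass-action
    solve or from exact canonical enumeration for small closed systems.
    Includes builders for coarse-grained protein complexes from PDB files with
    contact-derived patches, a chiral patchy-particle dimer system, an exactly
    solvable spherical dimer, and icosahedral 60-sphere cages with random
    growth paths.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tibble,
    dplyr,
    rlang,
    ggplot2,
    generics,
    yaml,
    bio3d
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
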