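Package: fmnet
Title: Fluctuation-Matched Heterogeneous Elastic Networks for Filament Lattices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Parameterizes heterogeneous elastic networks for coarse-grained
    lattice assemblies by iterative fluctuation matching: contacts are extracted
    from a reference structure within a distance window, spring constants are
    initialized inversely proportional to per-pair distance variances, and an
    iterative update matches coarse-grained distance fluctuations to reference
    (all-atom) targets. Also builds helical multi-protofilament filament
    lattices (e.g. 14-protofilament microtubules) from a dimer unit, computes
    per-pair distance statistics from trajectories, infers mechanical
    properties (Young's modulus from axial stress-strain, flexural rigidity
    from tip-load bending via Euler-Bernoulli beam theory, cross-section
    geometry from radial density inflection points), and provides structural
    observables (residue contacts and their survival times, helix and
    protofilament angles, dimer-separation correlations, radial ion densities).
    A built-in overdamped Brownian-dynamics bead-spring simulator closes the
    optimize-simulate-analyze loop without an external molecular dynamics
    engine.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
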