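Package: allodyn
Title: Allosteric Coordination, Non-Equilibrium Response and Energetic
    Coupling Analysis of Molecular-Dynamics Ensembles
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Trajectory-ensemble analytics for chaperone-client and other
    large protein complexes: residue-pair distance-fluctuation (DF) matrices
    with block averaging and quantized views to map allosteric coordination;
    dynamical non-equilibrium MD (D-NEMD) Kubo-Onsager subtraction to
    quantify per-residue responses to a perturbation; spectral analysis of
    residue-pair interaction-energy matrices (MLCE) to extract folding cores
    and weakly coupled soft spots; ensemble descriptors (RMSD, RMSF) and
    conformational-family clustering with silhouette-based model selection.
    Includes a seed-deterministic elastic-network-style synthetic-ensemble
    generator with known ground truth, so every stage is testable without
    microsecond trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    cluster,
    stats,
    tools,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
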