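Package: domainpath
Title: Smoothest-Path Analysis of Multi-Domain Protein Motions on
    Pose-Grid Energy Landscapes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to study large-scale rigid-body motions between protein
    domains, such as the release of a kinase domain from an autoinhibitory
    cavity.  Generates separation-by-rotation pose grids of a mobile domain
    about an anchor domain in the plane spanned by three domain mass
    centers, assembles total-energy matrices over the grid (from a built-in
    screened-Coulomb plus Lennard-Jones scorer, from synthetic landscape
    generators, or imported from external minimization runs), and finds the
    energetically smoothest activation path: the grid path minimizing the
    variance of per-step energy changes, solved exactly by a minimum-variance
    reformulation of Dijkstra's algorithm on the layered pose graph.  Also
    provides the accompanying trajectory statistics: RMSD with optional
    least-squares superposition, RMSF about the time-average structure, and
    hydrogen-bond occupancy under distance/angle criteria, for multi-model
    PDB trajectories.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    bio3d,
    jsonlite,
    stats,
    utils,
    graphics,
    grDevices
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
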