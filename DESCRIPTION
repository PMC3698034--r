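Package: lsbuild
Title: Molecular Distance Geometry from Sparse, Inaccurate Interval Distance Bounds
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Solves the molecular distance geometry problem (MDGP) with sparse
    and inaccurate data of the kind produced by NMR experiments: interval
    bounds l <= ||x_i - x_j|| <= u on a subset of inter-atomic distances.
    Implements the lsbuild algorithm (maximum-clique base selection, rank-3
    Gram embedding of a distance matrix sampled inside the bounds, linear
    least-squares point placement, and local refinement by a hyperbolic
    smoothing penalty minimised with limited-memory BFGS) together with the
    modified geometric buildup baseline, instance generators emulating two
    experimental protocols, and solution-quality metrics (LDME and optimal
    superposition RMSD over the full orthogonal group).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
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
    utils,
    withr
Suggests:
    igraph,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
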