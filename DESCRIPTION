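Package: capsidprof
Title: Structure-Based Conservation Models for Spherical Viral Capsids
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes per-residue structural conservation profiles for
    icosahedral viral capsids from Calpha coordinates: the cutoff-free
    weighted contact number (packing density) profile and the
    centroid-distance (radial) profile, both evaluated in the context of
    the whole capsid assembly. Reads PDB and mmCIF files, expands
    biological assemblies from stored or user-supplied symmetry
    operators, ingests Rate4Site/ConSurf site-specific conservation
    scores, and compares structural and conservation profiles via
    z-normalization, sliding-window smoothing, Pearson correlation and a
    binned conservation-trend analysis. Includes a synthetic capsid and
    conservation generator with known ground truth, colored-structure
    export for molecular viewers, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    optparse,
    purrr,
    readr,
    rlang,
    seqinr,
    stats,
    tibble,
    tidyr,
    tools,
    utils,
    yaml,
    zoo
Suggests: testthat (>= 3.0.0), withr
Config/testthat/edition: 3
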