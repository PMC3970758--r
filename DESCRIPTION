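Package: ringgeom
Title: Geometry of Hexameric Helicase Rings Bound to Single-Stranded DNA
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Geometric analysis of ring-shaped (pseudo-symmetric) protein
    assemblies and the single-stranded DNA they enclose, motivated by
    hexameric MCM helicase N-terminal domain structures. Provides
    deviation-from-cyclic-symmetry RMSD via optimal rigid-body
    superposition onto the one-step subunit permutation, channel-axis
    fitting and per-slice minimum channel radius profiles, probe-distance
    classification of subunit interfaces as DNA-engaged or disengaged,
    polarity/planarity/stretch analysis of a nucleic-acid path around the
    channel, Hill-model fitting of electrophoretic mobility shift
    titrations, and deterministic synthetic-assembly generators with
    ground truth for validation. All user-facing functions take and
    return tidy data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    bio3d,
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    minpack.lm,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
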