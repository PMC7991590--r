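Package: dmsites
Title: Functional and Buried Site Prediction from Deep Mutational Scanning Data
Version: 0.1.0
Authors@R:
    person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Predicts active-site, buried, and exposed non-active-site
    residues of a protein by combining per-position mutational sensitivity
    from deep mutational scanning (DMS) experiments with per-residue
    relative side-chain solvent accessibility, either calculated from
    structure (NACCESS) or predicted from sequence (PROF, NetSurfP,
    SPIDER3 and similar tools). Raw mutational effect scores are rescaled
    to [-1, 0] using distribution-derived anchors (5th percentile and the
    wild-type peak), averaged per position with a minimum-mutant filter,
    standardized, and combined with standardized accessibility into
    additive (active-site) and subtractive (buried) Z-scores thresholded
    one standard deviation from the mean. Includes confusion-matrix
    evaluation (sensitivity, specificity, accuracy, MCC), cross-dataset
    summaries, and a seeded synthetic-data generator emulating the
    substitution-preference structure of real saturation mutagenesis
    experiments so the whole pipeline can be exercised without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
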