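Package: stressdom
Title: Community Assembly Inference Along Stress Gradients from Phylogenetic and Phenotypic Structure
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to infer community assembly mechanisms (abiotic filtering,
    limiting similarity, hierarchical competition, neutrality) along
    environmental stress gradients from presence/absence communities, a dated
    phylogeny and species functional traits. Implements phylogenetic-signal
    tests (independent contrasts and Fitch parsimony change counts against
    tip-shuffling nulls), mean pairwise phylogenetic and phenotypic distances
    (MPD/PW) with regional-pool null models and standardized effect sizes
    including shape-corrected variants, functional dendrograms from
    generalized Gower distances and UPGMA, BLADJ-style node-age interpolation,
    phylobetadiversity with distance decay, the Thornthwaite-Mather monthly
    climatic water balance (including a simplified arid-climate variant),
    PCA with broken-stick axis retention, and a synthetic-data generator that
    assembles communities under known mechanisms for calibration and power
    analysis.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    vegan,
    geosphere,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    picante,
    phangorn,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
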