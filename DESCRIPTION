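Package: chromins
Title: Chromatin Insulator Networks, Aggregate Hi-C Statistics, and
    Multiplexed Imaging Trace Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools to quantify the role of insulator-bound chromatin in 3D
    genome folding. Builds chromatin-interaction networks from loop calls on
    binned contact maps and computes chromatin assortativity (ChAs,
    cross-ChAs, AND-ChAs) with distance-preserving randomization Z-scores;
    performs distance normalization (observed/expected), aggregate peak
    analysis with quintile stratification and anchor bootstraps, insulation
    score boundary calling, and loop/border classification; and analyzes
    multiplexed DNA-FISH chromatin traces (pairwise-distance ensembles,
    proximity maps at a distance cutoff, imaging insulation scores and
    domainograms, distance-matched control sets, and multiway proximity
    clusters against an independence null). A synthetic-data generator with
    known ground truth (power-law contact decay with planted domains and
    loops, graded peak tracks, polymer-like traces with planted
    colocalization and detection dropout) supports end-to-end recovery
    testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    graphics,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    withr
Config/testthat/edition: 3
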