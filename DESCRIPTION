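Package: ruggedpaths
Title: Roughness and Evolutionary Path Predictability of Fitness Landscapes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying the ruggedness of combinatorial
    genotype-fitness landscapes and the predictability of evolutionary
    trajectories across them.  Implements four roughness statistics
    (deviation from additivity under a peak-anchored additive model, local
    roughness, peak fraction, and mean distance to the tree component), the
    fraction of fitness-monotonic mutational paths to the main peak, and
    mean path divergence of trajectory bundles.  Evolutionary trajectories
    are sampled under diploid Kimura fixation dynamics in the low
    mutation-rate limit, from the neutral random-walk limit to the
    strong-selection limit.  Includes permutation (scrambled-landscape)
    null models with Z-scores, a generator of additive landscapes perturbed
    by tunable noise, and a coarse-grained off-lattice heteropolymer
    folding simulator in which fitness is derived from the probability of
    folding to a native structure ensemble via a misfolding-cost model.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
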