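Package: ddscore
Title: Distance-Dependent Statistical Potentials for Protein Model Quality Assessment
Version: 0.1.0
Authors@R: person("ddscore", "maintainers", email = "ddscore@example.org", role = c("aut", "cre"))
Description: Trains and applies knowledge-based, distance-dependent scoring
    functions for protein structure models. Structures are projected onto one
    of ten representations (C-alpha, C-beta, backbone, side-chains, all-atom,
    or MARTINI-style coarse-grained beads); conditional and reference distance
    distributions are estimated by Gaussian kernel density estimation and
    scored with either a potential-of-mean-force (negative log-likelihood
    ratio) or a total-information-gain (relative difference) formalism.
    Includes a Kabsch/TM-score similarity module, a decoy-set benchmark
    (pairwise ranking accuracy, per-target correlations, rank statistics,
    Wilcoxon comparisons), seeded synthetic structure generators for offline
    testing, and a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
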