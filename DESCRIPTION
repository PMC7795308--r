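Package: sdbn
Title: Deep Belief Network Reweighting of Molecular Fingerprints for Similarity Searching
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Ligand-based virtual screening with multi-descriptor fingerprint
    fusion. Trains stacked restricted Boltzmann machines (a deep belief
    network) on folded 2D fingerprints, scores features by reconstruction
    error, removes outlier features iteratively, selects re-constructible
    features via principal component analysis of the error matrix, fuses the
    selections from several descriptors into a combined representation, and
    ranks databases by binary or continuous Tanimoto similarity. Includes the
    full recall-at-n-percent evaluation protocol with Kendall coefficient of
    concordance, and a synthetic fingerprint generator with planted
    class-signal, background-noise and outlier features for end-to-end
    benchmarking without licensed structure databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
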