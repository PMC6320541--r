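Package: formdiv
Title: Diversity Partitioning of Fossil Metacommunities at the Formation Scale
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to partition the species diversity of fossil occurrence data
    into alpha (within-collection), beta (between-collection) and gamma
    (whole-formation) components, treating geological formations as
    metacommunities. Reads Paleobiology Database style occurrence tables,
    applies reproducible vetting rules, estimates diversity by repeated
    fixed-size subsampling of collections, computes Whittaker's beta and the
    multiple-site Simpson dissimilarity, fits alpha-gamma and beta-gamma
    trajectories per geological period, and tests the strength of beta-gamma
    coupling against a randomization null model. Includes a synthetic
    metacommunity generator with controllable habitat fidelity, patchy
    occupancy and time-averaging so the whole pipeline can be exercised and
    validated without any database download.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    geosphere,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    vegan,
    withr
Config/testthat/edition: 3
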