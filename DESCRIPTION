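Package: coopnet
Title: Signed Co-Occurrence Network Analysis of Free Word Associations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Extracts shared mental representations from free word association
    surveys. Every pair of associations is scored by a signed log-likelihood
    ratio (G) statistic against independence, giving a network with attractive
    and repulsive edges; modules are found by maximizing a signed extension of
    modularity with a Louvain optimizer stabilized by consensus clustering.
    Participants are linked to modules by plurality of their associations, and
    module profiles (emotion label distributions, substance/behavior
    composition, problem-intensity splits) are compared with chi-square,
    Kruskal-Wallis, and Dunn pairwise tests. Includes a synthetic survey
    generator with planted module structure for validation, GraphML/edge-list
    export, and ggplot2 visualization helpers.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    igraph,
    jsonlite,
    mclust,
    purrr,
    readr,
    rlang,
    stats,
    stringi,
    stringr,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
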