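Package: gutdiet
Title: Gut-Content Diet Composition, Niche Breadth, Overlap and Feeding Strategy
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative gut-content (stomach/foregut) diet analysis
    of fish and other predators: validation and filtering of individual-level
    diet records, the prey-importance triplet (frequency of occurrence F,
    relative abundance A, prey-specific abundance P), Levins' dietary niche
    breadth, Schoener's pairwise diet-overlap index, and the modified Costello
    (Amundsen) feeding-strategy diagram. Includes a synthetic gut-content
    generator (per-prey occupancy, conditional log-normal prey weights,
    phenotype mixtures) so every pipeline stage can be exercised and its
    estimators checked against known generative parameters.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
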