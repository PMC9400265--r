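Package: usevalue
Title: Quantitative Ethnobotany Indices and Availability-Hypothesis Tests
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantitative ethnobotanical surveys of wild useful
    plants: validated long-format interview data with controlled use-category
    and organ vocabularies; the standard citation-based indices (species and
    per-category use values, citation frequency, index value of organ, index
    of commercial value); vegetation-plot density estimation; tie-aware
    nonparametric tests of the resource availability hypothesis (group-level
    Spearman correlation of use value against local abundance) and of
    cross-cultural variation (Kruskal-Wallis on per-informant use values);
    PCA ordination of group-by-category use matrices; and a seeded synthetic
    survey generator with a tunable abundance-to-use coupling for power and
    type-I studies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
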