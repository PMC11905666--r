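Package: p4anon
Title: Partition-Parallel Anonymization of Tabular Health Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: An anonymization engine for tabular microdata built around
    full-domain generalization hierarchies, record suppression, and a suite
    of syntactic privacy models (k-anonymity, three flavours of l-diversity,
    t-closeness with equal and ordered ground distance, delta-disclosure
    privacy, basic and enhanced beta-likeness, average re-identification
    risk and sample uniqueness).  Datasets are anonymized either directly,
    by exhaustive search of the generalization lattice for the
    fidelity-optimal valid transformation, or through a four-step
    partition-based procedure that anonymizes disjoint partitions
    independently (and in parallel), harmonizes the per-partition
    generalization schemes, re-checks equivalence classes that coincide
    after merging against non-monotonic privacy models, and merges the
    result.  Utility is measured as domain-coverage data fidelity.  A
    synthetic-data module generates datasets and hierarchies for testing
    and benchmarking.
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
    parallel,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    boot,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
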