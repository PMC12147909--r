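Package: clonotrace
Title: T Cell Receptor Repertoire Diversity, Clonal Dynamics, and Outcome Association
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing bulk T cell receptor (TCR) repertoires from
    clone tables: AIRR Rearrangement and MiXCR-style readers with read-count
    and productivity filtering, normalized Shannon diversity and clonal
    expansion statistics, longitudinal clone-persistence tracking with an
    exact-binomial random-sharing null, blood-tumor compartment overlap
    analysis, simplified CDR3 motif specificity grouping with reference-based
    antigen annotation, and survival association of repertoire statistics.
    Includes a synthetic repertoire generator so every stage of the pipeline
    can be exercised and validated without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    tibble,
    dplyr,
    tidyr,
    purrr,
    rlang,
    readr,
    stats,
    utils,
    tools,
    survival,
    ggplot2,
    generics,
    jsonlite
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
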