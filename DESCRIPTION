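Package: oquare
Title: Structural Quality Metrics and Evolution Analysis for OWL Ontologies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Computes the fourteen OQuaRE structural quality metrics on OWL
    ontologies (RDF/XML or Turtle), discretises raw metric values to 1-5
    quality scores with the fixed OQuaRE static scale or with a corpus-fitted
    dynamic scale (exact one-dimensional k-means), aggregates scores into
    subcharacteristic and characteristic quality reports, and quantifies the
    evolution of a versioned ontology corpus through change-in-scale
    statistics, Wilcoxon ranking of consecutive version pairs, and principal
    component analysis of quality change against class-level editing
    activity. Includes a seeded synthetic ontology generator and version
    mutator so the full pipeline can be exercised without external downloads.
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
    jsonlite,
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    xml2,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
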