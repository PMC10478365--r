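Package: comorank
Title: Multi-Criteria Prioritization of Comorbidity Candidate Genes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds the intersection ("complete") gene network of two
    comorbid diseases from typed gene/protein association networks,
    computes ten ranking criteria for the shared genes (external
    prioritizer scores, participation in enriched Gene Ontology
    biological processes, network centralities, a Welch-test statistic of
    specificity for disease-shared processes, and binary criteria based
    on brain-eQTL SNPs with common minor alleles), and aggregates them by
    average rank into a candidate-gene priority table. Includes a
    synthetic study generator with planted driver genes for end-to-end
    validation, ggplot2 visualisations, and tidy()/glance() methods.
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
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    knitr,
    rmarkdown,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
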