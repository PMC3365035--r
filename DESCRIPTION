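Package: phyloerosion
Title: Erosion of Evolutionary History Under Pulse and Press Mass
    Extinctions in Digital Communities
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Individual-based simulation of communities of asexual digital
    replicators competing for a cascade of depletable cross-feeding resources,
    subjected to instantaneous random mass culls ("pulse" extinctions) and
    prolonged resource-restriction episodes ("press" extinctions).  Genotype
    genealogies are pruned to ultrametric phylogenies of extant genotypes, and
    the loss of evolutionary history is quantified through root-age shifts,
    temporally binned node retention, the Pybus-Harvey gamma statistic, and
    noncumulative stemminess, with ANOVA/Tukey and Kruskal-Wallis treatment
    comparisons and compact letter displays.
License: MIT
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
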