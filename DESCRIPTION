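Package: clonaldyn
Title: Clonal Dynamics and Somatic Evolution of Mouse Haematopoiesis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulation and inference tools for clonal dynamics of mouse
    haematopoietic stem and progenitor cells from single-cell-derived colony
    phylogenies and deep duplex sequencing. Includes a birth-death population
    simulator with genealogy sampling, somatic-variant and colony quality
    control filters, phylogeny construction and molecular-time clade
    analytics, a three-state (EMB/HSC/MPP) hidden Markov tree model of stem
    cell ontogeny, coalescent skyline and approximate Bayesian computation
    estimators of stem cell population size and division rate, a
    branching-process fitness-landscape estimator for clonal haematopoiesis
    variant allele fraction spectra, and mutational-signature attribution.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ape,
    lme4,
    Rcpp,
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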