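Package: crossmap3d
Title: Comparative Analysis of Chromatin Contacts, Domains, and
    Expression Across Two Species
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for orthology-aware comparison of Hi-C chromatin
    contact maps between two genome assemblies: reciprocal-best-hit
    interval mapping, distance-decay contact calling with a cumulative
    binomial test, cross-sample cyclic loess normalization, per-contact
    linear modeling of species, sex and batch effects with
    false-discovery-rate control, TAD and boundary conservation scoring,
    integration with gene expression (chi-squared enrichment sweeps,
    contact-expression correlation, mediation analysis with Monte Carlo
    confidence intervals), and weighted chromatin-state assignment of
    contact loci. Includes a synthetic two-species study generator with
    planted ground truth for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    grDevices,
    IRanges,
    S4Vectors,
    limma
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
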