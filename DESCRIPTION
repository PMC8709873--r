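Package: famseg
Title: Familial Aggregation and Rare-Variant Segregation in Extended Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for the genetic-analysis arm of extended high-risk family
    studies: ascertainment of high-risk families by observed versus expected
    affected counts under stratified population rates (standardized incidence
    ratio with an exact Poisson test), prioritization of rare functional
    variants by explicit filter rules on impact severity and SIFT/PolyPhen
    annotations, and estimation of the nominal probability that distantly
    related affected carriers share a rare variant by chance, decomposing
    chance sharing into single-founder transmission across meioses versus
    independent introduction by marry-in spouses. Includes an exact pedigree
    peeling engine, a gene-dropping Monte Carlo simulator serving as an
    independent oracle, and a synthetic multi-generation pedigree generator
    so every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), withr, vcfR, optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
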