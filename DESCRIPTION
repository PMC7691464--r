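Package: oakqg
Title: Quantitative Genetics of Contemporary Selection in Mixed Oak Stands
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: In-situ quantitative-genetic analysis of contemporary selection
    in a mapped two-species oak stand: spatially explicit synthetic stand
    generation, genomic (VanRaden) and pedigree relatedness matrices,
    competition/environment/spatial (PCNM) covariates, parentage- and
    mating-model-based fitness estimation, Lande-Arnold phenotypic selection
    gradients, REML animal models for genetic (co)variances with relative
    fitness (secondary theorem of selection), and predicted versus observed
    inter-generational responses.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ape,
    pracma,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    vegan,
    jsonlite
Config/testthat/edition: 3
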