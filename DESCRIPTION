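Package: famqtl
Title: Family Prioritization for Rare-Variant Discovery in Extended Pedigrees
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for a family-based strategy to discover rare variants with
    large effects on quantitative traits. An oligogenic segregation analysis
    (reversible-jump MCMC over the number of quantitative trait loci) is run on
    each extended family to find families likely to harbor excess trait loci;
    those families are followed up with variance-components linkage at gene
    positions with fully informative identity-by-descent sharing, rare variants
    in linked regions are filtered by founder entry and copy count, and
    candidate variants are tested by measured-genotype association with
    attribution of the linkage signal. Includes a synthetic-data generator that
    emulates extended-family exome studies, pedigree kinship computation, and
    PED/VCF input and output.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
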