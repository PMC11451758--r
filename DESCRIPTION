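Package: vqtlgxg
Title: Variance-QTL Based Discovery of Gene-Gene Interactions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for discovering gene-gene (GxG) interactions in quantitative
    and binary traits by prioritizing variance quantitative trait loci (vQTLs).
    Implements the squared-residual variance association scan on rank inverse
    normal transformed phenotypes, double generalized linear model dispersion
    testing for candidate genes, SNP-by-SNP interaction models for quantitative
    traits and disease outcomes with stratified effect estimates, EM-based
    pairwise linkage disequilibrium statistics for disambiguating cis epistasis,
    and non-central chi-squared power analysis for interaction tests. Includes a
    seeded synthetic-cohort generator emulating the statistical structure of
    biobank blood-trait data, simple VCF/TSV genotype input and output, and a
    config-driven pipeline running the full analysis end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    withr,
    jsonlite,
    yaml,
    vcfR
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
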