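Package: wheatmt
Title: Multi-Trait Association Mapping and Pleiotropy Versus Close Linkage
    Analysis for Wheat Yield Syndrome
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for dissecting the pleiotropic architecture of correlated
    quantitative traits in inbred crop panels. Implements a two-stage
    phenotypic analysis for multi-environment alpha-lattice trials (per
    environment and across-environment best linear unbiased estimators,
    variance components, plot- and entry-mean heritabilities), kinship from
    Rogers' distances, linkage-disequilibrium summaries including the
    effective number of independent markers (M_eff), a restricted maximum
    likelihood engine for multivariate mixed models with Kronecker-structured
    genetic (G0 x A) and residual (R0 x I) covariance, bivariate genome-wide
    association scans with Wald test hierarchies and multiple-testing
    corrections, a two-dimensional likelihood-ratio scan that contrasts
    pleiotropy with close linkage inside LD windows, and a simulation suite
    for quantifying the power and Type I error of that test across minor
    allele frequency, QTL size, and LD levels. Synthetic genotype and
    phenotype generators make the whole pipeline testable without external
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    lme4,
    stats,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
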