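Package: phenosim
Title: Phenotype Simulation and Power Analysis for Genetic Association Studies
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates quantitative, binary, count, ordinal and multivariate
    phenotypes conditional on real or synthetic genotypes under generalized
    linear models, proportional-odds ordinal models, Kronecker-structured
    variance-component models and generalized linear mixed models, and
    estimates the statistical power of likelihood-ratio association tests by
    Monte Carlo simulation. Includes a PLINK 1.9 binary fileset reader and
    writer built on a packed 2-bit genotype representation, genetic
    relationship matrix (GRM) estimation with Hardy-Weinberg mode imputation
    of missing genotypes, synthetic genotype generators for unrelated samples
    and sibships via gene dropping, maximum-likelihood fitters for ordinal and
    univariate variance-component models, and a command-line interface driven
    by declarative YAML configuration files.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    MASS,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
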