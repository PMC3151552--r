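Package: twinfactor
Title: Longitudinal Latent-Factor Genetic Association in Twin-Family Data
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Tools for genetic association analysis of repeatedly measured
    phenotypes in twin-family samples. A single latent factor captures the
    stability of a trait (such as anxious depression) across measurement
    occasions and raters; SNP effects are modeled on the latent factor with
    sex-specific coefficients, and familial resemblance is expressed through
    latent-factor correlations between relatives. Estimation uses full
    information maximum likelihood on raw family data with arbitrary
    missingness. The package includes a synthetic twin-family cohort
    generator with Mendelian genotype transmission, rank-based normal-scores
    phenotype transformation, genotype quality control (minor allele
    frequency, Hardy-Weinberg tests, Mendelian error checks), per-SNP
    likelihood-ratio association tests with between/within-family
    stratification and recessive re-analyses, Satorra-Saris noncentrality
    power analysis for multivariate versus univariate designs, and
    correlation-based heritability estimation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports: stats, utils, jsonlite
Suggests: testthat (>= 3.0.0), VariantAnnotation
Config/testthat/edition: 3
RoxygenNote: 7.3.3
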