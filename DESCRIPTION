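Package: mrtriad
Title: Univariable, Multivariable and Mediation Mendelian Randomization
    from GWAS Summary Statistics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A three-step Mendelian randomization (MR) toolchain driven
    entirely by GWAS summary statistics: instrument selection
    (genome-wide significance filtering, greedy LD clumping, LD-proxy
    substitution, R-squared and F-statistic diagnostics), harmonization
    of exposure and outcome effects onto shared effect alleles with
    palindromic-SNP handling, univariable two-sample estimators (Wald
    ratio, inverse-variance weighted, MR-Egger, weighted median) with a
    triangulation significance rule, a sensitivity battery (Cochran Q,
    Egger intercept, MR-PRESSO global and outlier tests, leave-one-out),
    multivariable MR with a multivariable Egger extension, and two-step
    mediation MR with product-of-coefficients mediated-proportion
    estimation. A seeded synthetic summary-statistic generator emulates
    causal effects, pleiotropy, LD blocks and mediation triangles so the
    whole chain is testable without external downloads.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports: methods, stats, utils, jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'AllClasses.R'
    'AllGenerics.R'
    'estimators.R'
    'instruments.R'
    'summary-stats.R'
    'mvmr.R'
    'mediation.R'
    'mrtriad-package.R'
    'sensitivity.R'
    'pipeline.R'
    'synthetic.R'
    'utils-internal.R'
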