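Package: vitdmr
Title: One-Sample Mendelian Randomization of Vitamin D Status and
    Cardiometabolic Disease
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for one-sample Mendelian randomization analyses of serum
    25-hydroxyvitamin D against metabolic syndrome, type 2 diabetes and
    abnormal blood pressure, built around genetic risk score instruments from
    four vitamin-D pathway SNPs. Provides a synthetic individual-level cohort
    generator with Hardy-Weinberg genotypes, a shared latent confounder and
    logistic outcome models; phenotype derivation (metabolic syndrome
    components, HOMA-IR, vitamin-D clinical categories and quintiles);
    instrument diagnostics (allele frequencies, Hardy-Weinberg tests,
    Cragg-Donald F statistics); causal estimators (per-SNP Wald ratios,
    fixed-effect inverse-variance weighted pooling, MR-Egger pleiotropy
    regression, Wald-type genetic risk score estimator and a two-stage
    regression estimator); observational quintile and trend analyses; and an
    end-to-end reproducible pipeline with CSV/YAML/JSON interfaces.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    metafor
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
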