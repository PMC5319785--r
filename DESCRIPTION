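Package: rhtn
Title: EHR Phenotyping, Case-Control GWAS, and Power Analysis for
    Resistant Hypertension
Version: 0.1.0
Authors@R:
    person("rhtn", "Maintainers", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Tools for electronic-health-record (EHR) based genetic studies of
    resistant hypertension. Implements a rule-based temporal phenotyping engine
    that classifies longitudinal patient records into resistant-hypertension
    cases (controlled and uncontrolled algorithms), controlled-hypertensive
    controls, exclusions, or unclassified, driven by antihypertensive
    medication-class concurrency, blood-pressure criteria, and laboratory/code
    exclusions (MDRD eGFR, ejection fraction, ICD-9-CM prefixes). Provides a
    case-control GWAS engine (call-rate/MAF/Hardy-Weinberg QC, ancestry
    principal components, case-only stratum removal, additive-model logistic
    association, genomic-control lambda, Manhattan/QQ tables, known-variant
    look-up), a CaTS-style analytic power calculator with prevalence-aware
    penetrance calibration and a minimum-detectable-odds-ratio solver, and a
    synthetic-data generator that plants phenotype labels and per-allele
    genetic effects so the full pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    VariantAnnotation
Config/testthat/edition: 3
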