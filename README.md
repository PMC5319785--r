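# rhtn

EHR phenotyping, case-control GWAS, and power analysis for resistant
hypertension.

## The problem

Resistant hypertension — blood pressure that stays above 140/90 mm Hg despite
three concurrent antihypertensive medication classes, or that requires four or
more classes to control — is common, clinically consequential, and hard to
study genetically because no registry records it directly. It has to be
*computed* from longitudinal electronic health records: blood-pressure
trajectories before and after treatment, medication-class concurrency inferred
from refill overlap and medication-list co-mentions, and laboratory/diagnosis
exclusions for mimics (advanced chronic kidney disease, systolic heart
failure, pathologic adrenergic states).

`rhtn` is for biostatisticians and informaticians who want that computation as
a tested, reusable pipeline rather than site-specific SQL: a rule-based
temporal phenotyping engine, a case-control association engine with ancestry
adjustment, a prevalence-aware genetic power calculator, and a synthetic-data
generator that plants ground truth so every stage is testable end to end
without access to any protected data.

## What it computes

**Phenotyping.** Each patient record is classified as
`CASE_CONTROLLED` (≥4 concurrent antihypertensive classes),
`CASE_UNCONTROLLED` (≥3 concurrent classes plus SBP >140 or DBP >90 mm Hg at
least one month after meeting the medication criteria), `CONTROL`
(hypertensive, never more than one simultaneous class, all BP <135/<90 mm Hg
from one month after first treatment), `EXCLUDED` (eGFR ≤30 ml/min by the
4-variable MDRD equation, EF ≤35%, or an excluded ICD-9-CM prefix), or
`UNCLASSIFIED` — with a full rule trace per patient. Concurrency uses 13
medication classes; direct alpha antagonists are deliberately unclassifiable.

**Association.** For sample *i* with minor-allele dosage
*g<sub>i</sub>* ∈ {0,1,2}:

    logit P(case_i) = β0 + β g_i + γ' x_i

fit per SNP by IRLS with Wald inference, after call-rate (>98% samples,
>99% SNPs), MAF (>5%) and Hardy–Weinberg (exact test in controls) QC,
removal of case-only site×platform strata, and EIGENSTRAT-style genotype PCA
for the ancestry covariates. Genomic-control λ, Manhattan/QQ tables, and a
known-variant look-up (significance + direction concordance) are included.

**Power.** Penetrances f₀, f₁, f₂ are calibrated so the population prevalence
under Hardy–Weinberg genotype frequencies equals K; case/control genotype
frequencies follow by Bayes inversion, and the two-sided 1-df
Cochran–Armitage trend test's power follows from its noncentrality. A
bisection solver returns the minimum detectable per-allele effect. The
default effect scale is the multiplicative genotype relative risk used by
CaTS-style calculators; a per-allele odds-ratio scale is available and is the
generative model of the genotype simulator.

## Worked example

```r
library(rhtn)

spec <- cohort_sim_spec(setNames(rep(10L, 7L), ARCHETYPES), seed = 42)
sim  <- simulate_cohort(spec)          # 70 patients, labels planted
ph   <- phenotype_cohort(sim$cohort)
print(ph$summary)
#> <phenotype_summary> 70 patients
#>   CASE_CONTROLLED       10
#>   CASE_UNCONTROLLED     10
#>   CONTROL               10
#>   EXCLUDED              20
#>   UNCLASSIFIED          20
#>   case algorithms: controlled 10, uncontrolled 10
mean(ph$calls$status == sim$truth$expected_status)
#> [1] 1
```

Ten patients of each archetype: both case definitions, controls, a
"pseudoresistant" near-miss (elevated only inside the one-month lag — stays
unclassified), CKD- and HF-excluded records, and normotensives. The
classifier recovers every planted label.

```r
power_additive(2830, 876, maf = 0.20, effect = 1.41,
               prevalence = 0.10, alpha = 5e-8)$power
#> [1] 0.6132048
min_detectable_or(2830, 876, maf = 0.20, prevalence = 0.10, alpha = 5e-8)
#> [1] 1.453688
```

With 2,830 cases and 876 controls at genome-wide significance, a risk-allele
frequency of 0.20 and prevalence 0.10, the smallest per-allele effect
detectable at 80% power is ≈1.45.

An end-to-end run (simulate → phenotype → VCF → GWAS → look-up → power, with
a config-hash-stamped manifest) is one call:

```r
run_all(run_config("runs/demo", seed = 1))
run_report("runs/demo")
```

or from the shell via the CLI launcher in `inst/cli/rhtn`
(`rhtn run-all --out runs/demo --seed 1`).

## Layout

- `R/` — data model + I/O, medication ontology, phenotyper, synthetic-data
  generators, GWAS engine, power module, pipeline/CLI.
- `vignettes/resistant-hypertension-pipeline.Rmd` — the methods vignette:
  model assumptions, parameter choices, and what the synthetic tests do and
  do not establish.
- `inst/extdata/` — starter medication-class dictionary and exclusion config
  (both editable CSVs/JSON).
- `tests/testthat/` — unit, property and acceptance suites with independent
  oracles (closed-form 2×2 OR, HWE enumeration, Monte-Carlo power).
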