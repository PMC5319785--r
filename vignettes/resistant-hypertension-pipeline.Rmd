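---
title: "Phenotyping, association and power for resistant hypertension: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Phenotyping, association and power for resistant hypertension}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rhtn)
```

# Overview

`rhtn` implements a complete desk-scale version of an EHR-based genetic study
of resistant hypertension: a rule-based temporal phenotyper, a case-control
additive-model association engine with ancestry adjustment, an analytic power
calculator, and a synthetic-data generator that makes the whole chain
testable. This vignette records the models, the tunable parameters and their
defaults, the numerical choices, and — importantly — what a passing test
suite does and does not establish.

# The phenotyping model

## Medication-class concurrency

The unit of evidence is a medication event. Three source types are
recognised: structured prescriptions, medication-list mentions extracted
from text, and refills. A list mention only counts when a *sig attribute*
(dose, strength, route or frequency) accompanies the drug name; a bare name
on a problem list is too weak an indication that the drug was actually
prescribed. Thirteen antihypertensive classes are counted (ACEi/ARB as one
class, beta blockers, the two calcium-channel-blocker subtypes, hydralazine,
minoxidil, central alpha agonists, direct renin antagonists, aldosterone
antagonists, alpha antagonists, and three diuretic subtypes). Direct alpha
antagonists (phentolamine, phenoxybenzamine) are deliberately mapped to
nothing: they treat pathologic adrenergic states, which are themselves an
exclusion.

Concurrency has two evidence routes:

* **Coverage intervals.** A refill covers `[date, date + days_supply)`;
  non-refill evidence covers `[date, date + mention_window_days)` (default
  90 days). The window is a modelling assumption — prescriptions and
  validated mentions carry no duration — and 90 days matches a typical
  chronic-disease prescription cycle. Intervals are half-open, so a refill
  ending the day another begins does not create spurious overlap.
* **Same-list co-mention.** Several classes named (with sigs) in one
  medication list establish same-day concurrency regardless of windows.

A patient is concurrently on *k* classes on the first date either route
reaches *k* distinct classes. The three diuretic subtypes count separately
by default because the algorithm enumerates them separately;
`collapse_diuretics = TRUE` gives the alternative convention in which "a
diuretic" counts once.

## Case, control and exclusion definitions

* **Controlled case**: ≥4 concurrent classes. Index date = first such date.
* **Uncontrolled case**: ≥3 concurrent classes, and an SBP >140 or DBP >90
  mm Hg measured at least `uncontrolled_bp_lag_days` (default 30) after the
  medication criteria were met, with ≥3 classes still concurrent on the
  measurement date. Index date = the qualifying measurement. The "one
  month" requirement is genuinely ambiguous between *sustained for a month*
  and *still present after a month*; the latter is implementable from
  sparse encounter data and is what we operationalise, with the lag
  configurable.
* **Control**: hypertension evidence (untreated BP >140/>90 before the first
  antihypertensive, or a 401.* code at any time), exactly one medication
  class at a time (the class may change; classes never overlap), and every
  BP from one month after the first prescription onward <135 systolic *and*
  <90 diastolic, with at least one such measurement. The asymmetric bounds
  (entry >140, maintenance <135) are kept exactly as the algorithm states
  them. Index date = first prescription.
* **Exclusions**, evaluated at the index date of the first definition whose
  criteria are met: any ICD-9-CM code with a configured excluded prefix
  (string-prefix match on the verbatim code; defaults cover adrenal
  neoplasms, hyperaldosteronism and secondary hypertension); chronic kidney
  disease, i.e. any MDRD eGFR ≤30 ml/min at/before the index date or within
  183 days after it; and systolic heart failure, i.e. EF ≤35% within ±365
  days of the index for cases, at any time for controls. The post-index CKD
  window is applied identically to all definitions — published deployments
  of such algorithms spell it out for one arm only, and symmetry is the
  only defensible generalisation; both window lengths are configurable.

Precedence is controlled case → uncontrolled case → control → unclassified,
with an exclusion at the qualifying definition overriding to `EXCLUDED`.
Ordering the two case algorithms is arbitrary but harmless (analyses combine
them); the rule trace records every decision.

## MDRD and age

The 4-variable IDMS-standardised MDRD equation
(175·scr^−1.154^·age^−0.203^·0.742^[female]^·1.212^[black]^) is used; the
literature also contains a 186-coefficient variant, and deployments rarely
record which they used — 175 is the contemporary standard. Birth
dates are not part of the data model (only birth decades), so age at a lab
date is computed from the decade midpoint; a five-year error moves eGFR by
~2%, far from the 30 ml/min threshold for any clinically unambiguous value.

# The synthetic cohort: a stated world

`simulate_cohort()` emits seven archetypes, one per branch of the logic:
both case types, controls, a *pseudoresistant near-miss* (three concurrent
classes whose elevated pressures all fall inside the one-month lag — the
classifier must leave it unclassified), CKD- and HF-excluded records, and
untreated normotensives. Blood pressures are deterministic templates
(elevated 158/98, controlled 120/76, normotensive 118/74 mm Hg) plus
Gaussian noise with `bp_noise_sd = 4` mm Hg, *truncated at 2.5 SD*. The
templates keep ≥3.75 SD of margin from every decision threshold, so with
truncation the noise provably cannot flip a planted label. That is a design
decision, not an accident: the planted-label recovery test is meant to
verify the classifier's logic, and a version whose labels could flip with
seed choice would test the generator instead.

What a green recovery test establishes: the classifier implements exactly
the stated rules on records that satisfy exactly one definition. What it
does not establish: performance on real records with incomplete medication
data, conflicting evidence, unit errors, or genuinely borderline
trajectories — the archetypes are unambiguous by construction, and real
EHR data are not. Chart-review validation cannot be simulated.

Genotypes (`simulate_genotypes()`) use two subpopulations whose per-SNP
allele frequencies diverge around a shared ancestral frequency in
Balding–Nichols fashion (Beta draws with variance parameter
`fst_like_divergence`), Hardy–Weinberg genotypes within subpopulation, and
retrospective sampling for causal SNPs: penetrances are calibrated to the
population prevalence (default 0.10) under the additive logistic model, and
genotypes are drawn from the implied case or control genotype frequencies.
This matches both the association engine's estimand (the per-allele OR) and
the power module's generative model, so analytic and simulated power agree
by construction of the model — their agreement test checks the normal
approximation, not the model. No linkage disequilibrium is simulated; PCA
behaviour under LD pruning is out of scope.

# The association engine

* **QC order**: sample call rate (> 0.98) first, then SNP call rate
  (> 0.99), MAF (> 0.05), and the Hardy–Weinberg exact test computed in
  controls only (threshold 1e-6, configurable; true associations distort
  HWE in cases, so testing in controls is the conventional choice).
* **HWE**: the exact conditional test — the p-value is the total
  probability, given the allele counts, of heterozygote counts no more
  probable than observed. Implemented by direct log-factorial evaluation
  over all attainable heterozygote counts; a tolerance of 1e-10 on
  log-probability ties guards against floating-point jitter in the "no more
  probable" comparison.
* **Coding**: the counted allele is forced to be the minor allele at load,
  with a per-SNP flip flag.
* **PCA**: columns centred by 2p̂ and scaled by √(2p̂(1−p̂)), missing dosages
  mean-imputed *only* inside PCA (they are dropped per SNP in association),
  monomorphic SNPs skipped with a warning, sample scores the orthonormal
  left singular vectors, each component's sign fixed by making its
  largest-magnitude SNP loading positive.
* **Strata guard**: samples in any site×platform stratum containing only
  cases or only controls are removed before fitting — such strata make the
  adjusted likelihood unbounded; removal is the remedy that matches how
  this failure is handled in practice (and the per-stratum table is
  reported).
* **Logistic fit**: IRLS (`glm.fit`) with tolerance 1e-8 and 25 iterations;
  Wald CI and two-sided p. Non-convergence, rank deficiency (including
  constant dosage), and separation (boundary-probability warning, or
  |β| > 15 / SE > 20 — absurd magnitudes for a per-allele log-odds) yield a
  flagged row with absent statistics rather than an exception or a Firth
  fallback; flagged SNPs are excluded from λ~GC~.
* **Ties** in output ordering break by (chrom, pos, snp id).

# The power module

For genotype frequencies *g* under HWE at risk-allele frequency *p* and
penetrances *f*, calibrated so Σg~i~f~i~ = K, the case/control genotype
frequencies are g~i~f~i~/K and g~i~(1−f~i~)/(1−K). The two-sided 1-df trend
test with dosage scores uses the pooled-frequency variance under the null
and the group-specific variance under the alternative:

power = Φ((−z~α/2~·se₀ − Δ)/se₁) + 1 − Φ((z~α/2~·se₀ − Δ)/se₁),

with Δ the case−control difference in mean dosage. `min_detectable_or()`
bisects on the effect in [1, 20] to 1e-4 and returns the upper bracket
endpoint, so the returned effect always meets the target power.

**Effect scale.** This was the one genuinely open design choice. The
penetrance model can place the per-allele effect on the odds scale
(odds~i~ = baseline·OR^i^ — the additive logistic model the association
engine estimates) or on the risk scale (f~i~ = f₀·GRR^i^ — the
multiplicative model the CaTS family of power calculators uses). The two
disagree noticeably at realistic prevalences: at 2,830/876,
MAF 0.20, K 0.10, α 5×10⁻⁸ the minimum detectable effect is 1.45 on the
risk scale and 1.52 on the odds scale. Power functions default to the risk
scale because emulating the established calculators is their stated
purpose; `calibrate_penetrance()`/`case_control_freqs()` default to the
odds scale because the genotype simulator plants odds ratios for the
logistic engine to estimate. Both accept `effect_scale` explicitly.
Prevalence defaults to 0.10, the upper end of the commonly cited 8–12%
share of treated hypertensives who are resistant; on the risk scale the
case genotype frequencies are prevalence-free and the control frequencies
depend on it only weakly, so this choice moves results by <1%.

Two-sided testing with no continuity correction throughout; the
relative-risk scale caps the feasible effect where f₂ reaches 1, and the
solver restricts its bracket accordingly.

# Pipeline and reproducibility

`run_all()` executes simulate → phenotype → genotype → GWAS → look-up →
power, writing a manifest with per-file MD5s and the configuration hash;
every delimited output carries that hash as a `#` comment line and the VCF
as a `##config_hash` header. Reruns of the same configuration are
byte-identical (the manifest records no timestamps for exactly this
reason). All temporal windows are computed in whole days (1 month = 30,
6 months = 183, 1 year = 365); dates are ISO-8601; same-day duplicate BP
readings are kept as separate measurements because the control definition
quantifies over *all* measurements.

# Known limitations

* Drug-name matching is exact (case-insensitive); no RxNorm/ingredient
  normalisation, no dose arithmetic, no adherence modelling.
* The phenotyper's validity on real data rests on the upstream quality of
  medication extraction — the sig-attribute rule is a proxy, not NLP.
* No imputation, no mixed models, no X-chromosome handling, no LD; the
  association engine targets hard-called autosomal biallelic genotypes.
* The power approximation is the standard shifted normal; at very small α
  and tiny samples the exact test is more conservative than the
  approximation.
* The synthetic world is deliberately unambiguous; recovery rates near 100%
  say nothing about positive predictive value in a real EHR.
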