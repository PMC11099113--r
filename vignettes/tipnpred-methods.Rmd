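---
title: "Staged polygenic prediction of persistent taxane-induced neuropathy symptoms"
author: "tipnpred"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Staged polygenic prediction of persistent taxane-induced neuropathy symptoms}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tipnpred)
```

## The problem

Persistent peripheral neuropathy after taxane chemotherapy (numbness,
tingling, cramps, and weakness-related motor difficulties) affects a large
share of early-stage breast cancer survivors, with no single predictive
gene: the phenotype behaves as a polygenic trait with small-to-modest
per-variant effects, modulated by clinical risk factors (age, BMI, taxane
type, diabetes). `tipnpred` implements, as a reusable and tested pipeline,
a staged construction-and-validation procedure for per-symptom polygenic
logistic prediction models from whole-exome variant data:

1. **Variant QC** on a multi-sample VCF;
2. **Per-variant association scans** under additive, dominant and recessive
   codings, with a **permutation-based FDR** rule to pick the per-symptom
   p-value threshold;
3. **Gene/region variance-component tests** of rare variants;
4. **Gene-set over-representation filtering** of the candidates;
5. **Combination with a literature panel** of previously associated
   variants;
6. **Variable-importance pruning** of the combined model;
7. **Held-out validation** (ROC/AUC, accuracy-targeted cutoff, risk-group
   summaries) on a test cohort never touched by any selection step.

Each symptom is analyzed separately: different symptoms plausibly have
different biological backgrounds, so one model per dichotomized outcome.

## Data model

A cohort is a `TaxaneCohort`, a `SummarizedExperiment` whose `dosage` assay
is a variants × samples matrix coded 0/1/2/NA (reference homozygote /
heterozygote / alternate homozygote / missing call), whose `rowData` holds
the per-variant record (locus, alleles, FILTER label, mean coverage, gene
annotation, optional CADD-like deleteriousness score), and whose `colData`
holds covariates and the five binary symptom outcomes with per-item
missingness. Questionnaire items on the four-level scale ("not at all" …
"very much") are dichotomized by `dichotomizeSymptom()`: the upper two
levels define the moderate-severe phenotype.

## Stage statistics

**QC** (`filterVariants`). A variant is kept iff genotyping rate ≥ 0.95,
mean coverage ≥ 10 reads, Hardy–Weinberg exact p ≥ 1e-4, biallelic, and
FILTER equal to `PASS`. All thresholds are *removal* conditions exactly as
conventionally printed ("< 0.95", "< 10", "p < 0.0001"), so boundary values
keep the variant. The HWE test (`hweExactP`) is the exact conditional test
on genotype counts: given the allele counts, heterozygote counts follow the
Levene–Haldane distribution, and the two-sided p sums the probabilities of
all tables no more likely than the observed one. The implementation uses
the numerically stable ratio recurrence; the test suite checks it against a
direct log-factorial enumeration over the whole count space. Multi-allelic
rows are flagged and dropped, not decomposed. Missing genotypes are never
imputed at QC time.

**Association scan** (`snvScan`). Per variant and per coding (additive
0/1/2, dominant 0/1/1, recessive 0/0/1) the package fits
`outcome ~ intercept + encoded genotype` by logistic regression and reports
the Wald test. The scan is genotype-only; clinical covariates enter at
model building, which mirrors the common practice of a crude scan followed
by covariate-adjusted modelling. Because a single-variant model has at most
three predictor levels, the data collapse to a 2 × 3 count table and the
fit runs on three support points — implemented in C++, which is what makes
1000-permutation FDR estimation affordable. A coding is skipped (p = 1)
when fewer than `minCount = 5` samples fall outside the modal encoded
category, or on separation. The best coding is the smallest p, ties broken
additive > dominant > recessive for determinism.

**Permutation FDR** (`permutationFdr`). Outcome labels are permuted (the
genotype matrix, and hence LD, is untouched), the full three-coding scan is
re-run per permutation, and for each candidate threshold $t$

$$\widehat{\mathrm{FDR}}(t) = \min\!\left(1,\;
  \frac{\overline{\#\{p^{\mathrm{perm}}_{\min} \le t\}}}
       {\max(1, \#\{p^{\mathrm{obs}}_{\min} \le t\})}\right),$$

with the chosen threshold the argmin, smallest-$t$ tie-break. The candidate
grid defaults to the 0.00001–0.005 window. Note the estimator's sampling
behaviour: under a global null the observed hit count is exchangeable with
the permutation draws, so at $k$ observed hits the estimate carries
roughly $1/\sqrt{k}$ relative noise; estimates near 1 with occasional dips
are expected, and the tests bound those dips by that envelope rather than
by a fixed constant.

**Region tests** (`regionScoreTest`, `regionScan`). For a gene's rare
variants (MAF < 0.01 by default) with null-model fitted values $\hat\mu$
from `y ~ covariates` and weights $W = \mathrm{diag}(w_j)$,

$$Q = (y-\hat\mu)^\top G\, W^2 G^\top (y-\hat\mu),$$

the familiar variance-component score statistic. Weights default to the
Beta(1, 25) density at the variant's MAF (the conventional rare-variant
upweighting; `weights = "flat"` available). Genes need at least two rare
variants. The asymptotic null is the mixture
$\sum_i \lambda_i \chi^2_{1,i}$ with $\lambda$ the eigenvalues of the
projected weighted kernel; the package evaluates it by a three-moment
chi-square match on $\sum_i \lambda_i^k$. Empirically, with a binary
outcome, rare variants and cohorts of a few hundred samples, that
asymptotic tail is visibly miscalibrated — the exact conditional
(permutation) null and the mixture differ in the body of the distribution
by several hundredths, more than any moment correction can absorb. The
package therefore treats the moment approximation as valid only for large
cohorts: `pMethod = "auto"` uses the permutation null (residual
permutation, shared across genes within a scan, 1000 shuffles by default)
below 2000 usable samples and the moment approximation above. This is the
"fallback when the approximation is out of its validity range" made
concrete, with the validity range established by measurement rather than
assumed.

**Over-representation filtering** (`oraHypergeometric`,
`enrichAndFilter`). Candidate genes are tested against user-supplied GMT
gene sets by the upper-tail hypergeometric probability of the observed
overlap. The universe defaults to the genes carrying at least one tested
variant — the space candidates are actually drawn from — rather than the
whole genome. Sets below the threshold are retained; candidate genes
survive iff they belong to a retained set, and variants iff they map to a
surviving gene. Raw set p-values are used by default (Benjamini–Hochberg
available but off), and the pipeline searches the threshold within the
0.005–0.2 window (0.0025–0.13 once the literature panel is combined in),
keeping the value that maximizes training AUC.

**Staged models** (`buildStage`). Stage A1 fits the literature panel
(additive coding, the panel convention) plus the four clinical covariates.
B1 fits the FDR-selected scan variants at their best codings. B2 widens the
scan inclusion to a rank cutoff (`b2TopK`), adds the variants of genes
passing the region tests (p ≤ 0.001, diagnosed by quantile–quantile
coordinates), and applies the over-representation filter. C1 adds the
panel variants significant in their source analysis (p < 0.05). C2 prunes
C1 by variable importance and refits. Every design is intercept + encoded
variants + covariates; exact collinearities are removed greedily
left-to-right (modified Gram–Schmidt, relative tolerance 1e-10), so
later-listed duplicates are the ones dropped; per-symptom missing outcomes
are excluded, remaining missingness is complete-case.

**Variable importance** is the absolute Wald $z$ of each non-intercept
coefficient. The source procedure only says importance was "collected"
from the fitted model; $|z|$ is the standard model-based importance for
this model class, and thresholds in the tuned 1.00–1.67 window are natural
on that scale. Thresholding is boundary-inclusive, forced covariates
survive regardless, and the pipeline picks the grid value maximizing
training AUC.

**Evaluation** (`rocAuc`, `aucCi`, `chooseCutoff`, `confusionAtCutoff`,
`acceptModel`). AUC uses the rank (Mann–Whitney) formulation with half
credit for ties; its confidence interval is a stratified percentile
bootstrap (positives and negatives resampled separately, 2000 replicates,
seeded). The probability cutoff is chosen on training data to minimize
|accuracy − target| over the midpoints of distinct predicted
probabilities, ties broken toward higher sensitivity and then the lower
cutoff; the default target is 80% accuracy. Classification at the cutoff is
$\ge$, i.e. the boundary sample lands in the predicted high-toxicity
group. A model is *accepted* iff training AUC > 80% and held-out test AUC
> 60%, both strict. Cohort-balance comparisons use the Welch
unequal-variance t-test.

## The overfitting guard

Logistic models with as many features as events are a known failure mode of
this procedure, and the staged design deliberately walks close to it. The
guard in `buildStage` refuses a fit when features exceed
events/`epvFloor`, and warns below five events per variable. The default
floor of 1 never allows more features than events. The published workflow
itself, however, fits 30 terms on about 28 events for the rarest symptom;
runs that emulate that regime (including the acceptance script) therefore
set `epvFloor = 0.85`, accepting the warning in exchange for faithfulness
to the procedure being reproduced.

## The synthetic cohort

Because the underlying patient-level data are not redistributable, the
package ships a generator that reproduces the statistical structure the
analysis assumes, with stored ground truth:

* **Genotypes**: per-variant MAF from a rare/common mixture (32% common,
  uniform on [0.01, 0.5]; the rest on [0.0005, 0.01]); dosages as two
  Bernoulli allele draws, so HWE holds marginally; optional linkage blocks
  through a Gaussian copula with a shared within-block factor; PASS
  filters, ~75× mean coverage, CADD-like scores; genes tiled over
  consecutive variants with occasional two-gene overlaps.
* **Covariates**: age truncated-normal (62 ± 10, range 31–86), BMI normal
  (26.9 ± 4.7), paclitaxel Bernoulli(0.445), diabetes treatment
  Bernoulli(0.047) — moments matched to the published cohort
  characteristics.
* **Phenotypes**: logistic liability per symptom,
  $P(y=1) = \mathrm{logit}^{-1}(\beta_0 + \sum_j \beta_j\,
  \mathrm{code}(g_j) + \gamma^\top x)$, with the intercept calibrated by
  root-finding so expected prevalence matches the five targets (25.5%,
  24.6%, 27.6%, 26.1%, 12.1–12.2%); default ten causal variants per
  symptom with |log-odds| 0.8, coding labels drawn 0.46/0.35/0.19
  additive/dominant/recessive; symptom correlation induced solely by a
  shared causal pool (30%) and shared covariates; 0.6% item missingness.
  A logistic (not probit) liability matches the analysis model and makes
  recovery checks direct.

The generator also emits the pipeline's on-disk formats (VCF with GT and an
INFO depth field, phenotype CSV, truth JSON), and helpers build a
26-variant literature panel (8 members significant at p < 0.05 in their
source) and a GMT collection with one planted pathway containing the causal
genes.

What the generator does *not* emulate — and hence what passing tests do not
establish about real data: realistic haplotype structure and LD decay,
population stratification and relatedness, genotype-calling error modes
correlated with coverage, batch effects, and the measurement model of the
questionnaire beyond independent item missingness. Results on synthetic
cohorts demonstrate that the machinery is correct and calibrated under its
own assumptions, not that the clinical models transfer.

## Numerical and design choices

* Variant ids default to the rsID and fall back to `chrom:pos:ref:alt`.
* Cohort split: the test-set size is `floor((1 − fraction) · n)` by
  default. No rounding convention maps (337, 0.7) onto the published
  237/100 split (floor gives 236/101), so `splitCohort` and the pipeline
  accept an explicit `nTest`; the study-scale emulation passes
  `nTest = 100`.
* Singularities: greedy left-to-right retention with relative tolerance
  1e-10; the later column of an exactly collinear pair is dropped.
* The IRLS engine is `stats::glm.fit` (binomial, epsilon 1e-10, 50
  iterations) with separation flagged when coefficients diverge alongside
  boundary fitted probabilities; the suite cross-checks against an
  independently coded Newton–Raphson fit.
* All randomness (split, permutations, bootstrap, simulation) flows from
  explicit seeds; the pipeline derives per-stage streams from one master
  seed, and two runs with the same configuration are byte-identical.
* Selection, threshold tuning and cutoff choice see training samples only;
  the held-out samples are touched exclusively by the final evaluation
  calls. Perturbing every held-out outcome changes no selected feature —
  this leak-freedom property is asserted in the tests.
* Degenerate inputs: monomorphic variants are skipped with p = 1;
  zero-variance regions return p = 1; all-missing dosage columns are
  errors; empty threshold grids are errors; an over-representation run in
  which no set passes returns an empty (valid) selection.

## Problem sizes

The shipped tests and the acceptance script run scaled-down cohorts chosen
to exercise every stage with adequate power: module tests use hundreds of
samples and hundreds of variants; calibration suites pool across 10–20
seeded replicates; the recovery suite uses n = 2000 with 10 causal among
100 candidates; the acceptance script emulates the study size itself
(n = 337, 237/100 split) over 6000 variants with 200 permutations. These
sizes are the package's own choices balancing statistical resolution
against a test suite that runs in minutes.

## Known limitations

The moment-matched region p-value remains available (`pMethod = "moment"`)
but is only trustworthy at cohort sizes well beyond this study's; the
permutation default is exact but discrete (resolution 1/(B+1)). The FDR
estimator inherits the high variance of its ratio construction at small
hit counts. A2-style models (large literature pathway panels) are
expressible via `buildStage` but overfit by construction at these sample
sizes — the guard exists precisely to surface that. Regularized
alternatives (lasso/ridge) and cross-validated selection are out of scope:
the procedure reproduced here uses a single split and unpenalized logistic
fits.
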