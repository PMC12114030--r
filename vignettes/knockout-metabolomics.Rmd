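---
title: "Methods: exact statistics for human-knockout metabolomics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: exact statistics for human-knockout metabolomics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(komet)
```

`komet` implements the statistical core of a human-knockout metabolomics
study: select predicted loss-of-function (pLoF) variant carriers from a
biobank-scale cohort, adjust untargeted metabolite abundances for
covariates, test knockout–metabolite associations with an exact rank test
under severe group imbalance, quantify detection power by simulation, and
test knockout–diagnosis associations with a stratified conditional exact
test. This vignette records the model, the numerical choices, and the
reasoning behind each default, so that every number the package produces can
be traced to a stated decision.

## 1. The statistical problem

A "human knockout" is an individual homozygous for a high-confidence pLoF
variant in a gene — both copies predicted non-functional. In a cohort of a
few hundred to a few thousand genotyped individuals with plasma
metabolomics, any one gene typically has 2–10 knockouts, compared against
roughly 258 non-carrier controls. Classical asymptotic tests are invalid at
n = 3 vs 258; the package therefore computes *exact* conditional null
distributions throughout:

- **Metabolite levels**: one-sided exact Wilcoxon rank-sum test
  (`exact_wilcoxon_one_sided()`), null distribution computed by dynamic
  programming over the observed (possibly tied) ranks.
- **Below-LOD missingness**: one-sided Fisher / hypergeometric tail
  (`missingness_test()`) on the 2×2 table of detected vs missing — absence
  of a measurement is informative when a metabolite falls under the
  platform's limit of detection (LOD).
- **Diagnoses**: exact conditional test for stratified 2×2 tables
  (`conditional_exact_test()`) with a conditional maximum-likelihood
  estimate of the common odds ratio (`cmle_common_or()`).

## 2. Exact Wilcoxon rank-sum tail

For carriers $x_1,\dots,x_{n_1}$ and controls $y_1,\dots,y_{n_2}$, the test
statistic is the carrier rank sum $W$ over the pooled midranks. The null
distribution is obtained exactly by a dynamic program over *doubled*
midranks (doubling makes tied midranks integral), counting for each total
$s$ the number of $n_1$-subsets of the pooled values with doubled-rank sum
$s$. The one-sided p-value is the tail count divided by
$\binom{n_1+n_2}{n_1}$. This conditions on the observed tie pattern, which
is the standard exact treatment of ties.

Numerical notes:

- Subset counts up to $n_1 + n_2 \approx 270$ fit exactly in doubles
  (counts are below $2^{53}$ for the group sizes used here relative to the
  total, since we normalize by the total computed in the same DP).
- `minimal_p(n1, n2)` $= 1/\binom{n_1+n_2}{n_1}$, the smallest attainable
  p-value, is computed as `exp(-lchoose(n1 + n2, n1))`. Relative error is
  ~1e-15, far below the three significant figures at which such values are
  ever reported.
- `alternative = "auto"` (the default in the scan) tests in the direction
  of the observed shift, matching how top hits are reported when every
  carrier lies beyond every control. A `"two.sided"` option doubles the
  smaller tail (capped at 1).

Fully separated groups reproduce textbook values: 10 carriers above 257
controls give $1/\binom{267}{10} = 2.34\times10^{-18}$.

```{r}
exact_wilcoxon_one_sided(258:267, 1:257, "greater")$p.value
minimal_p(10, 257)
```

## 3. Metabolite preprocessing

`preprocess_metabolites()` implements a two-stage covariate adjustment on
natural-log abundances:

1. Metabolites missing in more than `max_missing = 0.95` of samples are
   removed (strict inequality at the boundary).
2. **Stage 1**: each log metabolite is residualized on the always-adjusted
   covariates — age, sex and 10 genetic principal components — by ordinary
   least squares over the samples where the metabolite is observed.
3. **Candidate covariate selection**: BMI (linear slope t-test), smoking,
   education and season (one-way ANOVA) are tested marginally against the
   stage-1 residuals; covariates with p < `alpha = 0.05` are kept.
4. **Stage 2**: the model is refit from the log values with the base plus
   selected covariates; residuals are z-scored to mean 0, SD 1.

Missing metabolite values are *never* imputed: a sample missing a
metabolite, or missing a selected covariate, is simply absent from that
metabolite's residual vector. Residual invariants (column mean 0, SD 1 to
1e-8; missingness pattern a superset of the input's) are asserted in the
test suite.

## 4. Multiple testing via effective tests

Metabolite panels are strongly correlated, so Bonferroni over the raw
metabolite count is needlessly conservative. `effective_tests()` computes
the number of principal components explaining `variance_fraction = 0.90` of
the residual-matrix variance (singular value decomposition; missing entries
zero-filled, which is conservative for variance concentration), and
`significance_threshold(alpha, m_eff, n_variants)` divides `alpha` by
effective tests × variants:

```{r}
significance_threshold(0.05, m_eff = 368, n_variants = 152)
```

## 5. Variant selection

- **Strategy 1** (`select_strategy1()`): high-confidence LOFTEE pLoF
  variants with MAF < 2% (strict), at least 2 homozygous knockouts, in a
  gene present in the OMIM *or* Open Targets list (union).
- **Strategy 2** (`select_strategy2()`): per disease gene, pool *distinct*
  heterozygous carriers across variants with MAF ≤ 0.1% that are
  pathogenic or high-confidence pLoF; keep genes with ≥ 10 carriers.
- Compound heterozygotes (`find_compound_het_candidates()`) are reported
  for review but never auto-promoted to knockout status, since phase is
  unknown from dosage data.

## 6. Power simulation

`simulate_power()` estimates, for each (effect size β, knockout count)
cell, the probability that the one-sided exact test rejects at a given
threshold, with controls N(0,1) and knockouts N(β,1). Two design choices:

- Cells where even complete separation cannot reach the threshold
  (`minimal_p >= threshold`) are reported as power 0 without simulation
  ("unattainable").
- Because the simulated data are continuous, ties occur with probability
  zero, so the null tail CDF of the rank sum is computed *once* per group
  size and each trial reduces to comparing a rank sum against a critical
  value. This is the same exact test, not an approximation; the test suite
  asserts trial-level equivalence with `exact_wilcoxon_one_sided()`.

At β = 3, 5 knockouts, 258 controls and threshold 9×10⁻⁷, the true power is
within Monte-Carlo error of 80% — the canonical "detectable effect" for
this design.

## 7. Disease associations

`recurrent_case_table()` defines a case as ≥ 2 diagnosis events in an
ICD-10 three-character category (codes upper-cased, dots stripped,
malformed codes skipped with a warning). Aggregation to the category is
done *before* counting by default; the alternative reading — require ≥ 2
events of the same full code — is available via `category_level = FALSE`.
`apply_exclusions()` keeps categories with ≥ 5 cases and variants with ≥ 2
knockouts.

`build_strata()` cross-tabulates knockouts vs controls and cases vs
non-cases within sex × 10-year age bins (bins start at age 18; strata
lacking either a knockout or a control are dropped, as they carry no
information about the within-stratum association).

`conditional_exact_test()` conditions on all margins of every stratum: the
null distribution of $T=\sum_k a_k$ (summed knockout-case counts) is the
convolution of central hypergeometrics. The two-sided p-value uses the
probability-mass ("minlike") rule — sum the probabilities of all outcomes
no more likely than the observed one — which reduces exactly to Fisher's
two-sided test for a single stratum. `cmle_common_or()` solves
$E_\psi[T] = T_{obs}$ (the conditional score equation, whose left side is
strictly increasing in $\psi$) by bisection on $\log\psi$; an observed $T$
on the boundary of its support yields $\psi \in \{0, \infty\}$ with a
`boundary` flag.

## 8. Synthetic cohort generator

Real biobank data cannot ship with a package, so `generate_cohort()`
produces cohorts with a first-class *truth record* against which every
stage can be validated:

- log-abundance = baseline + covariate effects + knockout effect β
  (heterozygotes receive `het_effect_fraction = 0.5` of β) + correlated
  noise. Noise has a latent-factor structure (`factor_share = 0.35`,
  `n_factors = m/10`) so that, as in real panels, the effective test count
  is well below the metabolite count.
- Abundances are left-censored below a per-metabolite `lod_quantile`
  (default 5%), reproducing informative below-LOD missingness. Note that a
  strong *negative* knockout effect pushes all carriers below the LOD: the
  pair then becomes invisible to the rank test and is instead caught by
  `missingness_test()` — a deliberate feature mirroring how complete-loss
  phenotypes present in practice.
- EHR events follow a stratified logistic model with a configured common
  odds ratio for knockouts, so `cmle_common_or()` recovery is testable.
- Covariate missingness is injected after generation; controls never carry
  any variant.

What the generator does *not* emulate: genotype linkage disequilibrium,
batch effects, non-Gaussian abundance tails, and longitudinal diagnosis
timing. These do not affect the correctness of the exact tests, which
condition on the observed data.

## 9. Orchestration

`run_pipeline()` runs select → preprocess → associate → (optional) power →
EHR scan from a single YAML config, writes one TSV per stage plus a
Table-1-style report annotated by `annotate_report()` (drug-target and OMIM
flags, strategy labels), and logs every filter's input/output counts. Any
stage failure aborts with the stage name and removes partial outputs. A
fixed seed gives byte-identical outputs. A thin command-line wrapper lives
at `system.file("cli", "komet.R", package = "komet")`.

## 10. Limitations

- `minimal_p` uses log-gamma rather than rational arithmetic (no
  arbitrary-precision dependency); error ~1e-15 relative.
- The zero-fill in `effective_tests()` biases the effective count slightly
  upward under heavy missingness (more conservative thresholds).
- The conditional exact test enumerates the convolution support, which is
  fast for knockout-scale strata but not intended for exposed groups of
  thousands.
- Stage-2 covariate selection is marginal, not joint; with strongly
  collinear candidates a joint criterion could select differently.
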