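---
title: "Rule-based metabolic syndrome definitions and their diagnostic accuracy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rule-based metabolic syndrome definitions and their diagnostic accuracy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metsdx)
```

## The problem

Metabolic syndrome (MetS) is a cluster of five cardiometabolic risk
components -- abdominal obesity, elevated triglycerides, low HDL cholesterol,
elevated blood pressure and elevated fasting glucose -- and it has no single
definition. Each consensus body draws the component cutoffs differently and
imposes different combination rules, so the "same" cohort can show MetS
prevalence anywhere from under 5% to over 30% depending on the rule set
applied. metsdx implements six widely used rule sets as declarative,
auditable objects; classifies participant-level cohort tables under all of
them; and quantifies how well each definition agrees with the 2009
IDF/AHA/NHLBI harmonized definition, the natural gold standard because it
was negotiated precisely to unify its predecessors.

## The six rule sets

All cutoffs are stored in the units in which they are published: mg/dL for
glucose, triglycerides and HDL; mmHg for blood pressure; cm for waist
circumference. Conversion from mmol/L happens once, at ingest, so boundary
comparisons are never performed on converted values.

```{r}
mets_criteria("EGIR")[[1]]
```

Three structural features matter and are worth stating explicitly.

**Combination rules differ, not just cutoffs.** The harmonized definition,
NCEP-ATPIII and the Brazilian waist-cutoff adaptation of NCEP (Barbosa 2006)
require any 3 of 5 components. IDF makes central obesity a mandatory gate
plus any 2 of the remaining 4. EGIR and AACE gate on insulin resistance plus
any 2 of their component lists.

**Treatment substitutions.** A participant treated for hypertension has a
positive blood-pressure component regardless of the measured readings, and a
prior diabetes diagnosis or treatment makes the glucose component positive.
These substitutions are applied to the blood-pressure and glucose components
of every definition that includes them. Lipid-lowering treatment is
deliberately *not* a substitution: the cohort design this package mirrors
does not record it, and silently assuming it would inflate the TG/HDL
components.

**The EGIR gate is a proxy.** EGIR properly requires hyperinsulinemia (top
quartile of fasting insulin), but field cohorts of this kind carry no
insulin assay. The package operationalizes the gate as fasting glucose
>= 110 mg/dL or diabetes diagnosis/treatment -- the only EGIR-specific
glycemia cutoff in circulation -- and exposes the cutoff as a parameter
(`egir_glucose_cutoff`). This is a documented guess; its only validation is
that it produces the expected low EGIR prevalence (about 5% where the
harmonized rule finds about 31%). Any analysis leaning on EGIR should treat
that gate as a sensitivity-analysis knob, not a fact.

Two smaller decisions: the AACE rule here carries **no glucose component** by
default (its canonical impaired-fasting-glucose band needs an oral
glucose-tolerance work-up that screening cohorts lack; `aace_glucose = TRUE`
restores a 110-125 mg/dL band), and its insulin-resistance indicator list
treats **unknown optional history flags (family history, gestational
diabetes) as not satisfied** -- the conservative reading, which can only
underestimate AACE positivity. Comparators are taken literally from the
published cutoff tables: `>=` for most rows but strict `>` for the
NCEP/Barbosa waist rows, which is why the classifier is unit-tested exactly
at each boundary value.

## Accuracy statistics

With `a, b, c, d` the true-positive, false-positive, false-negative and
true-negative counts against the gold standard:

* Se = a/(a+c), Sp = d/(b+d), PPV = a/(a+b), NPV = d/(c+d), each with a
  Clopper-Pearson exact binomial 95% CI (beta-quantile form). The exact
  method is the right choice here because several comparisons produce
  boundary proportions (Sp = 100%, PPV = 100%) where Wald/Wilson intervals
  misbehave; the implementation is cross-checked in the tests against
  `stats::binom.test`. Predictive values are reported at the cohort's
  gold-standard prevalence (they are prevalence-dependent by construction,
  and the tests assert the Bayes identities to 1e-12).
* LR+ = Se/(1-Sp), LR- = (1-Se)/Sp, with log-method (Simel) intervals,
  e.g. for LR+: `exp(ln LR +/- 1.96 * sqrt(1/a - 1/(a+c) + 1/b - 1/(b+d)))`.
  When a comparison produces no false positives LR+ is undefined and is
  rendered as "-" in formatted output and `null` in JSON, never as Inf.
* Cohen's kappa = (Po - Pe)/(1 - Pe), banded as slight (<= 0.20), fair
  (0.21-0.40), moderate (0.41-0.60), substantial (0.61-0.80) and almost
  perfect (> 0.80). Band boundaries are half-open with an inclusive upper
  bound (0.60 is moderate, 0.61 is substantial). Note that under these
  thresholds a kappa of 0.8750 is "almost perfect"; descriptive tables in
  circulation sometimes label that value "substantial", which these bands
  treat as an inconsistency with their own stated thresholds rather than a
  different convention.

**Reconstruction from summary counts.** Published accuracy tables rarely
print the 2x2 cells, but `n`, the gold-positive count, each test-positive
count and the PPV determine them exactly:
`a = round(ppv * test_pos)`, `b = test_pos - a`, `c = gold_pos - a`,
`d = n - gold_pos - b`. `reconstruct_confusion()` implements this with
negative-cell detection; the test suite uses it to reproduce, to printed
rounding, a published five-criteria validity table from a cohort of 1,111
primary-care nursing professionals (gold-standard positives 347; comparison
positives 330/323/290/148/52). One caveat inherited from printed rounding:
a PPV printed to 3 figures can move `a` by one unit, which moves kappa by
about 2e-4 -- the tolerance the corresponding test uses.

```{r}
accuracy_report(reconstruct_confusion(1111, 347, 148, 0.973)) |>
  format_accuracy()
```

## Descriptive comparisons

`summarize_cohort()` reproduces the standard sex-stratified descriptive
layout. Choices that affect p-values:

* Pearson chi-square **without** Yates continuity correction for categorical
  rows; the uncorrected statistic is what reproduces the bivariate p-values
  printed in tables of this design (the corrected one does not).
* Continuous rows route on a Kolmogorov-Smirnov normality check per sex
  stratum at alpha = 0.05: both strata normal-looking -> Welch t-test,
  otherwise Mann-Whitney with normal approximation and tie correction. The
  KS check plugs in the sample mean and SD, so it inherits the Lilliefors
  caveat (anti-conservative as a formal test); it is used here only as a
  routing heuristic, matching field practice. Whether the check should be
  per stratum or pooled is underdetermined in the designs this mirrors;
  per-stratum is implemented because the routing decision is about the two
  samples actually compared.
* Component-positivity rows are computed by the same
  `evaluate_components()` predicates as the classifier -- a single source of
  truth for every cutoff, asserted in the tests.

One worked descriptive example in the tests deserves a note: a published
marital-status row prints cells (528, 477 | 70, 66) with p = 0.557, but 477
contradicts the table's own column totals (975 females); the reconciled cell
is 447, and the uncorrected chi-square on (528, 447 | 70, 66) reproduces
p = 0.557 exactly. The tests use the reconciled count.

## The synthetic cohort generator

`simulate_cohort()` exists so every downstream stage is testable without any
participant-level data. Its stated world:

* n = 1111, 87.7% female;
* per-sex means/SDs for the seven continuous measures taken from the
  clinical characteristics of a PHC nursing cohort (e.g. female fasting
  glucose 84.48 +/- 18.04 mg/dL);
* per-sex exceedance targets for the five harmonized component predicates
  (e.g. TG >= 150 in 32.31% of females, 41.18% of males);
* an exchangeable Gaussian-copula correlation rho = 0.3 among the five
  component axes;
* treatment flags conditional on the corresponding component (P = 0.5 given
  positive, 0.02 given negative), so the substitution code paths are
  exercised; remaining risk-indicator flags at fixed realistic rates
  (non-white 74.8% and sedentary 43.29% where printed; cvd 5%, pcos 8% of
  females, NAFLD 5%, acanthosis 3% as clinical defaults chosen once).

**Why quantile matching instead of the literal published normals:** real
metabolic measures are right-skewed, so a normal with the published mean/SD
does not reproduce the published component positivity fractions -- and the
positivity fractions are what the classifier logic consumes. Each marginal
therefore keeps the published SD but shifts its mean so the sex-appropriate
cutoff sits on the target quantile. Calibration is asserted to within 3
binomial SEs at n = 20,000.

**What the generator does not emulate.** (1) SBP and DBP are comonotone
transforms of a single latent, so the union predicate SBP >= 130 OR
DBP >= 85 calibrates exactly; the price is a degenerate SBP-DBP joint
distribution within subject. (2) rho = 0.3 is an assumption -- component
correlation information is simply not published -- and the realized joint
prevalence is therefore *not* a target: at the defaults the harmonized rule
classifies about 23% of simulated subjects versus about 31% in the real
cohort the marginals came from, because the real components are more
strongly coupled. (3) Skewness, measurement error and missingness mechanisms
are absent. A green classification test on synthetic data therefore
establishes that the rule logic (cutoffs, comparators, gates, substitutions)
is correct -- verified independently by a deliberately separate straight-line
re-implementation of all six rules -- but says nothing about any real
cohort's prevalence; published-table reproduction is done from printed
summary counts instead, where it is exact.

Degenerate marginal targets (0 or 1) are honored by clamping the measure to
the correct side of the cutoff; all measures are floored at small positive
values to respect the strictly-positive invariant, far below any cutoff so
no classification is affected.

## Numerical and degenerate-input conventions

* Undefined metrics (zero denominator) are `NA`, rendered "-"; they are
  never exceptions, because a perfect comparison (b = 0) is an expected,
  publishable outcome.
* Kappa with degenerate marginals (Pe = 1) is `NA`.
* Ingest never drops rows: cells failing coercion or invariants (negative
  measures, unparseable flags, male PCOS) become `NA` plus a row-level
  problem report; exclusion happens only in `filter_classifiable()`, which
  reconciles kept + excluded = input and is idempotent.
* Classification with missing required fields is an error naming the record
  and fields, not a silent `NA`.
* Full precision is kept internally; printed-style rounding (percentages to
  1 dp, kappa to 4 dp, LRs to 3 significant figures) happens only in
  `format_accuracy()`.

## Known limitations

* The EGIR gate proxy (above) is the largest interpretive choice.
* Sex-stratified accuracy is intentionally not computed (prevalence is
  stratified; accuracy is not -- between-sex differences in cohorts of this
  design do not justify it, and the package follows that scope).
* No ROC/AUC (the classifiers are binary rules, not scores), no multi-rater
  kappa, no bootstrap kappa intervals.
* `read_cohort()` handles CSV/TSV natively and XLSX via readxl when
  installed; codebooks must be supplied by the user because deposited
  datasets define their own column layouts.
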