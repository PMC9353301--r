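---
title: "Detecting drug-drug interaction signals in spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting drug-drug interaction signals in spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(faersddi)
```

## The problem

Spontaneous adverse event reporting systems such as FAERS collect
suspected drug–adverse-event reports without any denominator of drug
users, so only case/non-case designs are possible. `faersddi`
implements a discovery-driven pipeline for drug–drug interaction (DDI)
signal detection in such data: for every combination of a treatment
drug A (here: a COVID-19 therapy), a co-medication B and an adverse
event E, it asks whether the co-exposed reports carry more of the
event than the two drugs' separate effects explain. Flagged
combinations are hypotheses for pharmacological follow-up, not
established interactions.

## The model

For one (A, B, E) triple, over all cohort reports,

$$\mathrm{logit}\,P(E = 1) = \beta_0 + \beta_1 A + \beta_2 B +
\beta_3 AB + \boldsymbol{\beta}_4' \mathbf{z},$$

where $\mathbf{z}$ holds the confounders: the binary age group
(under 65 vs 65 and over), gender, and the number of unique drug
ingredient exposures coded as two dummies for the 3–4 and $\ge 5$ bins
(reference $\le 2$). Polypharmacy is the key confounder in reporting
data — reports listing many drugs mechanically co-expose many pairs —
which is why the drug count enters every model.

### Firth's penalty

Co-exposure cells are often sparse, and ordinary maximum likelihood is
biased in small samples and divergent under separation. The package
therefore maximizes the Jeffreys-penalized likelihood
$\ell(\beta) + \tfrac12 \log \det I(\beta)$ (Firth's correction) by
Newton–Raphson on the modified score
$U^*(\beta) = X'(y - \pi + h(\tfrac12 - \pi))$, with $h$ the diagonal
of the weighted hat matrix and step-halving whenever a step would
lower the penalized likelihood. Estimates are finite even when all
co-exposed reports carry the event. The reported covariance is the
inverse Fisher information at the optimum (Wald-type); delta-method
intervals below use it. Profile-penalized-likelihood intervals are a
known alternative and are out of scope here.

### Two interaction scales

*Additive.* The relative excess risk due to interaction, with odds
ratios approximating risk ratios because the outcomes are rare:

$$\mathrm{RERI} = e^{\beta_1+\beta_2+\beta_3} - e^{\beta_1} -
e^{\beta_2} + 1 .$$

Its standard error comes from the delta method with gradient
$(e^s - e^{\beta_1},\, e^s - e^{\beta_2},\, e^s)$,
$s = \beta_1+\beta_2+\beta_3$, applied to the $3\times3$ coefficient
covariance block; the 95% interval uses the unrounded normal quantile
1.959964. A positive additive interaction requires both the estimate
and the interval's lower bound to exceed 0.

*Multiplicative.* The ratio of odds ratios
$\mathrm{OR}_{11}/(\mathrm{OR}_{10}\mathrm{OR}_{01}) = e^{\beta_3}$,
judged by a two-sided Wald test of $\beta_3 = 0$; positive
multiplicative interaction requires $e^{\beta_3} > 1$ and $p < 0.05$.
Whether a Wald, likelihood-ratio or penalized-likelihood-ratio p-value
is meant was an open design choice; Wald was selected because it is
what the reported covariance directly supports.

A combination is a **signal** when either scale fires. No
multiple-testing correction is applied by default (each test is run at
$\alpha = 0.05$, matching the discovery-driven design);
`results_table(..., adjust_p = "BH")` adds a Benjamini–Hochberg column
for users who want it, without altering the verdicts.

### Events per variable

A triple is analyzable only when the number of outcome-positive
reports divided by the number of non-intercept parameters is at least
5. The parameter count is 7 (drug A, drug B, interaction, age group,
gender, two drug-count dummies), so at least 35 events are required;
the boundary is inclusive. "Variable" counting was unspecified in the
source design; counting fitted non-intercept parameters is the reading
that matches the model above, and both the threshold and the
denominator are configurable in `cohort_config()`.

### Age and gender disparity

For each signal triple, a Firth model of the outcome on the stratum
indicator (over-65, or male), adjusted for the other demographic, the
drug-count dummies and both drug indicators, is fit over the triple's
full analysis rows. This is a deliberate resolution of an ambiguity:
the natural-seeming alternative — modelling within co-exposed reports
only — makes the drug-use adjusters constant and unidentifiable. The
per-stratum counts reported alongside the odds ratio are tallied among
co-exposed outcome-positive reports, which is how such tables are
conventionally displayed. A p-value below 0.05 marks the signal as
age- or gender-specific.

## Cohort construction

* Reports are selected by exact, case-insensitive,
  whitespace-normalized matching of indication terms against a narrow
  SMQ term list (`default_covid_smq_terms()`); no fuzzy matching.
* Adverse event PTs roll up to their primary HLT; duplicate PTs under
  one HLT collapse. HLTs under six nonspecific SOCs (injuries/
  procedural complications, social circumstances, product issues,
  procedures, investigations, general disorders/administration site
  conditions) are excluded.
* Drug A candidates are the cohort-observed members of the configured
  COVID-19 treatment list; the co-medication side is *every*
  cohort-observed ingredient, so two treatment drugs can pair with
  each other (both orientations are analyzed; pairs are deduplicated
  to unordered form at evaluation time). A drug never pairs with
  itself.
* Reports missing age or gender are excluded from analysis rows
  (complete case) because every covariate of the model is required;
  the exclusion count is kept on each triple.

## Ingestion conventions

Quarterly tables are `$`-delimited with headers; the delimiter is
configurable. Deduplication keeps, per case, the record with the
highest case version, breaking ties by the highest `primaryid` —
deterministic and idempotent. Ages convert to years as YR×1, MON÷12,
WK÷52.14, DY÷365.25; unknown unit codes become missing age (tallied).
Exactly 65.0 years falls in the elderly group. Verbatim drug names are
matched case-insensitively after whitespace normalization; unmapped
names are dropped from the ingredient set while the report is kept,
and coverage is reported as the mapped fraction of name occurrences.

## Reference evaluation and the empirical p-value

Signal pairs are compared with a graded reference DDI table
(unordered pairs; grades `no_interaction`, `potential_weak`,
`potential`, `do_not_coadminister`). "Documented" means any grade but
`no_interaction`. The Monte Carlo empirical p-value draws, in each of
$n$ simulations, as many distinct unordered (treatment,
co-medication) pairs as were observed, uniformly without replacement
from the cohort's candidate universe (self-pairs excluded), and
counts the simulations whose documented overlap is at least the
observed one (ties count — conservative):
$p = (r+1)/(n+1) \in [1/(n+1),\, 1]$. The original shuffling scheme
was under-specified; uniform sampling of distinct pairs is the
simplest reading that preserves the pair count and the bipartite
structure, and the sampler is isolated so alternatives can be
plugged in.

## The synthetic generator

`generate_reports()` draws reports from exactly the model the pipeline
fits: independent Bernoulli drug exposures, demographics with the
published cohort's marginals (52.7% male, 46.25% aged 65+), and
adverse events from the logistic model with planted
$(\beta_1,\beta_2,\beta_3)$ per (A, B, E) and shared covariate
effects. Defaults, chosen once as the study conditions:

* 10,000 reports — the operating point at which a planted
  $\beta_3 = \ln 2$ is recoverable with power $\ge$ 0.8;
* exposure probabilities 0.08–0.20, echoing the usage shares of the
  most-reported treatments;
* baseline AE logit $\mathrm{logit}(0.05)$ — the rare-outcome regime
  the OR-for-RR approximation in the RERI assumes;
* 80% of reports carry a COVID-19 indication (the rest are background
  reports the SMQ filter must reject);
* two planted interactions — one strong ($\beta_3 = \ln 2$) and one
  moderate ($\ln 1.8$) — all other drug effects null;
* 2% missing age and gender; 10% of cases get superseded earlier
  versions; 5% junk unmapped drug rows.

`generate_fixture_tables()` writes the generated reports back out in
the raw quarterly dialect with deliberately messy verbatim names,
planted duplicate case versions and unmapped junk rows, plus the
mapping fixtures (name map, MedDRA slice, graded reference table, ATC
level-1 map), so ingestion is testable end to end; reading the files
back reproduces the generated report set exactly.

What the generator does **not** emulate — and what passing tests
therefore cannot show about real reporting data: under- and
stimulated reporting, correlated co-prescription (exposures are
independent by default), within-report correlation of adverse events,
free-text drug-name chaos beyond the planted variants, and duplicate
reports that are not case-version duplicates. One seed fixes the
entire stream; the fixture writer derives its sub-stream from
`seed + 1`.

## Numerical choices

* Convergence: max |modified score| < 1e-6 and max |step| < 1e-6,
  at most 50 iterations, up to 10 step-halvings per iteration.
* Constant design columns are dropped with a warning before fitting;
  a constant interaction column aborts the triple with a recorded
  reason (the effect is unidentifiable).
* Rank-deficient designs after drops raise an error naming the
  aliased columns.
* Percentages in summary tables are rounded half-up to two decimals
  (base `round()` is round-half-even).
* Empty inputs degrade cleanly: an empty cohort yields an empty
  summary, an unreachable EPV threshold yields a clean run with zero
  triples, and an empty signal set yields an all-zero concordance.

## Problem sizes used in the shipped checks

The test-suite simulations use 2,000 null triples of 2,000 reports for
the calibration of the multiplicative test, 200 replicates of 10,000
reports for interval coverage of a planted $\beta_3 = \ln 2$, a
2,000-replicate parametric bootstrap for the delta-method standard
error, 22 tiny all-binary datasets (including separated ones) for the
grid-search cross-check of the fitter, and full pipeline runs of
1,500–10,000 synthetic reports. The numbered scripts under `analysis/`
run the default 10,000-report study end to end.

## Limitations

Signals are disproportionality-style hypotheses: no causal claim, no
incidence, no dose or route information, and confounding beyond age,
gender and drug count is unaddressed. The EPV rule filters triples by
event count only; a retained triple can still have an empty
co-exposure cell (Firth keeps it estimable, but intervals are wide).
The reference-table comparison inherits every limitation of the
reference itself, and the empirical p-value conditions on the observed
number of pairs.
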