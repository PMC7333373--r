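---
title: "Entropy-based epistasis screening: models, choices and limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Entropy-based epistasis screening: models, choices and limits}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(episcreen)
```

## The analysis in one paragraph

The package screens a case-control cohort — binary bronchodilator
responder status against eight dichotomized clinical, environmental
and psychosocial predictors — for synergistic interactions using
information gain, an entropy statistic that measures how much of the
outcome's uncertainty a *set* of predictors explains beyond the sum of
its parts. Because the statistic has no model for covariates, a
confounder (age) is removed beforehand by local case-control
subsampling; because its null distribution is awkward analytically,
inference is by permutation with Bonferroni familywise control; and
because the field's default is logistic regression, every hit is also
refit as a multiplicative-interaction regression model for comparison.

## Statistics and their conventions

All entropies are plug-in (maximum-likelihood) estimates in base-2
logarithms, so for a binary class $H(C) \le 1$ bit and information
gain lies in $[-1, 1]$. Plug-in estimation is biased upward for sparse
tables; no bias correction is applied because the permutation null is
computed with the same estimator and therefore absorbs the bias. The
percent form reported next to every statistic is
$100 \times \mathrm{bits} / H(C)$ — "percent of class entropy
explained" — with raw bits always co-reported, since for a near-balanced
cohort ($H(C) \approx 1$) the two conventions are nearly
indistinguishable and the literature rarely states which it prints.

The three-variable gain subtracts, by default, only the *positive*
(synergistic) pairwise gains:
$IG_3 = MI(\{P_1,P_2,P_3\};C) - \sum_{\text{pairs}} \max(IG_2, 0) -
\sum_i MI(P_i;C)$. The alternative — subtracting raw pairwise gains,
as a literal reading of the defining formula would have it — is
available via `clamp_synergy = FALSE`. The two differ exactly when a
pairwise gain is negative, i.e. when two predictors are redundant; the
clamped form then refuses to *credit* the triple for redundancy among
its parts, which is the behavior described in the method's prose and
the one that remains sensible under extreme predictor correlation.
The discrepancy between formula and prose is deliberately surfaced as
a flag rather than silently resolved.

Permutation p-values use the add-one estimator
$p = (1 + \#\{IG^{perm} \ge IG^{obs}\}) / (B + 1)$ with ties counted
toward the null: it never returns 0, and at the default $B = 1000$ its
smallest value is $1/1001 \approx 0.001$, matching the granularity at
which such screens are reported. One permutation set is shared across
all models of a family (main effects, pairs, triples are three
separate Bonferroni families with $m = 8, 28, 56$), which removes
between-model Monte-Carlo noise from comparisons at the price of
correlated p-values — the right trade for a screen whose output is a
ranked table. The test is one-sided toward synergy: negative
(redundant) gains are reported but never classed significant.
Critical values are also reported rounded to one significant digit
(0.006, 0.002/0.004, 0.0009/0.002) because that is how such
thresholds are printed and compared in practice.

## Confounder removal

The local case-control device: fit a pilot logistic model of the
outcome on the confounders only, then keep each observation with
probability $|y_i - \tilde p_i|$. Observations the pilot predicts well
are discarded; in the retained subsample the pilot's effect is
cancelled, so an analysis with no covariate machinery can run
unadjusted. Operationally the package asserts the acceptance
probabilities' $[0,1]$ bounds, makes exactly one Bernoulli draw per
call (the subsample size is an outcome, not a target), and refits the
pilot on the subsample as a balance diagnostic — the residual slope
should be statistically indistinguishable from zero, and the
acceptance suite requires this in at least 90% of 100 draws on a
strongly confounded cohort of 20,000. Age remains available as a
dichotomized *predictor* in the screen even after adjustment: the
roles are independent.

A note on seeding: every randomized operation derives its RNG state
from a hash of the user's seed and a purpose tag. Seeding logically
independent draws with raw nearby integers is a real hazard — two
operations at the same raw seed consume the *same* uniform sequence,
which can correlate, say, a predictor column with a subsampling
decision strongly enough to fabricate an interaction.

## The regression arm

Each screen hit is refit as
`outcome ~ age + mains + all products` (5 columns for a pair, 9 for a
triple, age continuous). Before fitting, the design is screened for
complete and quasi-complete separation with a two-stage linear
program (a separating direction exists iff the first LP's optimum is
positive; separation is complete iff a strictly separating direction
exists) and for multicollinearity via VIFs and the condition number of
the column-equilibrated design (flag levels 10 and 30; flags annotate,
they never drop models — except exact aliasing, e.g. an empty
interaction cell, which makes the model not assessable). Maximum
likelihood refuses separated designs, mirroring analyses reported as
"could not be assessed"; Firth's bias-reduced fit (Jeffreys-prior
penalized likelihood) is dispatched automatically when any cell of the
interaction cross-classification holds fewer than 5 observations or
separation is detected. "Fewer than 5 per cell" is interpreted on
*observed* counts of the component-variable cross-classification.

The Firth solver is Newton iteration on the modified score
$U^*(\beta) = X'(y - p + h(1/2 - p))$ with step-halving on the
penalized log-likelihood, convergence at $\max|U^*| < 10^{-8}$, at
most 200 iterations, and a line search that never accepts a
penalized-likelihood decrease. Its p-values are penalized
likelihood-ratio tests (refit without the term), the convention of
bias-reduced practice; Wald p-values are co-reported. On a saturated
2×2 design the Firth optimum coincides with adding ½ to every cell,
which gives the test suite a closed form to verify the optimizer
against (to 1e-6, including separated tables).

## What the generator emulates — and what it does not

`cohort_spec()` defaults encode the study conditions: $n = 617$
pre-adjustment; age truncated-normal with mean 14, SD 3 on [8, 21]
years; a confounder slope of 0.2 log-odds/year (visible but not
pathological at that size — the acceptance checks use 1.0/year where
they need strong confounding); baseline responder prevalence 118/233;
and the seven sampled predictor margins taken from the age-adjusted
descriptive table (female 42%, ancestry ≥ 80% 149/233, obese 86/233,
EOD 114/233, PSE 40/233, medium/high SES 154/233, NO₂ ≥ median
116/233). `age_hi` is derived by median-splitting the drawn ages
rather than sampled, so its within-cohort construction matches the
dichotomization rule. Interactions are embedded as penetrance tables
— maps from predictor-value combinations to outcome probabilities —
whose exact population information gain `population_ig()` computes by
enumerating the joint distribution; this is the oracle that
parameter-recovery tests compare sampled statistics against. A
continuous `bdr_pct` consistent with responder status (truncated
normals on either side of the 12% threshold) supports the post-hoc
summaries.

What the generator does *not* model: correlations between predictors
(margins only — real EOD, SES and NO₂ are surely dependent),
age→predictor paths (confounding enters only through the outcome),
measurement error in questionnaire items, and any spatial or family
structure. Green tests therefore certify the machinery — calibration,
parameter recovery, confounder removal — under independence, not that
real-data conclusions transfer.

## Numerical and degenerate-input choices

- $0 \log 0 := 0$ throughout; entropy of an all-zero count vector is
  an error, not 0.
- Median splits code ties upward (value = median → 1); an all-equal
  column becomes constant 1 and is excluded from screens as degenerate,
  with a warning.
- The SES composite is the sum of three 0–2 indicators with a
  configurable low-SES cutoff (≤ 1 by default); the aggregation is a
  package convention, recorded in the rule object.
- BDR outliers are fenced at mean ± 4 SD by default (configurable),
  with an exclusion log.
- 2×2 chi-squared tests use the Yates continuity correction — the
  convention validated by reproducing all six reference demographic
  p-values from their printed counts (the uncorrected versions do
  not).
- Two-group proportion tests dispatch to Fisher's exact test when any
  observed cell is below 5; the rank-sum test is exact for small
  untied samples, normal-approximated with tie correction otherwise.
- Permutation tie-counting uses a 1e-12 absolute tolerance so that
  statistics equal up to floating-point noise count as ties.
- The LP separation test poses both programs with ≤-constraints and
  nonnegative right-hand sides so the all-slack basis is feasible — a
  formulation chosen for numerical robustness of the simplex
  implementation used; verdicts are cross-checked against brute-force
  search on tiny designs in the tests.

## Problem sizes in the test and acceptance suites

The suites are sized to certify correctness quickly rather than to
maximize statistical resolution: exhaustive truth tables (4–16 rows)
for exact oracle values; all ~4.9×10⁷ contingency tables with total
≤ 30 for kernel-vs-oracle equivalence (vectorized, minutes); 1000
replicate null cohorts at n = 233 with B = 199 for calibration; 100
subsample draws at n = 20,000 for confounder removal; 500 replicate
cohorts at n = 233 with B = 999 for the power comparison, with the
embedded effect anchored to the reported headline interaction
strengths (pairwise 2.78%, three-way 2.39% of class entropy) at the
default margins. On the power question the package takes no side
beyond what those runs compute: at the pairwise order, where a
penetrance XOR is exactly a multiplicative-logit interaction, the
permutation screen and the interaction-term regression perform
near-identically; the entropy screen's advantage appears at the
three-variable order, where the regression model must estimate nine
parameters from sparse cells.

## Known limitations

Orders above 3 are out of scope, as are continuous (differential)
entropies — dichotomization is assumed done, with its usual
information loss. The screen's families assume all predictors are
usable; degenerate columns shrink the family and the Bonferroni m
accordingly. Firth p-values for very large designs refit once per
term and scale accordingly. GraphML and DOT exports carry nodes and
pairwise edges only (hyperedges have no standard encoding there; JSON
round-trips everything).
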