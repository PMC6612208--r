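---
title: "Combining AHP priorities with Likert satisfaction: methods and design notes"
author: "ahpgap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Combining AHP priorities with Likert satisfaction: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ahpgap)
```

## The problem

Health technology assessment (HTA) weighs a candidate technology across
clinical, technical, organizational, economic, social, ethical and legal
dimensions at once. `ahpgap` implements a two-instrument survey design for
this problem: the analytic hierarchy process (AHP) elicits how much each
evaluation criterion *matters* to a panel of experts, and a Likert
questionnaire measures how *satisfied* the same panel is with each
criterion today. The two are then joined in an importance–satisfaction gap
analysis: criteria that carry a large AHP weight but a low satisfaction
index are where improvement effort pays off most.

The package's running worked example is an assessment of a thyroglobulin
(Tg) assay in thyroid-cancer care, comparing the incumbent cytological
analysis against two fibre-optic biosensors (a lab-on-fibre tip sensor,
LOF, and a long-period-grating sensor, LPG), across five criteria broken
into fourteen sub-criteria. All of its printed matrices and weights are
reproduced by the test suite.

## The AHP model

For the children of each node of the decision hierarchy (the five criteria
under the goal; the sub-criteria under each criterion), each respondent
supplies pairwise judgments on Saaty's 1–9 ratio scale: \(a_{ij}\) says how
many times more important child \(i\) is than child \(j\); the mirrored
comparison is the exact reciprocal \(1/a_{ij}\).

**Group aggregation.** The \(N\) respondents' judgments for one pair are
combined by the weighted geometric mean
\(\prod_k a_k^{\beta_k}\) with \(\beta_k = 1/N\) by default — the N-th root
of the product, computed in the log domain. The geometric (not arithmetic)
mean is the right aggregate on a ratio scale: it commutes with taking
reciprocals, so the aggregated matrix is reciprocal by construction. The
aggregate is then rounded to the nearest Saaty value. Rounding is applied
only on the \(\ge 1\) side of each pair and mirrored, because rounding both
directions independently would break reciprocity; halves round up (the
convention is configurable in `round_to_saaty()`'s documentation sense —
it is fixed here and stated). A `rounding = FALSE` mode keeps the raw
geometric means, since rounding discards information; the default follows
the printed worked-example matrices, which hold integers and unit
fractions only.

**Priorities.** The priority vector of a comparison matrix is its
principal (Perron) eigenvector. `principal_eigen()` uses the dense
`eigen()` decomposition — every matrix here is at most 9×9 — with a power
iteration (tolerance 1e-10) as fallback, and reports the raw eigenvector
at unit Euclidean norm; `normalize_weights()` rescales it to unit sum.
The unit-2-norm convention for the raw vector matches the worked example,
whose printed raw eigenvector has sum of squares ≈ 1.

**Consistency.** Judgments need not be transitive; the consistency index
\(CI = (\lambda_{max} - n)/(n-1)\) and consistency ratio \(CR = CI/RI(n)\)
quantify how far they are from a rank-one consistent matrix
(\(\lambda_{max} = n\), \(CR = 0\)). The random index table is Saaty's
standard one (0.58, 0.90, 1.12, 1.24, 1.32, 1.41, 1.45 for \(n = 3..9\));
\(RI(5) = 1.12\) is the value the worked example uses. For \(n \le 2\) a
reciprocal matrix is always consistent and CR is defined as 0. The
conventional acceptance cutoff is \(CR \le 0.1\); because ratios somewhat
above 0.1 are tolerated in practice, `assess_node()` warns and annotates
by default and only rejects in `strict` mode.

**Propagation and synthesis.** Each sub-criterion's global weight is its
local (sibling-normalized) weight times its parent criterion's weight, so
leaf globals sum to 1. When per-alternative local weights are available
for every leaf, each alternative's final priority is the sum over leaves
of global leaf weight × local alternative weight. Totals are deliberately
*not* renormalized by default: the worked example's printed contribution
lists sum to ≈ 1.11 across alternatives, and reporting raw sums keeps
every printed summand auditable. `normalize = TRUE` gives the unit-sum
view. One printed contribution list (the incumbent's) totals 0.343 when
summed although a different total is printed alongside it; the package
always reports the sum of the list it is given.

## Indicator models

Where operational data exist, the local weights of the alternatives under
each sub-criterion come from twelve operational indicators plus two static
score panels, computed by `compute_indicator_panel()` over a window of
per-timestep records:

* window **sums**: executed exams (technological efficiency; also the
  social-respect indicator, which counts the same examinations), exams
  queued for faults (reliability), net profit (usefulness/profit — the
  two names denote the same economic sub-criterion and the package uses
  one label), side-effect exams plus effective-with-error exams (side
  effects), ethically refused exams, surgeon- plus patient-side (ethical
  respect);
* window **ratios**, aggregated as sum/sum over the whole window and
  divided once: executed/planned daily exams (procedural complexity),
  MON / net revenues (ROS), effective tests / incoming requests
  (effectiveness). Aggregating before dividing weights every timestep by
  its volume and avoids instability when single-timestep denominators are
  small; a per-timestep-then-average variant was considered and rejected
  as the default for that reason;
* **clinical efficiency** as (exams needing no additional withdrawals +
  exams needing no further investigation) − (exams requiring further
  withdrawals); the bracketing follows the prose definition (exams without
  repetitions minus exams with repetitions);
* **staffing** as medical specialists + biologists (window mean of a
  near-constant field);
* static panels: technological safety as the sum of five 1–10 scores
  (10 best), legal respect as the sum of six 1–10 scores (1 best), and
  investments as investment / purchase cost.

Each indicator carries an orientation. Benefit-type indicators normalize
proportionally across alternatives (\(w_i = v_i/\sum v\)); cost-type
indicators (reliability, procedural complexity, side effects, ethical
refusals, legal score) are inverted by reciprocal first, with an epsilon
floor of 1e-9 guarding zeros. Reciprocal inversion is the standard
ratio-scale treatment and makes cost weights exactly the benefit weights
of the reciprocal values (a tested duality); max-minus-value is the usual
alternative and changes only the spread, not the ordering.

## Likert scoring

The 13-item questionnaire is scored on a 5-point agreement scale (the
scale width is configurable from 4 to 7 for reuse; 5 including
"uncertain" is what the instrument uses). Items 4, 8, 12 and 13 are
reverse-coded: strong agreement scores 1, so a reverse score is always
\(k + 1\) minus the direct score — an exact involution the tests check on
every category. Per item the package reports category percentages, the
mean score, and a satisfaction index \((\mathrm{mean} - 1)/(k - 1)\) in
[0, 1]. Missing answers are dropped item-wise and the per-item respondent
count is reported.

Items map to sub-criteria through the codebook: two staffing items both
inform human resources, and the single cost-adequacy item informs all
three economic sub-criteria; a sub-criterion with several items takes
their mean index. This many-to-many mapping is the package's design
choice — the instrument has 13 items against 14 sub-criteria, so a pure
bijection is impossible.

## Gap analysis

`importance_satisfaction()` joins global AHP weights with satisfaction
indices, cuts both at their medians by default (the source analysis
speaks only of "high" and "low"; medians make that reproducible, and both
cutoffs are configurable and echoed in the output), labels the four
quadrants, and ranks improvement priority by
\(\mathrm{importance} \times (1 - \mathrm{satisfaction})\) — zero when
satisfaction saturates, monotone in importance and in dissatisfaction.
Only high-importance/low-satisfaction items are flagged `improve`.

## The synthetic study generator

The original 80-expert survey is not deposited, so the package ships a
generator with known ground truth instead; it is first-class, tested
code, and the frozen `paper_scenario()` is the default test bed: the
worked example's hierarchy, its eigenvector weights as the truth at every
node, N = 80 respondents, log-normal judgment noise 0.3, satisfaction
means following the reported pattern (high for technological safety,
staffing, side effects, social respect at 4.3; moderate 3.8; low 2.8 for
the clinical-efficacy, cost-adequacy and duration items), and operational
rates under which the LPG biosensor beats cytology on effectiveness and
reliability — roughly a dozen incoming exams per timestep with
realistic execution, repetition and margin fractions.

* **Judgments**: respondent k's answer for pair (i, j) is
  \((w_i/w_j)\,e^\varepsilon\), \(\varepsilon \sim N(0, \sigma^2)\),
  clamped to [1/9, 9] and Saaty-rounded. Multiplicative log-normal noise
  respects the ratio scale and keeps each respondent's matrix reciprocal.
  At noise 0 the aggregated group matrix equals the Saaty-rounding of the
  truth-ratio matrix *exactly* — every recovery error is then
  attributable to the rounding map itself, which is how the end-to-end
  recovery tests are phrased. (Rounding error is not negligible: the
  worked example's criteria weights span a 12:1 ratio that clamps to 9,
  displacing the recovered economic weight by ≈ 0.03.)
* **Likert answers**: discretized-normal draws on 1..k with the item's
  true mean and dispersion; reverse items are emitted mirrored on the
  agreement scale so downstream scoring recovers the intended
  satisfaction.
* **Timesteps**: Poisson arrivals thinned binomially into executed,
  effective, repeated, side-effect and error counts — so effective tests
  never exceed incoming requests — with Poisson fault and refusal
  processes and margin-based financials.

All three generators are pure functions of (scenario, seed) and restore
the caller's RNG state.

What the generator does *not* emulate: correlated judgments between
respondents or between nodes, systematic respondent bias, item
non-response patterns, and seasonal structure in the operational series.
Passing the recovery tests therefore shows the pipeline is correct and
well-calibrated under independent noise, not that it is robust to every
failure mode of real survey data.

## Numerical choices and problem sizes

Tolerances: matrix reciprocity and weight sums are enforced at 1e-9;
eigen/power-iteration agreement is tested at 1e-9; the three WGMM
formulations agree to 1e-12. Stochastic test tolerances were frozen from
a 100-replicate pilot: raw-WGMM eigenvector recovery at noise 0.3, N = 80
stays within 0.05 L1 of truth (pilot max 0.035), and mean L1 error falls
monotonically over N = 5, 20, 80. The suite runs its replicate loops at
30 seeds and timestep windows of 30–50 steps, which keeps the whole suite
in seconds while leaving the concentration margins wide.

Degenerate inputs: one-child nodes take local weight 1 without a
comparison matrix; all-zero indicator vectors are an error (no weight can
be defined); ties in every ranking are broken by config order, which
makes printed-table comparisons stable.

## Known limitations

* No fuzzy-AHP, ANP, interval judgments, or Delphi consensus rounds.
* No psychometric reliability analysis of the questionnaire (Cronbach's
  alpha, factor structure).
* The gap analysis is single-stakeholder: no weighting across respondent
  groups.
* Cost-effectiveness modelling (ICER/QALY) is out of scope; the economic
  sub-criteria are accounting indicators only.
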