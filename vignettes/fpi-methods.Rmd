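---
title: "Methods: the FPI instrument model, aggregation, comparison and synthetic data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: the FPI instrument model, aggregation, comparison and synthetic data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fpitools)
```

## The instrument as data

The Fishery Performance Indicators are a three-level hierarchy: 1–5 scored
*metrics* grouped into *dimensions* grouped into *indicators*, with the 68
outcome metrics carrying **two** dimension memberships — one under the
triple-bottom-line partitioning (Ecology / Economics / Community) and one
under the sector partitioning (Stock / Harvest Sector / Post-Harvest Sector).
The 54 enabling-factor metrics sit in a single hierarchy of 15 dimensions
under 5 input components. `fpitools` treats this structure entirely as data:
a packaged YAML definition (`fpi_default_schema_path()`) is the single source
of truth, and `validate_schema()` enforces the instrument's published
structural constraints — the 68/54/15/5 totals, the fixed TBL dimension
lists, the component→dimension memberships, five level descriptors per
metric, and the braiding being a total function on outcome metrics under each
partitioning. A faulty edit to the definition file therefore fails loudly
rather than silently shifting aggregates.

Two editorial choices deserve flagging, because the instrument's running
description fixes totals and several anchor memberships but not the complete
per-dimension metric lists:

- The per-dimension metric names and counts in the packaged schema are this
  package's transcription choices, constrained to satisfy every stated total
  and anchor (the Safety metric joins the sector Harvest dimension; the
  Support Industry metric joins Post-Harvest Processing & Support Industry;
  Trade maps to Market Performance and Product Form to Post-Harvest Asset
  Performance; Leadership and Social Cohesion are the Community input
  dimension; enforcement, shared stock, subsidies and management expenditure
  form Management Inputs). The validator pins all of these.
- The Ecology metric set and the Stock Performance metric set are taken to be
  identical (the single Ecology dimension maps one-to-one onto the sector
  Stock dimension). The instrument's description implies but does not state
  this; it is the default schema's assumption.

## Scoring

Metric levels are integers 1–5; a score may be missing (`NA`), and a missing
level may not carry a quality rating. Quality ratings follow the
instrument's definitions: A — highly confident the score is correct; B —
highly confident the true score is within one bin; C — an educated guess.

A few metrics are scored mechanically from a measured quantity through a
`threshold_rule`. The packaged crew-earnings rule scores the ratio *r* of
annual crew earnings to regional average earnings. The criterion text fixes
the band interiors ("within 10%", "more than 50% above", "less than half");
the ownership of each boundary point is a convention this package documents
explicitly: **an interval edge belongs to the band closer to the scale
midpoint**, so the level-3 band is closed (`|r − 1| ≤ 0.10`) and the extreme
bands are open (`r < 0.50`, `r > 1.50`), giving

| level | band |
|---|---|
| 1 | r < 0.50 |
| 2 | 0.50 ≤ r < 0.90 |
| 3 | 0.90 ≤ r ≤ 1.10 |
| 4 | 1.10 < r ≤ 1.50 |
| 5 | r > 1.50 |

The criterion text does not say which bands own exactly 0.50 and 0.90; the
convention above assigns both upward (toward the midpoint). Scoring is
deterministic, monotone in *r* for benefit-type rules, and surjective onto
1–5.

## Aggregation

For case $c$ and dimension $d$, with non-missing levels $L_m$ and quality
weights $w_{q(m)}$,

$$\mathrm{dim}(c,d) = \frac{\sum_m w_{q(m)} L_m}{\sum_m w_{q(m)}},$$

missing metrics excluded. Defaults: $w_A = 1$, $w_B = 0.6$, $w_C = 0.3$.
The instrument's description does not print a quality-weighting formula; it
reports only that quality-weighted rankings are practically indistinguishable
from unweighted ones, a property any reasonable decreasing weight vector
should reproduce — and which the test suite checks (Spearman correlation
between weighted and unweighted case rankings above 0.9 on synthetic data
with mostly A/B ratings). Setting $w_A = w_B = w_C$ reproduces unweighted
aggregation *exactly*, and this identity is tested, not merely approximated.
A scored metric with no quality rating receives weight 1 (`unrated_weight`,
configurable): an unrated score is a statement about metadata coverage, not
about confidence, so it is not down-weighted by default.

Indicator scores default to the **dimension mean** (each dimension
contributes equally regardless of its metric count), because the dimension is
the instrument's interpretive unit; `metric_mean` is retained as an option
for users who want metric-level flat averaging, and the two genuinely differ
whenever dimension sizes differ.

Missing data policy: a dimension with no scored metric is `NA`; a dimension
with coverage below `min_coverage` (default 0.5) is **flagged, never
dropped** — partial scoring is a designed-for condition of the instrument,
and silently discarding partial dimensions would bias group profiles.
Aggregates are mathematically contained in the range of their inputs; the
implementation clamps sub-epsilon floating-point excursions at the [1, 5]
boundaries so downstream binning never sees 5 + 2⁻⁵².

Color bins anchor the instrument's reading of the scale — 3 is the level
below which improvement should be considered — as red < 3 ≤ yellow < 4 ≤
green (configurable cutpoints).

## Rank-based comparison

Case rankings are descending by score with **average ranks** over ties, so
rank sums are always $n(n+1)/2$ and Spearman's $\rho$ is the Pearson
correlation of the average ranks.

`rank_sum_test()` implements the two-sided Wilcoxon/Mann–Whitney test with an
explicit exact/approximate policy:

- **Exact branch** — when $\min(n_1, n_2) \le 10$ and there are no ties, the
  p-value is computed by complete enumeration of all
  $\binom{n_1+n_2}{n_1}$ equally likely rank assignments;
  $p = 2\min(P(W \le w), P(W \ge w), 0.5)$, capped at 1. Enumeration is
  additionally bounded at $2\times10^6$ subsets so that a tiny sample paired
  with a very large one cannot request an infeasible enumeration; such cases
  use the approximation.
- **Approximate branch** — otherwise, the normal approximation with
  continuity correction 0.5 and tie-corrected variance
  $\sigma^2 = \tfrac{n_1 n_2}{12}\bigl[(n+1) - \sum_t (t^3 - t)/(n(n-1))\bigr]$.
  Ties always route here: mid-p exact tie handling is out of scope.

The switch point at 10 keeps toy comparisons exact while a 61-case
cross-section (roughly 30 per group) lands in the approximation, which is
accurate at that size. The test suite verifies the exact branch against the
Mann–Whitney distribution (`stats::pwilcox`) for *every* rank split with
$n_1, n_2 \le 6$, and the tie branch against `stats::wilcox.test`; these
library routines serve only as oracles, never as the implementation.

Group profiles (`group_dimension_means()`, `quality_profile()`) average
per-case dimension scores, and numeric quality values, within developed /
developing groups (or any user-supplied labelling). The quality map direction
is a documented choice — A→3, B→2, C→1, higher = better information — and is
configurable, since only the ordering, not the constants, is inherent to the
rating scale.

## The synthetic generator

`generate()` draws, per case, a latent Gaussian vector over all 122 metrics
from a shared-factor decomposition,

$$X_{im} = \sqrt{\rho_x}\,A_i + \sqrt{\rho_b-\rho_x}\,B_{i,k(m)}
         + \sqrt{\rho_w-\rho_b}\,C_{i,d(m)} + \sqrt{1-\rho_w}\,\varepsilon_{im}
         + \delta\,\mathbb{1}[\text{developed}],$$

so metrics within one dimension correlate at $\rho_w$, across dimensions of
one indicator at $\rho_b$, and across indicators at $\rho_x$; any
$\rho_w \ge \rho_b \ge \rho_x \ge 0$ is positive semi-definite by
construction, which is why the constraint is enforced rather than repaired.
Latents are cut at fixed cutpoints (default $\{-1.5, -0.5, 0.5, 1.5\}$ —
symmetric, all five levels attainable) into ordinal levels; quality labels
are drawn independently of levels (no coupling is documented for the real
instrument); scores are knocked out independently at `missing_rate`.
Everything is reproducible from a single seed.

Default parameters were chosen once, as the study conditions the generator
emulates:

| parameter | default | rationale |
|---|---|---|
| `n_cases` | 30/group | the scale of the instrument's initial cross-section (61 cases, two development groups) |
| `rho_w` | 0.6 | metrics in a dimension measure one construct: clearly correlated |
| `rho_b` | 0.3 | dimensions of an indicator cohere more weakly |
| `rho_x` | 0.1 | pillars are correlated but distinct |
| `delta` | 1.0857 | the latent shift whose *expected* ordinal gap is exactly one score level under the default cutpoints (solved by `latent_shift_for_level_gap(1)`; developed-country stocks score about one level higher) |
| `quality_probs` | A .45, B .35, C .20 | mostly confident ratings, as in real profiles |
| `missing_rate` | 0.05 | occasional unscorable metrics |

Note the $\delta$ calibration: a raw latent shift of 1 produces an expected
ordinal gap of only ≈ 0.93 levels because discretization attenuates shifts;
solving the expectation for a one-level gap is done analytically at
design time, not by tuning against test outcomes.

What the generator does **not** emulate — and what passing tests therefore do
not establish about real data: informative missingness (real gaps concentrate
in data-poor sectors), quality ratings correlated with scores or with
development status, per-metric marginal heterogeneity (all metrics share one
set of cutpoints), skewed or multimodal latent structure, and any causal
input→output linkage. Tests on synthetic collections validate the
*machinery* (aggregation algebra, test calibration, recovery of known
structure), not substantive claims about fisheries.

## Problem sizes and numerical checks in the test suite

The suite's statistical checks use sizes chosen to keep Monte-Carlo error
well inside their tolerances:

- rank-sum exactness: every rank split, all $n_1, n_2 \le 6$ (exhaustive);
- null calibration: 2000 replicate null collections, 30 cases/group, testing
  one 9-metric dimension's scores; rejection rate compared to 5% within 3
  binomial standard errors (±1.5 points);
- shift recovery: five collections of 200 cases/group; per-dimension gaps
  averaged over collections, within ±0.15 of one level on every outcome and
  input dimension;
- latent-to-ordinal attenuation: a 200,000-draw bivariate oracle at the same
  cutpoints, recovery within ±0.1.

## Known limitations

- The packaged metric lists are a faithful-but-editorial transcription (see
  above); per-dimension counts beyond the anchored ones should not be treated
  as canonical.
- Exact rank-sum p-values with ties are not implemented (tie-corrected
  approximation only).
- Quality ratings act as weights, not variances: no interval estimates on
  aggregates.
- No imputation of missing levels; coverage flags are the only missing-data
  signal beyond `NA` propagation.
- The CLI is a thin wrapper (`inst/cli/fpi.R`); it deliberately exposes only
  file-in/file-out operations of the library functions.
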