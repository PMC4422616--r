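# fpitools

Toolkit for the **Fishery Performance Indicators (FPIs)**, a rapid-assessment
instrument for evaluating fisheries against the triple bottom line (TBL) of
ecological, economic and community sustainability.

## The problem and the instrument

Most cross-fishery assessment frameworks measure stock status well and almost
nothing else: basic economic data (ex-vessel prices, harvest costs) and
community outcomes (earnings relative to local alternatives, local ownership,
career stability) are rarely collected, especially in data-poor fisheries and
in the post-harvest sector. The FPIs address this with structured expert
elicitation: **68 outcome metrics**, each scored on a discrete 1–5 scale
against level criteria (5 = best performance), rolled up into **dimensions**
and then into three **indicators** under either of two interpretive
*partitionings* of the same metrics:

- **TBL partitioning** — *Ecology* (1 dimension), *Economics* (6 dimensions:
  Harvest, Harvest Assets, Post-Harvest Assets, Risk, Trade, Product Form),
  *Community* (7 dimensions: Managerial Returns, Labor Returns, Health and
  Sanitation, Community Support Services, Local Ownership, Local Labor,
  Career);
- **Sector partitioning** — *Stock Performance*, *Harvest Sector Performance*,
  *Post-Harvest Sector Performance* (the "braiding": every outcome metric
  belongs to exactly one dimension under each partitioning).

Separately, **54 enabling-factor metrics** in **15 dimensions** across **5
input components** (Macro Factors; Property Rights & Responsibility;
Co-management; Management; Post-Harvest) describe management regimes and
exogenous conditions, kept apart from outcomes so that conjectured drivers are
never conflated with measured performance.

Each score also carries a **quality rating** — A (highly confident the score
is correct), B (highly confident the true score is within one bin), C
(educated guess) — which can be used as aggregation weights.

For a case *c* and dimension *d* with scored metric levels
`L_m ∈ {1..5}` and quality weights `w_q`:

```
dim_score(c, d) = Σ_m w_{q(m)} L_m / Σ_m w_{q(m)}        (missing excluded)
ind_score(c, I) = mean_d dim_score(c, d)                  (dimension mean)
```

Cross-fishery analytics are rank-based and nonparametric: average-rank case
rankings, exact (complete-enumeration) and tie-corrected normal-approximation
Wilcoxon/Mann–Whitney rank-sum tests `U = W − n₁(n₁+1)/2`, Spearman rank
correlation between indicator rankings, and group (developed vs developing)
dimension-mean and quality-metadata profiles.

A latent-threshold generator produces synthetic case collections with known
ground truth (nested block correlations within dimension/indicator, a latent
developed-vs-developing shift calibrated to an expected one-level gap,
A/B/C quality labels, random missingness), so the entire pipeline is testable
without transcribing any real scored dataset.

## Worked example

```r
library(fpitools)
s <- fpi_schema()
s
#> FPI instrument schema (version 1.0)
#>   outcome metrics: 68  enabling-factor metrics: 54
#>   tbl dimensions: 14
#>   sector dimensions: 11
#>   input dimensions: 15

# Threshold scoring: crew annual earnings at 1.60x / 1.05x / 0.40x the
# regional average map to levels 5 / 3 / 1
rule <- load_threshold_rules()$crew_earnings_vs_regional
score_from_thresholds(c(1.60, 1.05, 0.40), rule)
#> [1] 5 3 1

# A synthetic collection: 3 developed + 3 developing fisheries
cc <- generate(synthetic_params(n_cases = 3, seed = 7), s)
tab <- score_all(cc, s, weighting_scheme(), partitioning = "tbl")
head(as.data.frame(tab)[tab$node_level == "indicator", ], 3)
#>      case_id partitioning node_level   node_id    score coverage  flag  color
#> 1  synth_001          tbl  indicator   ecology 3.888889       NA FALSE yellow
#> 2  synth_001          tbl  indicator economics 4.160931       NA FALSE  green
#> 3  synth_001          tbl  indicator community 4.771331       NA FALSE  green

# Do developed cases outrank developing ones on Ecology?
rank_sum_test(tab$score[tab$node_id == "ecology"][1:3],
              tab$score[tab$node_id == "ecology"][4:6])
#> Wilcoxon/Mann-Whitney rank-sum test (exact)
#>   n1 = 3, n2 = 3, W = 7, U = 1, two-sided p = 0.2
```

Scores are means of 1–5 metric levels, so a dimension cell of 4.38 reads "well
above the improvement threshold of 3"; the `color` bin follows the
instrument's traffic-light reading (red < 3 ≤ yellow < 4 ≤ green).
`render_heatmap_table(tab, "ecology")` renders the table Fig-4 style with
cases sorted by Ecology, as text or single-file HTML, and
`inst/cli/fpi.R` exposes `validate` / `score` / `aggregate` / `compare` /
`simulate` / `report` subcommands.

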