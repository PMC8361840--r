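# evidemcda

Multi-criteria decision analysis (MCDA) for hospital drug appraisal with the
EVIDEM framework's 13-criterion quantitative core model.

Hospital pharmacy committees choosing among near-substitutable drugs need a
transparent way to combine effectiveness, safety, patient-reported outcomes,
costs and evidence quality into one appraisal. Under EVIDEM, each committee
member weights every criterion by importance (1–5) and scores each candidate
on each criterion — 0–5 for *absolute* criteria, −5..+5 against a comparator
for *relative* ones. With normalized weights `Wx` (unit sum) and standardized
scores `Sx = s̄/5`, each intervention's value estimate is the linear additive

```
V = Σx Vx = Σx Wx · Sx,   V ∈ [−1, 1]
```

The package provides: the validated core model and qualitative contextual
tool; panelist-level weight/score matrices with range validation, aggregation
(mean, n−1 SD) and CSV/JSON serialization; the value model with two explicit
policies for weighted-but-unscored criteria; ranking; Monte-Carlo
rank-stability analysis; a synthetic committee generator for end-to-end
testing; and a built-in worked example — the aggregated appraisal of five
DPP-4 inhibitors (anti-diabetic drugs) by a six-member hospital committee.

## Worked example

```r
library(evidemcda)

fx <- dpp4_panel()                 # committee tables: core model + aggregated panel
est <- compute_value(fx$panel)     # default policy: retain_weights
est
#> <mcda_value> policy = retain_weights, weight denominator = 41.7
#> # A tibble: 5 × 3
#>   intervention total n_criteria
#>   <chr>        <dbl>      <int>
#> 1 Saxagliptin   0.39         12
#> 2 Alogliptin    0.41         12
#> 3 Sitagliptin   0.44         12
#> 4 Linagliptin   0.43         12
#> 5 Vildagliptin  0.42         12

rank_interventions(est)
#> # A tibble: 5 × 3
#>    rank intervention total
#>   <int> <chr>        <dbl>
#> 1     1 Sitagliptin  0.438
#> 2     2 Linagliptin  0.430
#> 3     3 Vildagliptin 0.417
#> 4     4 Alogliptin   0.410
#> 5     5 Saxagliptin  0.393
```

Sitagliptin ranks first and Saxagliptin last, with all five totals inside a
0.05 band — the committee's "similar overall value" conclusion in numbers.
The totals sit about 0.01 below the committee's published 0.45–0.40 because
the published normalization is under-specified; the ordering is exact, and
the alternative `renormalize_excluding` policy is one argument away
(`compute_value(fx$panel, "renormalize_excluding")`). Broom-style accessors
(`tidy()`, `glance()`), `decompose_value()` and `autoplot()` expose
per-criterion contributions; `simulate_ranks(fx$panel, 10000, seed = 1)`
turns the SD columns into rank-acceptability probabilities.

A thin CLI wraps the same functions:

```sh
Rscript inst/cli/evidemcda.R report --policy retain_weights --draws 10000 --seed 1 --out report.json
```

## Layout

- `R/` — criterion models, panel containers/aggregation, valuation, rank
  stability, synthetic generator, pipeline/report.
- `inst/extdata/` — the aggregated DPP-4 committee tables (CSV).
- `inst/schema/report.schema.json` — structural contract of pipeline reports.
- `vignettes/mcda-valuation.Rmd` — methods and design notes.
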