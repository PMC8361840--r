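---
title: "Valuing interventions with the EVIDEM core model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Valuing interventions with the EVIDEM core model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(evidemcda)
library(dplyr)
```

## The appraisal problem

Hospital pharmacy committees must choose among near-substitutable drugs under
time pressure, weighing effectiveness, safety, patient-reported outcomes,
costs and the quality of the available evidence all at once. Multi-criteria
decision analysis (MCDA) makes that trade-off explicit: an appraisal committee
first states how much each criterion *matters* (weights), then judges how each
candidate *performs* on each criterion (scores), and a linear additive model
combines the two into a single value estimate per candidate.

`evidemcda` implements this workflow for the EVIDEM framework's quantitative
core model — 13 criteria in five domains — together with its 7-criterion
qualitative contextual tool (discussed deliberatively, never scored). The
package ships the aggregated appraisal of five DPP-4 inhibitors by a
six-member hospital committee as a worked example and test bed.

## The value model

Each committee member rates every criterion's importance on a 1–5 scale.
Per-criterion mean weights $\bar w_x$ are normalized to unit sum over the
included criteria,

$$W_x = \frac{\bar w_x}{\sum_{y} \bar w_y}, \qquad \sum_x W_x = 1 .$$

Performance scores come on one of two elicitation scales: *absolute* criteria
(disease severity, unmet needs, quality of evidence, ...) are scored 0–5 on
their own merits; *relative* criteria (comparative effectiveness, safety,
costs, ...) are scored −5..+5 against a comparator, negative meaning worse.
Mean scores are standardized by dividing by 5,

$$S_x = \bar s_x / 5 \in [-1, 1],$$

and the value estimate of an intervention is the weighted sum

$$V = \sum_x V_x = \sum_x W_x S_x .$$

$V$ is dimensionless, bounded by $[-1, 1]$, and lies in $[0, 1]$ whenever no
criterion is judged worse than the comparator. We deliberately divide both
scale kinds by 5 rather than min–max mapping −5..5 onto 0..1: the sign of a
comparative judgment is information (a negative cost contribution *should*
pull the total down), and a min–max rescaling would force all totals strongly
positive and mask harms. For the same reason "transformed to a 0–1 scale" is
realised here as the $W_x$/$S_x$ normalization itself, not as a post-hoc
min–max across interventions, which would pin the best and worst candidates
to 1 and 0 by construction.

## Missing criteria

Real committees skip criteria when no evidence exists. In the DPP-4 example
no scores were given for *other medical costs* and neither weight nor score
for *type of preventive benefit*. The arithmetic treatment of a weighted but
unscored criterion is genuinely ambiguous, so both readings are first-class:

* `retain_weights` (default): the criterion keeps its weight in the
  normalization denominator and contributes $S_x = 0$. The committee's stated
  importance still dilutes every other criterion's share.
* `renormalize_excluding`: the criterion is dropped before normalization and
  the remaining criteria absorb its share.

Both policies apply one denominator to all interventions, so the *ranking* is
identical under either; only the absolute level of $V$ moves. On the built-in
example `retain_weights` reproduces the published totals to within about
0.01, `renormalize_excluding` sits about 0.03–0.04 higher, and we default to
the former. We do not rescale further to force exact agreement: the published
computation's precise normalization is not recoverable from the tables, and
an honest near-miss is more useful than a tuned match.

```{r}
fx <- dpp4_panel()
est <- compute_value(fx$panel, "retain_weights")
est
rank_interventions(est)
```

Criteria with no weight at all never enter the sum under either policy —
there is no defensible share to assign them.

## Aggregation conventions

Panelist-level matrices aggregate to per-criterion means and sample standard
deviations with the $n-1$ denominator; the committee tables' printed SDs
(e.g. 0.52 for a mean of 4.33 over six panelists) match that convention.
Missing responses are explicit `NA`s, never zeros. Weights are stored as
possibly fractional values in $[1, 5]$: several published mean weights (3.58,
3.01, 4.01 over six members) are impossible as means of six integers, which
implies some upstream per-panelist rescaling; fractional storage keeps such
panels representable. Displayed numbers are rounded half away from zero to
two decimals to match committee-report formatting; full precision is kept
internally.

## Rank stability (an extension)

The deterministic appraisal hides how fragile the order is: the five DPP-4
totals span only 0.39–0.44. `simulate_ranks()` propagates the reported
dispersion through the model by Monte Carlo: each mean weight is resampled
from a normal truncated to $[1,5]$ and each mean score from a normal
truncated to its scale, by default with the standard error of the mean
($SD/\sqrt{n}$) as spread — the decision-relevant uncertainty is in the panel
mean, not in any single panelist. A `raw_sd` mode explores panel
heterogeneity instead. Criteria are resampled independently; no covariance
structure is reported and none is invented. This stage is a package
extension around the committee procedure, flagged as such, not a reproduction
of anything the committee did.

```{r}
st <- simulate_ranks(fx$panel, n_draws = 2000, seed = 1)
st$rank_probability
```

With the example's dispersions the top candidate's first-rank probability is
well below 1 — the "similar overall value" reading of the appraisal, made
quantitative. Truncated-normal draws use the inverse-CDF construction on
`stats::qnorm`, which is exact up to floating point and needs no rejection
loop.

## The synthetic committee generator

`generate_panel()` manufactures raw panelist matrices with the statistical
structure the pipeline assumes, so aggregation and valuation are testable end
to end without any real elicitation data. Scores are drawn from truncated
normals at the target (mean, SD), rounded to the integer scale, then a repair
pass nudges single entries one step at a time until the column mean is the
closest the integer scale allows (ties broken toward the target SD) — at
$n = 6$ an unrepaired rounded draw rarely hits targets like 4.67. Mean
targets are therefore hard up to the scale's resolution ($1/2n$); SD targets
are soft, matched in expectation over replicates, because exact integer
(mean, SD) solutions often do not exist at small $n$. A zero-SD target pins
every panelist to the rounded mean. Weights may be fractional and are
recentred on their target mean after truncation.

What the generator does *not* emulate: panelist-role effects (a doctor and a
health economist are exchangeable draws), inter-criterion correlation, and
any systematic elicitation bias. Passing parameter-recovery tests therefore
demonstrates that the pipeline's arithmetic is faithful under its own
assumptions — not that real committees behave like truncated normals.

## Problem sizes and numerical choices

The test suite checks oracle equivalence of the value model against an
independent brute-force summation on 1,000 random panels at tolerance
1e−12; parameter recovery aggregates 200 replicate six-member synthetic
committees (tolerance ±0.15, the Monte-Carlo error at $SD/\sqrt{6\cdot200}$);
rank-stability regression uses 10,000 draws. Weight normalization requires at
least one criterion that is both weighted and scored and a strictly positive
denominator; ties in ranking share the minimum rank and order alphabetically;
the degenerate all-zero estimate reports undefined (NaN) contribution shares
rather than inventing a split.

## Known limitations

* Value estimates combine panel *means* (mean-then-combine). Averaging
  per-panelist value estimates instead is supported when raw matrices are
  supplied (aggregate, then value), but published aggregated tables cannot be
  disaggregated.
* The published worked example's exact normalization is under-specified; the
  package reproduces its totals to ~0.01 and its ordering exactly, under two
  documented policies, and stops there.
* The contextual tool is carried as structured annotation only; deliberation
  is not modelled.
* No cost-effectiveness modelling, evidence grading, or elicitation UI.
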