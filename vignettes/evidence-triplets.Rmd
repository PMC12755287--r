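---
title: "Evidence triplets for two-arm binary trials: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Evidence triplets for two-arm binary trials: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pfrnb)
```

## The model

A two-arm trial with a binary outcome is summarised by a 2x2 table with
cells $\{a, b, c, d\}$ (events / non-events in arm 1, then arm 2), arm sizes
$n_1 = a + b$ and $n_2 = c + d$, and total $N$. pfrnb characterises the
evidence such a table carries along three 0--1 dimensions that are computed
independently and then combined:

* **Significance** — a two-sided p-value against the null of identical
  event probabilities, with significance declared at $p \le 0.05$
  throughout.
* **Fragility** — the *modified-arm fragility quotient*
  $\mathrm{MFQ} = \mathrm{FI} / n_{\mathrm{mod}}$, where the fragility
  index FI is the minimum number of single-patient outcome toggles inside
  one designated arm that moves the trial across the $p = 0.05$ boundary,
  and $n_{\mathrm{mod}}$ is that arm's size. MFQ near 0 means the
  significance label is precarious; MFQ = 1 means no achievable outcome
  change in the arm could flip it. The classical fragility quotient
  $\mathrm{FQ} = \mathrm{FI}/N$ is carried alongside; under 1:1 allocation
  $\mathrm{MFQ} = 2\,\mathrm{FQ}$, so the fragile/stable cut
  $\mathrm{MFQ} \le 0.10$ corresponds to $\mathrm{FQ} \le 0.05$, mirroring
  the 5% significance level.
* **Robustness** — the *risk quotient*
  $\mathrm{RQ} = |ad - bc| / (N^2/4)$, the absolute determinant of the
  table normalised by its maximum over all tables of size $N$. RQ is 0
  exactly on the neutrality boundary $ad = bc$ (identical event odds in
  both arms) and 1 at maximal separation. It is invariant to swapping the
  arms or relabelling event/non-event in both arms simultaneously.

Fragility and robustness are deliberately *not* opposites: fragility asks
how stable the decision label is, robustness how far the data sit from
no-effect. A small underpowered trial can be fragile yet strongly robust; a
very large trial can be stable yet hug the neutrality boundary.

### Evidence patterns

The triplet is collapsed to one of five mutually exclusive patterns:

| pattern | significance | stability | robustness |
|---|---|---|---|
| CP (concordant-positive) | $p \le 0.05$ | MFQ $> 0.10$ | RQ $\ge 0.227$ |
| SFW (significant-fragile-weak) | $p \le 0.05$ | MFQ $\le 0.10$ | RQ $< 0.075$ |
| concordant-null | $p > 0.05$ | MFQ $> 0.10$ | RQ $< 0.075$ |
| other-significant | $p \le 0.05$ | — | — |
| other-nonsignificant | $p > 0.05$ | — | — |

The two residual classes make the partition exhaustive, so pattern counts
always sum to the number of trials — a property the test suite asserts on
every dataset it touches.

## Tests and their selection

Two tests are implemented. *Fisher's exact test* uses the two-sided
minimum-likelihood rule: the p-value sums the hypergeometric point
probabilities, over all tables sharing the observed margins, that do not
exceed the observed table's probability (the dominant convention, and the
one `stats::fisher.test` uses; the suite checks exact agreement). *Pearson's
chi-square* is the uncorrected one-degree-of-freedom statistic
$\sum (O - E)^2 / E$. No Yates continuity correction is applied: the
uncorrected statistic is the plainly stated default, and the correction
would only push small-sample tables further from the exact test they are
already routed away from.

Which test runs depends on the analysis context:

* `context = "simulation"`: Fisher when $N \le 50$ or any cell $< 5$,
  Pearson otherwise. This keeps exactness where expected counts are small
  and the cheap closed form everywhere else.
* `context = "empirical"`: Fisher for most trials; Pearson only for large
  trials with $N > 5000$ and every cell $\ge 50$.

Both rules are re-applied to the *current* table at every step of the
fragility search, because a toggle can move a cell across the "$< 5$"
boundary. Records carry a `test_switched` audit flag when that happens
along the shortest toggle path.

## The fragility search

The modified arm is the arm with fewer events; an event-count tie goes to
the smaller arm, and a full tie to arm 1 (a deterministic convention —
the tie itself makes the arms symmetric). Toggling changes outcomes only
within that arm, so the family of reachable tables is parameterised by a
single integer: the modified arm's event count
$e \in \{0, \dots, n_{\mathrm{mod}}\}$. FI is the minimum
$|e' - e_{\mathrm{obs}}|$ over splits $e'$ whose significance
classification differs from the observed one. Because the reachable tables
form this one-parameter family, mixed toggle sequences can never beat the
best monotone sequence (all additions or all removals), so searching the
two monotone directions is exact; the implementation simply evaluates the
significance of the whole profile (vectorised for Pearson splits, per-split
enumeration for Fisher ones) and takes the nearest flip. An exhaustive
brute-force search over every achievable split, driven by independent test
routines, confirms equality for all tables with $N \le 40$.

Significant tables are toggled to nonsignificance; nonsignificant tables
get a *reverse* fragility index (toggles to reach significance) by the same
algorithm, so stability is defined on both sides of the 0.05 boundary.
When no achievable split crosses the boundary, FI is capped at
$n_{\mathrm{mod}}$ (`capped = TRUE`, MFQ = 1, maximally stable) — this
honours the 0-to-1 range of MFQ and arises for tables too small or too
one-sided to ever change classification.

### Numerical conventions

* A p-value exactly equal to 0.05 counts as significant. Because discrete
  exact p-values can equal 0.05 exactly (e.g. the table (38, 1, 0, 1)),
  while floating-point summation order can land the computed value a few
  ulps on either side, the comparison uses an absolute guard of $10^{-9}$ —
  far below the spacing of achievable p-values near 0.05 at any realistic
  sample size.
* The Fisher minimum-likelihood comparison uses the same relative
  tolerance ($1 + 10^{-7}$) as `stats::fisher.test`, so the two routes
  agree exactly.
* RQ's cell products are formed in double precision (integer products
  overflow beyond cells of roughly 50,000; trial collections can contain
  six-figure arms).

## Robustness thresholds

The weak/moderate/strong cuts 0.075 and 0.227 are the 33rd and 67th
percentiles of the RQ distribution from a prior large simulation over
realistic trial parameters (sample sizes 30--1,200, event rates 0.03--0.60,
relative risks 0.20--3.0). They are consumed as fixed named constants —
`rq_thresholds()` — and are overridable for sensitivity analyses; the
package does not re-derive them, since the deriving simulation's parameter
sampling scheme is not part of this package's scope. Boundary conventions:
weak is strictly below 0.075, strong is at or above 0.227, moderate is the
half-open band between.

## The Monte Carlo simulator

`default_grid()` encodes the factorial benchmark design: total sample sizes
60, 100, 200, 400, 800; allocation ratios 1:1, 2:1, 3:2; control event
rates 0.05, 0.10, 0.20, 0.40; true relative risks 1.00 (null), 0.90, 0.80,
0.70, 0.60, 1.10 — 360 scenarios, conventionally run at 2,000 replications
each (720,000 trials; the null subset contributes 120,000). Event counts
are binomial: the control arm draws $\mathrm{Bin}(n_2, \mathrm{CER})$ and
the intervention arm $\mathrm{Bin}(n_1, \mathrm{CER} \times \mathrm{RR})$;
the largest product, $0.40 \times 1.10 = 0.44$, stays a valid probability.
Simulated trials are analysed with `context = "simulation"`.

Conventions the design leaves open were fixed once and recorded here:

* **Arm roles.** The intervention is arm 1 and receives the larger share
  under unequal allocation (2:1 and 3:2 are read intervention:control).
* **Allocation rounding.** Arm 1 gets
  $\lfloor N r_1/(r_1+r_2) + 0.5 \rfloor$ (half-up), so 100 at 2:1 splits
  67/33.
* **Seeding.** One master seed initialises a draw stream that assigns each
  scenario its own sub-seed (`sample.int` under the master seed), so a
  scenario can be re-simulated in isolation and the full record stream is
  bit-identical for a given grid and master seed.

The simulator models unfiltered random trial generation only: no
publication bias, stopping rules, or selective reporting. Its pattern
prevalences are therefore *benchmark expectations* for what raw data
generation produces under a known effect — the baseline against which an
observed collection's enrichment is measured — not a model of the published
literature.

Two behaviours of the null benchmark are worth flagging. The significant
fraction under the null sits near 4%, below the nominal 5%, because
Fisher's exact test is conservative at the small expected counts the rule
routes to it. And the SFW share among significant trials is roughly flat
(about a quarter to a third) across all effect sizes: conditional on
landing just past $p = 0.05$, a trial tends to sit near both the
significance and neutrality boundaries regardless of the true effect, which
is what makes SFW a boundary phenomenon rather than a false-positive
detector.

## Summary statistics

Prevalences are reported as $k/n$ with 95% Wilson score intervals (the
score-test inversion; the normal quantile is computed for the requested
level, not hard-coded). Enrichment of an observed prevalence over a
simulated expectation combines an exact binomial test (two-sided
minimum-likelihood rule via `stats::binom.test`; a one-sided alternative is
available) with a fold elevation. The fold is reported twice: the raw ratio,
and a display variant that first rounds both proportions to one decimal on
the percentage scale — the convention that reproduces headline ratios
quoted from printed percentages (39.0% over 1.4% gives 27.9).

## The synthetic fixture generator

No published multi-specialty trial collection ships with the package, so
`generate_fixture_trials()` produces a synthetic stand-in: total sizes
log-uniform between configurable bounds (default 20--2,000, echoing the
heavy right skew of real trial collections at desk scale), control event
rates uniform on 0.05--0.5, allocations drawn from {1:1, 2:1, 3:2} with 1:1
most likely, and each trial's true relative risk drawn from a configurable
mixture of null and non-null effects chosen so that all five evidence
patterns occur (the generator verifies this and retries with an
incremented sub-seed a bounded number of times before erroring). What it
does *not* emulate: publication filtering, domain-specific event-rate
structure, extreme mega-trials, or any real collection's pattern
prevalences. Tests passing on fixtures therefore validate the machinery —
classification, summaries, I/O — and say nothing about what any real
literature sample contains.

## Problem sizes used in the packaged checks

The package's own benchmark checks run the null sub-grid (60 scenarios) at
1,000 replications per scenario and the non-null sub-grids at 500 — enough
that the Monte Carlo standard error of each checked prevalence is a few
tenths of a percentage point, small against the tolerance bands asserted,
while keeping a full run in minutes on one core. The exhaustive oracle
comparisons (Fisher p against direct enumeration, FI against brute-force
search) cover every table up to $N = 30$ and $N = 40$ respectively.

## Known limitations

* Only independent-sample two-arm binary designs: matched-pair and
  crossover layouts are out of scope, as are continuous, ordinal, survival
  and correlation outcomes (the neutrality-boundary construction
  generalises, but nothing beyond 2x2 tables is implemented or validated
  here).
* FI never toggles outside the modified arm, including when the search is
  capped.
* Recomputed p-values can differ from originally published ones (different
  test choices, corrections, or covariate adjustment in the source
  analyses); the classification is defined on the recomputed value.
* The triplet stratifies the statistical evidence in a table. It does not
  estimate effect size, prove causality, or predict replication.
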