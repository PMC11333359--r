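---
title: "Methods: disproportionality screening of spontaneous reports"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: disproportionality screening of spontaneous reports}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The model and its assumptions

Spontaneous-reporting data have no exposure denominator, so `pvsignal`
estimates nothing about incidence. Everything rests on one assumption:
under no association, a drug's share of reports mentioning a given event
should match its share of all other reports. Each (drug, PT) pair is
reduced to a 2×2 table — `a` (target drug and target event), `b` (target
drug, other events), `c` (other drugs, target event), `d` (the rest) — and
four estimators quantify the departure from that null. A pair is called a
positive signal only when **all four** criteria hold at once; the
conjunction is deliberately conservative, since each method alone is known
to be sensitive but noisy.

Three of the four statistics (ROR, χ², EBGM) are invariant to swapping `b`
and `c`; only the PRR's interpretation depends on the convention. We fix
`b` = target drug & other events, which is the convention under which
`PRR = [a/(a+b)]/[c/(c+d)]` reads as "the drug's event-reporting rate over
everyone else's".

### Counting unit

The 2×2 universe can be built from *mentions* (each (report, PT) row is one
unit; margins sum to total mentions) or from *reports* (each report counts
once per distinct PT, `N` = number of reports). Published analyses rarely
state which they used and the printed frequencies alone cannot
discriminate, so both are exposed (`unit = "mentions" | "reports"` in
`make_contingency()` and `screen_signals()`), with mentions as the default:
it is the convention under which every marginal identity holds exactly
(the per-drug `a` cells sum to the drug's total mentions), which makes the
pipeline's own bookkeeping checkable.

### Degenerate tables and zero cells

No Haldane/continuity correction is applied anywhere, because the estimator
definitions used here do not include one. A zero cell makes ROR and the
Woolf interval undefined (`NA`, flag `FALSE`); `c = 0` or `a+b = 0` makes
PRR undefined likewise. The BCPNN information component is the exception:
its priors keep every term positive, so the IC is finite for every table
with `N > 0`, including `a = b = c = 0`. The simplified EBGM point estimate
needs `a > 0` and positive margins; its lower bound shares the Woolf
standard error and therefore needs all four cells positive.

Two criterion readings were fixed here. The MGPS positivity condition is
stated in the source material as "`N > 0`"; read literally (total table
size) it is vacuous, so it is implemented as `a > 0` — the pair must
actually have been observed. The EBGM05 bound uses `z = 1.96` exactly as
printed even though it is described as a one-sided limit (a one-sided 95%
bound would use 1.645); we preserve the printed formula.

## Deduplication

FAERS re-submits cases across quarters, so deduplication is global over all
loaded quarters, with two rules:

1. a `primaryid` occurring on more than one raw row is a data error and
   **all** its rows are excluded;
2. among rows sharing a `caseid`, only the largest `primaryid` (latest case
   version) survives.

The rules' order is ambiguous in common practice; we detect primaryid
collisions on the **raw input**, before version selection. Rationale: a
collision marks rows as invalid, and invalid rows should not be allowed to
win (or lose) a version-selection contest first. The operation is
idempotent and order-invariant, which the test suite checks by property.

Alternative schemes used by other FAERS studies (e.g. keeping the latest
`FDA_DT` per case) are out of scope.

## Tunable parameters that matter

| parameter | where | default | why |
|---|---|---|---|
| `unit` | `screen_signals()` | `"mentions"` | see above |
| `n` (top-list size) | `top_signals()`, `heatmap_matrix()` | 20 | the conventional table size in published signal studies |
| `log_base` | `heatmap_matrix()` | `e` | the heatmap transform is `log(ROR+1)`; the source only says "logarithm", natural log is the default and the base is configurable |
| `n_countries` | `demographics()` | 4 | individually listed reporter countries; the remainder is Other/Missing |
| z for CIs | fixed | 1.96 | printed value; not configurable to avoid silently changing the criteria |
| age bins | fixed | `<18, [18,65), [65,85], >85`, missing | the printed bin edges; 65.0 falls in the 65–85 bin ("18 to <65") |

Percentages in emitted tables are rounded half-up to 2 decimals (the
printed style); base R's banker's rounding would disagree with printed
tables on exact halves, hence `round_half_up()`.

## The synthetic generator: what it emulates, and what it does not

`synth_generate()` produces DEMO/DRUG/REAC quarters in the exact dialect
the reader parses. Per report: one primary-suspect drug drawn from
configurable background shares; `1 + Poisson(λ_e)` PT mentions drawn from a
Zipf-like event-rate vector, where a planted (drug, PT) pair multiplies
that PT's rate by `λ` for that drug's reports; optional concomitant (role
`C`) drug rows to exercise role filtering; demographics with configurable
missingness. Duplicate case versions (same `caseid`, larger `primaryid`,
identical content) and colliding-`primaryid` error rows are injected at
configurable rates, constructed to be disjoint so that deduplication
recovers exactly `n_reports − n_error_cases` reports.

Because mentions are drawn i.i.d. given the suspect drug, the population
reporting odds ratio of any pair has a closed form (`expected_ror()`), and
for a drug with a single planted PT it equals `λ` exactly — the
renormalization of the event distribution cancels in the odds ratio. This
is what makes parameter-recovery testing honest: the target is analytic,
not simulated.

Default demographic distributions follow the printed margins of a real
insomnia-drug cohort (sex F/M/missing 0.55/0.33/0.12; age missing 0.60;
consumer/health-professional/other 0.75/0.24/0.01; country US/JP/other
≈ 0.92/0.07/0.01), and study-drug shares are 1–3% of reports, the order of
magnitude a recently marketed drug class occupies in the full database.
These are statements about the world being emulated and were fixed before
any acceptance measurement; they are not tuning knobs.

What the generator does **not** emulate: drug-name misspellings and free-text
noise, longitudinal case versioning beyond the two duplicate mechanisms,
correlated PT co-occurrence within a report (mentions are conditionally
independent), reporting-bias dynamics over time, and the outcome/therapy/
indication tables. A green recovery test therefore establishes that the
pipeline is correct *under the stated generative model* — not that real
FAERS data meet that model.

## Numerical and algorithmic choices

* All logarithms are taken in natural base internally; `log2` appears only
  at the IC interface. The IC formula is evaluated as a sum of logs, never
  as a ratio of products, so it cannot overflow at large `N`.
* Hierarchical clustering of the heatmap rows uses Euclidean distance and
  average linkage (`stats::hclust`). Leaf order is made deterministic: rows
  enter in alphabetical PT order, and at each merge the tighter (lower)
  subtree is placed first, with exact-height ties broken by the smallest
  row label. The ordering is therefore a pure function of the matrix
  content, which the suite checks by permutation.
* The heatmap row set is the **union** of the per-drug top-20 lists. The
  source material calls it an intersection while reporting more rows than
  any single list — only a union produces that; the union is implemented.
  Cells are `log(ROR+1)` where the PT is a detected (positive) signal for
  that drug and `0` otherwise, so the matrix is finite and non-negative by
  construction.
* Demographic "Overall" is reported twice: `overall_sum` stacks the
  per-drug groups (the convention under which the overall total equals the
  sum of the drug columns, matching how such tables are printed) and
  `overall_distinct` counts each exposed report once; they differ exactly
  when a report names two queried drugs as primary suspect.
* SOC frequencies count report-event occurrences (sums of `a` cells), not
  distinct PTs — the convention under which a drug's SOC total can exceed
  its report count, consistent with printed totals in this literature.
* No multiple-testing adjustment is applied: positivity is by the fixed
  thresholds above, as is standard for these four criteria.
* Drug-name matching is case-insensitive substring matching of the query
  keywords against `drugname` and `prod_ai` on PS rows only. Substrings
  (rather than exact equality) are needed because verbatim FAERS drug
  names carry dose and form suffixes.

## Known limitations

* The EBGM implemented is the simplified observed/expected form with a
  log-normal interval; it matches the printed formula set this package
  implements, but will not reproduce numbers from the full DuMouchel
  gamma-Poisson shrinker with EM-fitted hyperpriors.
* Disproportionality is unstratified; age/sex/era stratification (as in
  regulatory MGPS deployments) is not implemented.
* The PT→SOC rollup uses a single primary SOC per PT from a user-supplied
  table; MedDRA's multi-axial secondary assignments and intermediate
  hierarchy levels (HLT/HLGT) are out of scope.
* XML-format FAERS distributions are not parsed; only the ASCII dialect.
* Confidence-interval coverage statements for ROR rest on the Woolf
  normal approximation and degrade for very small cells; the criteria's
  `a ≥ 3` floor is the only guard.
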