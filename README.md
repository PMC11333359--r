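# pvsignal

Disproportionality-based signal detection for spontaneous adverse-event
reporting databases distributed in the FAERS quarterly ASCII format.

## What problem this solves, and for whom

Spontaneous-reporting systems such as the FDA Adverse Event Reporting System
(FAERS) collect millions of reports in which a suspect drug is linked to one
or more adverse events coded as MedDRA preferred terms (PTs). Because there
is no denominator of drug exposure, safety signals are mined by
*disproportionality analysis*: for every (drug, PT) pair, the pair's
reporting frequency is compared with the background of all other reports via
a 2×2 table

|              | target event | other events |
|--------------|--------------|--------------|
| target drug  | a            | b            |
| other drugs  | c            | d            |

`pvsignal` is for pharmacoepidemiologists and drug-safety analysts who want
this pipeline as tested, reusable code: reading the quarterly tables,
deduplicating cases, restricting to primary-suspect (PS) reports for a
queried drug, screening every PT with four standard statistics, and
producing the usual reporting surfaces (demographics, top-N signal tables,
per-method counts, cross-drug intersections, a clustered signal heatmap and
a PT→SOC rollup).

## The statistics

With `N = a+b+c+d`, the four estimators and their positivity criteria are:

* **ROR** (reporting odds ratio) `= ad/bc`, with the Woolf interval
  `exp(ln ROR ± 1.96·√(1/a+1/b+1/c+1/d))`; positive if the CI lower bound
  `> 1` and `a ≥ 3`.
* **PRR** (proportional reporting ratio) `= [a/(a+b)] / [c/(c+d)]` with the
  uncorrected Pearson χ² `= (ad−bc)²·N / [(a+b)(c+d)(a+c)(b+d)]`; positive
  if `PRR ≥ 2`, `χ² ≥ 4` and `a ≥ 3`.
* **BCPNN information component**, the closed-form shrunken log2
  observed-to-expected: with drug margin `m_d = a+b`, event margin
  `m_e = a+c` and `γ = (N+2)²/[(m_d+1)(m_e+1)]`,
  `E(IC) = log2[(a+1)(N+2)² / ((N+γ)(m_d+1)(m_e+1))]`, and
  `IC025 = E(IC) − 2·√V(IC)`; positive if `IC025 > 0`. The IC is finite for
  every table, including zero cells.
* **EBGM**, the simplified empirical Bayes geometric mean
  `= aN/[(a+b)(a+c)]` (observed/expected under independence) with a
  log-normal lower bound `EBGM05 = exp(ln EBGM − 1.96·√(1/a+1/b+1/c+1/d))`;
  positive if `EBGM05 ≥ 2` and `a > 0`. This is the printed simplified
  form, not the full gamma-Poisson mixture fit.

A (drug, PT) pair is a **positive signal** only when all four criteria hold
simultaneously — the conjunction trades sensitivity for a much lower
false-positive rate.

## Worked example

No real FAERS quarters are needed: the package generates its own, with a
planted association of known strength. Here a pair (`agent_a`, `pt_010`) is
planted with rate multiplier 8, which makes the population reporting odds
ratio exactly 8.

```r
library(pvsignal)

cfg <- synth_config(
  n_reports = 20000,
  planted = data.frame(drug_label = "agent_a", pt = "pt_010", lambda = 8),
  seed = 42)
gen <- synth_generate(cfg, dir = "faers_synth")   # writes DEMO/DRUG/REAC quarters

raw   <- read_quarter_dir("faers_synth")
cases <- parse_demo(raw$demo)
ds    <- build_dataset(cases, raw$drug, raw$reac,
                       list(drug_query("agent_a", "agent_a", "Avexa")))
ds
#> <faers_dataset>
#>  cases:  19904 (from 21107 raw rows; 192 excluded by primaryid collision, 1011 superseded case versions)
#>  events: 39827 PT mentions
#>   exposure[agent_a]: 569 reports
```

The generator injected duplicate case versions and colliding primaryids;
deduplication removed exactly those. Screening every PT reported with
`agent_a`:

```r
res <- screen_signals(ds, "agent_a")
format_signal_table(top_signals(res[positive == TRUE], 3))
#>        pt frequency           ror_ci      prr_chi2 ebgm_ebgm05    ic_ic025
#> 1: pt_010       180 8.34 (7.01-9.91) 7.19 (810.62) 6.10 (5.13) 2.57 (2.32)
```

Only the planted pair is positive: its estimated ROR 8.34 (CI 7.01–9.91)
covers the true value 8 (`expected_ror(cfg, "agent_a", "pt_010")` returns
8 exactly), the 180 target-PT mentions among exposed reports are the
`a` cell, and shrinkage pulls EBGM (6.10) and 2^IC below the raw odds
ratio, as it should at this sample size. Rolling positive signals up to
system organ classes with a user-supplied PT→SOC table:

```r
map <- load_pt_soc_map(system.file("extdata/synthetic_pt_soc_map.tsv",
                                   package = "pvsignal"))
aggregate_soc(res, map)
#>    drug_label                                            soc frequency percent
#> 1:    agent_a Injury, poisoning and procedural complications       180     100

demographics(ds)[group == "agent_a" & block == "sex"]
#>      group  block   level count total percent
#> 1: agent_a    sex  female   328   569   57.64
#> 2: agent_a    sex    male   173   569   30.40
#> 3: agent_a    sex missing    68   569   11.95
```

`run_pipeline("config.txt")` drives the same flow from a flat key/value
configuration and writes every surface as TSV; `inst/cli/pvsignal.R`
exposes `simulate` / `screen` / `report` subcommands for `Rscript`. The
`screen` subcommand works on a bare CSV of `label,a,b,c,d` rows, so the
statistics are usable with no FAERS input at all.

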