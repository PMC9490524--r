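# burnoutscreen

Burnout is an occupational syndrome arising from chronic, unmanaged workplace
stress; health professionals are disproportionately affected, and free,
repeatable self-screening is one of the recommended early-detection tools.
`burnoutscreen` is an R implementation of the computational core of such a
screening workflow: it scores the two free instruments involved, combines
them into a four-outcome screening result, tracks a respondent's evolution
over repeated self-assessments, and scores the System Usability Scale (SUS)
survey used to evaluate the screening app itself. It is aimed at researchers
and engineers who need a tested, scriptable scoring engine for these
instruments rather than a mobile UI.

The screening outcome is an orientation aid, not a medical diagnosis.

## What it computes

**GHQ-12 (psychological distress).** Twelve items, four ordered options each,
scored bimodally: option codes 0–1 score 0, codes 2–3 score 1, so the total
is

&nbsp;&nbsp;&nbsp;&nbsp;*S* = Σᵢ 𝟙[xᵢ ∈ {2,3}],&nbsp;&nbsp; *S* ∈ {0, …, 12}.

The distress flag is *S* ≥ *t* with screening threshold *t* = 3 by default
(deliberately below the conventional cut-off so no symptoms are missed); the
conventional bands are always reported alongside (*S* ≥ 4 possible distress,
*S* ≥ 8 stress-related disorders).

**CBI (Copenhagen Burnout Inventory).** Nineteen items over three subscales —
personal (6), work-related (7), client-related (6) — each item valued
100/75/50/25/0 from highest to lowest intensity, with the positively worded
work item ("enough energy for family and friends") reverse-scored. Each
subscale score is the mean of its item values; levels are low (< 50),
moderate ([50, 75)) and high (≥ 75). Overall risk: high with ≥ 2 high
subscales; moderate with exactly 1 high or ≥ 2 moderate; low otherwise.

**Diagnosis.** `diagnose()` maps (distress, overall risk) to one of
*critical* (distress + high), *moderate* (moderate risk, regardless of GHQ),
*great* (no distress + low), or *contradictory* (the two remaining,
disagreeing combinations — a retest is recommended, by default in 3 months).

**SUS.** Ten items answered 1–5; odd (positive) items contribute
(x−1)·2.5, even (negative) items (5−x)·2.5, total 0–100, interpreted on the
standard adjective bands (> 80.3 excellent … < 51 awful). Aggregated count
tables are scored exactly via linearity of the total in the per-item
contributions.

A seeded simulator (`respondent_profile()`, `simulate_ghq()`,
`simulate_cbi()`, `simulate_sus()`, `simulate_history()`) generates
respondents with controllable severity so every stage is testable without
collecting data.

## Worked example

```r
library(burnoutscreen)

banks <- load_builtin_instruments()

# a distressed, burned-out respondent, answered by labels
ghq <- response_record("GHQ12", "u1",
  setNames(rep(3, 12), names(banks$GHQ12$items)), "2022-01-15")
cbi <- response_record("CBI", "u1",
  setNames(rep("Always", 19), names(banks$CBI$items)), "2022-01-15")

rec <- make_record(ghq, cbi)
rec
#> <test record u1 @ 2022-01-15T00:00:00Z>
#> <GHQ-12: score 12/12, distress YES (threshold 3), band stress_disorders>
#>   personal 100.00  high
#>   work      85.71  high
#>   client   100.00  high
#> <CBI overall risk: high>
#> <diagnosis: critical — distress on the GHQ and high burnout risk on the CBI>
```

The work subscale is 85.71 rather than 100 because the reverse-scored energy
item contributes 0 under "Always": (6·100 + 0)/7. The GHQ total of 12 (every
item in its symptomatic half) exceeds the threshold of 3, so together with
high CBI risk the outcome is *critical*.

Scoring the bundled 40-user usability survey:

```r
tab <- read_sus_counts(system.file("extdata", "sus_survey_counts.csv",
                                   package = "burnoutscreen"))
sus_report(tab)
#> <SUS: 95.62 (excellent), n = 40>
```

A thin command-line wrapper over the same functions ships in
`inst/cli/burnoutscreen.R` (subcommands `score-ghq`, `score-cbi`, `diagnose`,
`history {add,show,chart,due}`, `sus {score,aggregate}`, `simulate`,
`instruments dump`; exit codes 0 / 2 validation / 1 internal).

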