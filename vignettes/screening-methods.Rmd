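---
title: "Scoring models and design choices in burnoutscreen"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring models and design choices in burnoutscreen}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(burnoutscreen)
```

`burnoutscreen` implements the scoring core of a burnout self-screening
workflow: the GHQ-12 distress screen, the Copenhagen Burnout Inventory (CBI),
their combination into a four-outcome result, longitudinal monitoring, and
System Usability Scale (SUS) scoring. This vignette explains the models, the
tunable parameters, the numerical conventions at band boundaries, what the
bundled simulator does and does not emulate, and the design choices that were
genuinely open.

## GHQ-12: bimodal scoring

Each of the 12 items offers four options ordered from most positive to most
negative. Bimodal scoring collapses each item to a binary indicator — the
first two options score 0, the last two score 1 — and the total is the count
of symptomatic answers, range 0–12. The alternative Likert scoring (0-1-2-3
per item) is deliberately not implemented: the screening workflow this engine
reproduces commits to bimodal scoring only.

The **distress threshold** (`threshold`, points, default 3) flags distress
when the total reaches it. Three is a deliberately sensitive screening
choice, one point below the conventional cut-off, so that mild symptom loads
are not ignored. Because users of the engine may want the conventional
reading, every result also carries `standard_band`: `none` below 4,
`possible_distress` in 4–7, `stress_disorders` at 8 and above. The diagnosis
stage uses the configurable flag, not the bands; both interpretations are
exposed so neither is lost.

```{r}
ghq_bank <- load_builtin_instruments()$GHQ12
# five symptomatic answers, seven non-symptomatic
codes <- setNames(c(rep(3, 5), rep(0, 7)), names(ghq_bank$items))
score_ghq(response_record("GHQ12", "u1", codes, "2022-01-15"))
```

## CBI: subscale means and risk combination

The 19 items split into personal (6), work-related (7) and client-related
(6) subscales. Options are valued 100/75/50/25/0 from highest to lowest
intensity; two synonymous label packs (frequency wording and degree wording)
map to the same codes and are accepted interchangeably, since the instrument
uses them indistinctly. The single positively worded item — the
work-dimension energy question — is reverse-scored (0/25/50/75/100) so that
higher always means more burnout. A subscale score is the plain mean of its
item values; no prorating of missing answers is performed (both instruments
are short, and no missing-data rule exists for them), so incomplete records
are rejected at validation with a full list of violations.

**Level boundaries.** Levels are low, moderate, high with cut-offs at 50
and 75. The published moderate band is labelled "50–74" with high "75–100";
we read the 74 as inclusive shorthand and implement moderate = [50, 75).
The choice is vacuous in practice: for a 6-item subscale attainable means
are multiples of 25/6, and none falls strictly between 74 and 75 (the test
suite checks this exhaustively).

**Overall risk.** The published combination table lists the clear cases
(all-low, low-low-moderate → low; three moderates, and mixed-moderate cases
→ moderate; two or three highs → high). One printed moderate case is
garbled — it names four subscales for a three-subscale instrument — and we
read it as the two minimal-edit cases MML and MMH, both moderate. Two
combinations are not printed at all (LLH, LMH); the completion rule
implemented is:

* high if ≥ 2 subscales are high;
* else moderate if exactly 1 is high, or ≥ 2 are moderate;
* else low.

This reproduces every printed case and resolves the unprinted single-high
combinations *conservatively* to moderate — one severely affected dimension
should never yield an all-clear. The rule is total and monotone over all 27
combinations (checked exhaustively).

## The four-outcome diagnosis

`diagnose()` is a total function on (distress flag) × (overall risk):
*critical* = distress + high risk; *moderate* = moderate risk regardless of
the GHQ; *great* = no distress + low risk; the two remaining cells —
distress with low burnout, or high burnout without distress — are
*contradictory*: the instruments disagree and a retest is recommended.
"Contradictory" is defined as the complement of the three positive rules,
which is the only reading that makes the published rule set total. The
critical rule consumes the engine's distress flag, i.e. the configurable
threshold (default 3), not the conventional ≥ 4 band; the two coincide for
all totals except exactly 3.

## Monitoring

Histories are per-respondent, time-ordered lists of scored records
(duplicate timestamps rejected; storage is UTC ISO-8601 so ordering is
unambiguous). `recent_diagnoses()` returns the last 4 records by default
(the app's column chart of past tests) carrying both the CBI overall risk
and the combined category, so either can be plotted. `dimension_deltas()`
compares the last two records per subscale; *improved* means a lower score,
as all CBI scales are symptom-positive. `status_message()` yields an alert
on GHQ distress, congratulations when all three subscales are exactly 0
without distress, and nothing otherwise; alert strictly dominates on
conflict because distress marks a critical state. `next_due()` adds the
retest interval (default 3 months) in calendar months with end-of-month
clamping — "every 3 months" is a calendar statement, and clamping
(2022-11-30 → 2023-02-28) is the only reading that always yields a valid
date.

## SUS

Per-respondent scoring is the standard arithmetic: odd (positive) items
contribute (x−1)·2.5, even (negative) items (5−x)·2.5, total 0–100.
Aggregated count tables are scored by **exact linearity**: the cohort mean
equals the sum over items of the count-weighted mean contribution, identical
to the mean of per-respondent scores for *any* disaggregation consistent
with the counts — so no individual reconstruction is attempted or needed.

```{r}
tab <- read_sus_counts(system.file("extdata", "sus_survey_counts.csv",
                                   package = "burnoutscreen"))
mean_sus_from_counts(tab)
```

The bundled 40-user survey scores exactly `r mean_sus_from_counts(tab)`; the
figure published for the same counts is 95.8, a 0.175-point gap we attribute
to rounding in the source and therefore do not reproduce — the engine
reports the exact value. Interpretation bands overlap as published
("68–80.3 good", "68 okay", "51–68 poor"); the implemented partition keeps
the printed singleton: exactly 68 → okay, (68, 80.3] → good, [51, 68) →
poor, so the bands tile [0, 100] without overlap.

## The simulator: what it emulates, and what it does not

`respondent_profile()` controls four severity dials: `ghq_negativity` (the
probability each GHQ item is answered in its symptomatic half, making the
total Binomial(12, p)); `cbi_target` (per-subscale target means, 0–100);
`cbi_noise` (item-level spread); `sus_positivity` (probability of an optimal
SUS answer). Defaults (negativity 0.2, targets 30, noise 0.5, positivity
0.9) describe a mildly loaded, non-clinical respondent with the strongly
positive usability ratings seen in the app's field evaluation; they are a
plausible operating point, not an estimate of any population's prevalence,
which the simulator makes no attempt to match.

The CBI generator works in two stages. *Bracketing*: within each subscale
the items are split deterministically between the two option values flanking
the target, in the proportion that makes the noise-free subscale mean the
closest attainable mean to the target. With `cbi_noise = 0` the classified
level therefore recovers `classify_level(target)` for every target further
than 25/(2n) points (about 2.1 for a 6-item subscale) from a cut-off —
pure nearest-option snapping would not have this property, because targets
like 60 would snap every item to 50, parking the mean exactly on a boundary.
*Jitter*: each item's option is then displaced one step up or down with
probability `cbi_noise/2` each, clamped at the scale ends. The reverse item
is handled in contribution space, so the target governs what it adds to the
mean, not its raw option. All randomness flows from a single integer seed
(`withr::with_seed`), so fixtures are bit-reproducible and the global RNG
state is never disturbed.

What passing simulator-based tests shows is that the *engine* is correct
under controlled severity: parameter recovery, monotonicity, linearity.
Synthetic respondents answer items independently given the profile; real
questionnaire data has correlated items, response styles, and missing
answers, none of which the simulator emulates — so simulator results say
nothing about the instruments' psychometrics on real populations.

## Problem sizes and numerical notes

The property suites run at modest, fixed sizes chosen to make the checked
properties overwhelmingly informative: 1,000 random responses for the GHQ
recount oracle, 2,000 draws for the simulator mean (standard error ≈ 0.04
against a ±0.2 band), 500 cohorts for SUS linearity, 500 seeds for noisy
level recovery, exhaustive enumeration wherever the space is finite (48
GHQ coding cells, 27 risk combinations, 6 diagnosis cells, 5^6 subscale
sums). All scores are exact multiples of small rationals (25/n, 2.5), so
comparisons use exact equality except where means of doubles are involved,
which use tight floating-point tolerances. Run configuration files are JSON
or YAML; both are versioned alongside the record and history schemas.

## Known limitations

* English wording only; the screening app's Spanish/Catalan localisation is
  UI-level and out of scope.
* Only the 19-item CBI and 12-item GHQ are implemented — no GHQ-28/30/60,
  no 16-item CBI variant, no client-wording substitutions, no population
  norms or reliability statistics.
* The lifestyle questionnaire is captured as a validated data type but has
  no scoring rule, by design.
* The four-outcome result is a screening aid; nothing in this package is a
  medical diagnosis.
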