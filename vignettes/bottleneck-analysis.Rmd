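---
title: "Screening survey data for bottlenecks in the implementation of health promotion interventions"
author: "BottleneckProfiler authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening survey data for implementation bottlenecks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(BottleneckProfiler)
```

## The problem

When a health promotion intervention is introduced into a local context, it
has to interact with that context: the implementer's skills, the partner
organizations, the political climate, the materials at hand.  A *condition
for implementation* is any such prerequisite.  When a condition is both
*important* for an intervention and *sub-optimally present*, it is a
*bottleneck for implementation*.  If bottlenecks pattern with the function
of an intervention — operationalized as the triple (behaviour change
method, health theme, implementation setting), the *intervention system* —
they can be anticipated; if they arise independently of it, implementation
plans need local flexibility.

This package implements the survey-analysis pipeline for that question.
The measurement model is deliberately simple and rule-based; everything of
interest lies in how the rules compose across stratifications.

## Data model

A survey covers 47 conditions organized in seven categories: 5 about the
prime implementer, 5 about the co-implementer(s), 10 about the
intervention, 10 about the prime implementer's organization, 11 about the
co-implementer's organization(s), 4 about the broader context and 2 about
the implementation strategy.  For each implemented intervention, the prime
implementer

* rates the presence of each condition on a five-point agreement scale
  (1 = strongly disagree … 5 = strongly agree), and
* selects the (at most) five conditions most important for that
  intervention, either from the pre-listed 47 or as free text.

The container is a `BottleneckSurvey`, a `SummarizedExperiment` with one
row per condition and one column per intervention: the `ratings` assay
holds the ordinal responses, `colData` the system triple and identifiers,
`rowData` the condition registry.

## The classification rules

1. **Dichotomization.** Presence is *optimal* only under strong agreement
   (rating 5); every other answer is *sub-optimal*.  The cut-off reflects
   the right-skewed presence distributions typical of such surveys: any
   laxer cut collapses the sub-optimal class and hides bottlenecks.
2. **Importance.** A condition is *important* for an intervention when it
   appears in the resolved top-5, irrespective of rank.  Free-text answers
   are recoded onto pre-listed conditions by exact match after case-folding
   and whitespace normalization; unmatched answers are dropped and counted.
   No fuzzy matching is attempted — the recode map fully determines the
   outcome, which keeps reruns reproducible.
3. **Bottleneck (intervention level).** `bottleneck = sub-optimal AND
   important`.
4. **Frequent systems.** Systems occurring strictly more than 10 times.
5. **Bottleneck (stratum level).** Within any stratum — a frequent system,
   all systems sharing one characteristic level, or all systems — a
   condition is a bottleneck when flagged in *strictly more than* 10% of
   the stratum's members.  The comparison is done in integer arithmetic
   (`n_flagged * 10^4 > round(threshold * 10^4) * n_members`), so exact
   boundary rates (2/20, 3/30) are never called.
6. **Congruence.** For each (frequent system, condition) pair, the
   frequent-system call is compared with the calls in the three
   characteristic strata the system belongs to: expectedly present (EPB),
   unexpectedly present (UPB), unexpectedly absent (UAB), or concordantly
   absent.

### The existential reading of "a characteristic in common"

Whether a characteristic-linked bottleneck should mean "a bottleneck in
*at least one* of the three matching characteristic strata" or "in *all
three*" is genuinely open.  We default to the existential reading: the
phenomenon of interest is whether a bottleneck is *associated with* any
aspect of the system's function, and a single strong association (say,
with the regulation method) is exactly the kind of regularity one wants to
detect.  The universal reading is available via
`requireAllCharacteristics = TRUE` (or `--require-all-characteristics`)
as a sensitivity analysis; it reclassifies some EPBs as UPBs and removes
UABs that rested on a single characteristic.

### Missing ratings

A missing rating is treated as *not sub-optimal* and marked unrated, while
denominators remain the full stratum.  Missingness therefore deflates
percentages — the conservative direction for a screening instrument whose
calls trigger follow-up.  The switch `imputeMissingAsSuboptimal = TRUE`
implements the opposite extreme for sensitivity analyses.  Similarly,
characteristic strata by default include *all* systems sharing the level;
`frequentOnly = TRUE` restricts them to systems inside frequent triples.

## The synthetic cohort generator

Raw survey data of this kind are typically not public, so the generator is
a first-class module: every pipeline stage is exercisable, and recovery
experiments quantify what the rules can and cannot detect.

`simulationConfig()` defaults encode the study conditions the pipeline is
designed for:

* 243 interventions in 30 projects by 120 implementers (implementers drawn
  with replacement, so one may hold several interventions);
* marginal weights 137/57/25/13/11 over methods
  (education/facilitation/regulation/case finding/citizen participation),
  123/102/16 over themes (overweight/alcohol/other), and
  75/38/38/24/24/24/15 over settings (school/outdoor public/public
  building/health-welfare building/sports facility/commercial
  building/home), drawn independently;
* a latent-threshold (cumulative) ordinal model for presence:
  `latent = presenceBase + injected shifts + N(0, 1)`, cut at
  (−2, −1.2, −0.4, 0.3), making "strongly agree" modal (right-skewed
  presence).  The default `presenceBase` is back-transformed from
  per-condition sub-optimal probabilities spread over 40–83% with mean
  ≈56.5%, matching the observed spread of sub-optimal percentages;
* top-5 importance as a softmax draw without replacement with weight
  `exp((baseImportance + boost + coupling · s) / temperature)` where
  `s = (5 − rating)/4` is the sub-optimality score.  The default coupling
  of −3 with a baseline-importance amplitude of 0.45 was calibrated once
  so that the cross-condition Pearson correlation between % sub-optimal
  and % important averages ≈ −0.4: conditions that are widely sub-optimal
  tend not to be the ones deemed important.  (Note the sign convention:
  the coupling multiplies *sub-optimality*, so negative coupling yields
  the negative correlation.)
* 2% missing ratings; 11% of importance selections rendered as recodable
  free-text aliases and 11% as unmappable free text, mirroring the
  reported fate of added answers.

What the generator does **not** emulate: project- and implementer-level
clustering of responses, response styles, any joint dependence among
method, theme and setting (their joint distribution is not published;
`jointSystemWeights` accepts one if known), and item-level psychometrics.
Passing tests therefore show that the *rules* behave as specified under
realistic marginals — not that real surveys are this well behaved.  One
visible consequence of the independence assumption: the default cohort
yields 3–6 frequent systems covering ≈25–40% of interventions, fewer than
the nine covering 58% observed when methods, themes and settings co-occur
in structured ways.

## Recovery experiments and their calibration

`recoveryExperiment()` generates replicate cohorts, runs the pipeline and
records, for every (condition, characteristic level) pair, whether the
condition was called a bottleneck in that characteristic stratum.

The reference fixtures are built on `homogeneousConfig()` — exchangeable
conditions (flat presence and importance baselines) — because with
heterogeneous conditions a stratum call may reflect a genuinely
bottleneck-prone condition rather than a characteristic link, which is not
what the false-call rate should measure.

* **Sensitivity.** Three injected pairs with presence shift −2 and
  importance boost +3 under the study's marginal weights are recovered in
  their characteristic strata in essentially every replicate
  (sensitivity 1.0 at 200 replicates).
* **False calls.** The null fixture uses *uniform* characteristic weights.
  This is a deliberate calibration: under the study's skewed marginals the
  smallest characteristic strata hold ~11 systems, where the strict >10%
  rule fires on a single chance cell (per-pair false-call rates up to
  ≈0.15–0.30 — a property of the rule at small stratum sizes, worth
  knowing in itself).  Balanced weights give every stratum ≥~25 members,
  where the rule requires several concordant chance cells; the maximum
  per-pair false-call rate is then ≈0.05 at 200 replicates.

A practical reading: stratum-level calls from strata of barely more than
ten systems are noisy, and the weakly supported characteristic levels
(citizen participation, case finding, the "other" theme, the home setting)
should be interpreted with that in mind.

## Numerical and degenerate-input choices

* Thresholds are strict (`> 10` systems, `> 10%` rate) with exact integer
  comparison; ties are excluded by construction, never broken by floating
  point.
* Percentages are carried at full precision and only rounded for display
  (one decimal).
* Empty cohorts, header-only CSV files, all-optimal surveys and zero
  injected effects are all valid inputs with well-defined outputs; empty
  strata and constant correlation inputs raise errors rather than
  returning NaN.
* All randomness flows from the configuration seed; `generateDataset()`
  seeds the RNG itself, so identical configurations give byte-identical
  CSV exports.

## Problem sizes used in the test suite

The packaged checks run the full cohort (n = 243) for property and
partition invariants, 100 seeded small instances (≤10 conditions, ≤30
records) against an independent brute-force oracle, 50 replicates for the
correlation sign test, and 200 replicates each for the sensitivity and
null recovery experiments — sizes at which the Monte-Carlo margins above
are comfortable while the whole suite stays quick.

## A worked run

```{r example, eval = FALSE}
cfg <- simulationConfig(seed = 7)
ds <- generateDataset(cfg)
rs <- runPipeline(ds$survey, recodeMap = defaultRecodeMap(registry(ds$survey)))
rs
congruenceLabels(rs$congruence)[1:5, , drop = FALSE]
```

## Known limitations

* The congruence labels are descriptive, not inferential: no uncertainty
  accompanies a stratum call, and comparisons between strata are
  observational by design.
* The default registry ships placeholder statement texts (the category
  exemplars are real); supply the full questionnaire via `loadRegistry()`
  when available.  Statement texts affect no computation.
* Free-text recoding is exact-match; a real analysis will want a curated
  recode map.
* With the independence assumption over characteristics, the frequent-
  system landscape of synthetic cohorts is flatter than in structured
  real samples; supply `jointSystemWeights` to emulate a known joint
  distribution.
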