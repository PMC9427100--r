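---
title: "Classifying randomized trials by four conditions of informativeness"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Classifying randomized trials by four conditions of informativeness}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialinform)
```

## The model

A randomized trial can only guide clinical, policy, or research decisions if
a chain of conditions holds: it must have been *feasible* (it actually
recruited the population it was powered for, in the time it planned),
*reported* (its primary outcome results are publicly accessible), *important*
(the clinical community judged the results worth synthesizing), and *well
designed* (its internal validity is not compromised by bias). This package
operationalizes each condition as a dichotomous surrogate computable from a
structured registry record plus coded citation and risk-of-bias evidence, and
classifies a trial **informative** when all four hold.

The conditions are logically and practically ordered — citation in a
synthesizing document cannot be assessed before results exist — so scoring is
sequential: feasibility, then reporting, then importance, then design, with a
trial leaving the pipeline at its first failure. Two consequences matter for
interpretation. First, per-condition failure counts are *attributable*
counts (the stage at which the trial left), not marginal failure rates: a
trial failing feasibility might also have failed design, but is never
assessed there. Second, the informative proportion is invariant to the
ordering even though the per-stage counts are not.

### Condition rules and their parameters

**Feasibility.** Completed trials pass when final enrollment reaches at
least a threshold fraction (default `0.85`) of the enrollment anticipated in
the final registration record *before study start* — using the pre-start
snapshot avoids crediting goalpost-moving. The wording is strict at the
boundary: enrollment *below* 85% reflects a substantial loss of power, so
exactly 85% passes. Terminated trials pass only when termination was for a
scientific reason (accumulated evidence of early efficacy, futility, or
toxicity), irrespective of enrollment: stopping for futility is the design
working, not failing. Ongoing trials fail once the assessment date is past
`window_multiplier` (default 2) times the planned start-to-completion
interval; inside that window they are *indeterminate* and belong outside the
cohort — reaching the assessor in that state is an error, not a verdict.
Both parameters are exposed (`threshold`, `window_multiplier`) but every
analysis here uses the defaults.

**Reporting.** Registry results deposition or a journal publication of the
primary outcome; either suffices. Where several publications exist, the
record carries the earliest.

**Importance.** Citation of the trial's *results* in a high-quality
synthesizing document, checked in a fixed hierarchy: systematic review
(Cochrane and AHRQ reviews are high-quality by definition; other SRs carry a
coded quality judgment), then clinical practice guideline, then a
point-of-care review article. The hierarchy front-loads SRs because their
citation practices are results-neutral, so negative trials are not
penalized. The verdict reports the highest satisfying tier; lower-tier
evidence never overrides it.

**Design.** A trial passes when a risk-of-bias assessment exists and no
element is high risk *and* strictly more elements are low than unclear. With
an even element count and a low/unclear tie, the trial fails — "a majority
low" is read strictly. A trial with no locatable risk-of-bias information
fails with reason `missing_rob`: a trial whose bias cannot be established
cannot be shown informative. This is a package decision; the alternative
(treating it as unassessable and dropping it) would silently shrink the
denominator of the primary outcome.

### Eligibility screening

`screen_trials()` applies the cohort rules in a fixed order (randomized; US
site; disease area; start date in window; not early-phase; treatment or
prevention purpose; intervention on an FDA-approvable path; not
indeterminate) and reports the *first* failing reason. The order affects
only the reported reason, never membership. Unknown-status trials are
treated as ongoing for the indeterminate rule, so they enter the cohort only
once past the doubled window — at which point they fail feasibility as
overdue. Registry dates may be month-precision; a missing day resolves
deterministically to the first of the month so the doubled window stays
computable.

## Statistics

The primary outcome is a binomial proportion with an exact Clopper–Pearson
interval from Beta quantiles; CP is conservative (coverage at least nominal),
which the test suite checks by simulation over a grid of `n` and `p` (2,000
replicates per cell, fixed seed). Stratified comparisons fix the test family
by stratifier, mirroring how such cohorts are analyzed: chi-square for
disease area and sponsor (Yates continuity correction on 2×2 tables only,
the default behaviour of standard statistical environments), Fisher exact
for phase and intervention class, where small strata make the asymptotic
test unreliable. The Fisher p-value is computed by full enumeration of all
2×K tables with the observed margins, summing multivariate-hypergeometric
probabilities no greater than the observed table's (relative tolerance 1e-7
absorbing floating-point ties), with a capacity guard at 10^7 candidate
tables; per-stratum intervals are Clopper–Pearson for every stratifier, a
deliberate simplification (per-stratum binomial CP is itself exact) rather
than conditional exact intervals for the Fisher rows.

Two sensitivity analyses recompute the primary outcome on subsets: excluding
small pilot-type trials — those at or below the empirical 25th percentile
(type-7, the default linear-interpolation convention) of target enrollment,
with boundary ties all excluded, except in the degenerate all-tied case
where nothing is excluded — and excluding phase-1/2 and phase-2 trials.
Cohen's kappa supports dual-reviewer agreement checks; it has no numeric
anchor in the reference results and is tested at formula level against an
independent implementation.

## The synthetic cohort

`build_reference_cohort()` deterministically constructs 125 eligible records
whose classification reproduces every published margin of the reference
cohort: attribute totals (disease 40/57/28, status 99/15/5/6, phase
24/50/19/32, intervention 77/8/8/32, sponsor 58/67, outcome type 42/83),
informative counts per stratum (11/18/4, 2/25/2/4, 27/2/0/4, 29/4, each
re-summing to 33), funnel failures 35/9/18/30 with exactly 21 feasibility
failures via under-enrollment, 8 of 18 importance failures with
registry-posted results and no publication, a 35-trial lowest-quartile
exclusion set containing exactly one informative trial, and enrollment
totals of 193,839 participants overall and 129,973 in informative trials.

The published margins do not determine the joint distribution. Once the
stage labels are fixed, however, the remaining constraints act on one
attribute column at a time, so a direct block assignment suffices and no
search is needed. Status interacts with the funnel arithmetic: all 5
active-not-recruiting and all 6 unknown trials must be overdue feasibility
failures (they could not otherwise have entered the cohort), which with the
21 under-enrolled completed trials forces exactly 3 non-scientific
terminations among the feasibility failures and leaves 12 terminated trials
feasible by scientific termination; the construction places those 12 among
design-stage failures, so all 33 informative trials are completed trials —
the status-by-informativeness joint is unpublished and hence free. Any
cohort satisfying the margins reproduces all margin-level statistics, which
is exactly what the acceptance checks assert; unpublished joints
(e.g. sponsor × phase among informative trials) are arbitrary.
`fixture_constraint_report()` re-derives every constraint programmatically.

Enrollment values make the quartile set clean: the 35 smallest trials share
target enrollment 100 (so the type-7 quartile lands on the tied value and
the at-or-below rule excludes exactly 35), and the remaining values are
chosen to hit the published participant totals exactly.

`generate_random_registry()` draws the four condition outcomes independently
per trial with probabilities `(p_feasible, p_reported, p_important,
p_low_rob)` — defaulting to the reference cohort's conditional stage pass
rates 90/125, 81/90, 63/81, 33/63 — and *realizes* each outcome through
concrete record fields (an infeasible trial becomes under-enrolled,
non-scientifically terminated, or overdue, at random), so the assessors, not
the generator, decide the verdicts. Under independence the informative
fraction converges to the product of the four probabilities, which the suite
verifies at n = 10,000 within three binomial standard errors. What the
generator does *not* emulate: correlation between conditions (industry
sponsorship predicting both reporting and feasibility, as the stratified
results suggest), attribute-dependent pass rates, calendar trends, or
missing/inconsistent registry data beyond optional fields. Tests passing on
these registries therefore validate the machinery — gating, counting,
intervals, invariances — not the epidemiology of any real cohort.

## Numerical choices and edge cases

* Exactly-85% enrollment passes feasibility; the threshold comparison is
  `>=` on exact integers.
* The overdue deadline is `start + multiplier * (planned_completion -
  start)` in days; an assessment falling exactly on the deadline is *not*
  overdue (the trial has not "surpassed" it).
* Subsample sizes round half up; selection preserves input order and uses a
  private RNG stream so callers' reproducibility is unaffected.
* `classify_trials()` refuses duplicate registry ids and propagates assessor
  data errors (missing enrollment on a completed trial, indeterminate trials
  reaching feasibility) with the offending ids.
* Fisher enumeration sums probabilities in plain double precision; the test
  suite checks the margin-fixed table set sums to 1 within 1e-10.
* Empty strata are dropped with a warning before testing; a single remaining
  stratum is an error.

## Problem sizes

The reference analyses run on 125 records in well under a second. Property
checks use registries of 60–600 trials, one 10,000-trial registry for the
independence-product recovery, and 2,000 replicates per cell for interval
coverage; the full suite completes in well under a minute on one CPU.

## Known limitations

Surrogate conditions are proxies: a trial can fail importance for citing
practices unrelated to its scientific value (niche populations), and a
high-bias trial can still change practice. The sequential design means
per-condition failure rates are not marginal prevalences. Conditions are
assessed from coded inputs — the package does not perform AMSTAR scoring,
risk-of-bias judgment from publications, or literature searches; those
judgments arrive as data. The Fisher-row per-stratum intervals are
Clopper–Pearson, not conditional exact intervals.
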