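---
title: "Methods: integrity screening of trials and its impact on meta-analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrity screening of trials and its impact on meta-analyses}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(riaimpact)
```

## The problem

Systematic reviews of randomized controlled trials (RCTs) assume that the
trials they pool are what they claim to be. A growing share of published
trials — prominently in the COVID-19 literature — show signs of compromised
research integrity: retracted reports, missing or retrospective trial
registration, unverifiable ethics approval, implausible methods or results,
or non-randomized studies mislabelled as RCTs. `riaimpact` implements a
complete pipeline for (a) screening trials with a hierarchical six-domain
research integrity assessment (RIA), (b) quantifying how reliably two
assessors agree on that screen, (c) re-pooling review meta-analyses after
removing trials that fail the screen, and (d) classifying how the pooled
conclusions change.

## The hierarchical screen

The six domains are assessed in a fixed order: retraction, prospective
trial registration, ethics approval and informed consent, authorship,
plausibility of methods, plausibility of results. At each domain the
assessor decides `no_concern`, `awaiting` (classification pending,
typically until trial authors respond), or `exclude`. In the registration
and plausibility-of-methods domains a study can instead be flagged
`non_rct`. `exclude` and `non_rct` are terminal: later domains are skipped
(`not_assessed`). The overall classification is the first terminal verdict,
else `awaiting` if any domain is awaiting, else `no_concern`
(`assess_overall()`).

Two design points deserve note:

* **Non-RCT as a fourth terminal state.** The reference screening exercise
  reports misclassified non-randomized studies separately from exclusions,
  so the engine models `non_rct` as a parallel terminal verdict that
  truncates like exclusion. For reliability analysis (three ordered
  categories) it maps to `exclude`.
* **Adjudication policy.** A third (senior) assessor always re-rates
  domains 1–3 and re-rates domains 4–6 when the first two assessors
  disagree, agree on a non-benign verdict, or fewer than two ratings exist
  (`adjudication_policy()`, all four triggers on by default). Consistent
  benign pairs stand. The worklist is ordered by `(study_id, domain)` for
  reproducible reports.
* **Author correspondence.** Authors get 14 days plus a 7-day reminder
  extension. A domain flips from `awaiting` to `no_concern` only for a
  resolved query; when dates are absent the resolved flag alone decides,
  because screening datasets typically record outcomes, not
  correspondence timestamps.

## Interrater reliability

Agreement per domain and on the overall decision uses Cohen's kappa for
the three ordered categories `no_concern < awaiting < exclude` with linear
weights `w_ij = 1 - |i - j|/2` — `awaiting` is genuinely intermediate in
severity, which makes partial credit for near-miss disagreements
meaningful. Pairs are formed only where both assessors rated the domain;
the hierarchical truncation makes later domains progressively sparser, so
one-rating and no-rating tallies are reported alongside
(`build_pairs()`).

The standard error is the large-sample (Fleiss–Cohen–Everitt) weighted
kappa variance rather than a bootstrap, mirroring common calculator
output; the test suite verifies it against a 10,000-replicate bootstrap.
Verbal bands (slight/fair/moderate/substantial/almost perfect) are
assigned after rounding the coefficient half-away-from-zero to two
decimals, because the conventional band edges are two-decimal closed
ranges with gaps (0.20 vs 0.21): a kappa of 0.205 is "fair".

`analytic_kappa()` gives the closed-form kappa implied by two confusion
profiles and a truth distribution — the joint rating distribution is
`sum_t P(t) row_a(t) ⊗ row_b(t)` — and anchors the simulation recovery
tests.

## Meta-analysis and sensitivity re-analysis

Per-trial effects come from the standard 2×2 estimators (risk ratio and
odds ratio with their delta-method log-scale standard errors). Any zero
cell triggers a 0.5 continuity correction on all four cells — the default
of the mainstream meta-analysis software this mirrors — and double-zero
trials are flagged non-contributing. Pooling is inverse-variance, either
fixed-effect or DerSimonian–Laird random-effects with the moment estimator
of `tau^2`; confidence intervals use the normal quantile 1.96 (no
Hartung–Knapp, matching the headline CIs that reviews report). A
single-trial "pool" returns that trial's effect rather than refusing:
review impact tables legitimately print one-trial rows. Network
meta-analyses are represented but never re-pooled; their sensitivity
results are not estimable by construction.

`sensitivity_reanalysis()` keeps only trials whose final screening
classification is `no_concern`, records the excluded ids, and returns a
not-estimable result when nothing remains. Where a review has several
comparisons, `select_comparison()` picks the one with the most trials,
ties broken by participants, then lexicographic id.

## Equivalence-range classification

Direction, precision and interpretation are assessed against a
prespecified equivalence range, default 0.9–1.11 on the ratio scale:

* **Direction** — point inside the (closed) range: no-or-minimal effect;
  below 0.9: benefit when lower is better (mortality), harm when higher is
  better (clinical improvement); above 1.11: the opposite.
* **Precision** — imprecise iff the open CI interval strictly contains a
  boundary. An endpoint exactly on a boundary is *not* a crossing: a CI of
  0.90–1.06 is precise. This strictness is what makes the bundled corpus
  reproduce the reference counts of precise no-or-minimal estimates.
* **Interpretation** — the pair of the two, six estimable classes plus
  `not_estimable`; a change in any dimension (or becoming not estimable)
  is an interpretation change.

The bundled 26-row corpus (`covid_review_corpus()`) stores, for the one
review that mixed RCTs with non-randomized studies in its primary
meta-analysis, the recalculated RCT-only pooled estimate as the "original"
value. With that choice the classifier reproduces the reference tallies
exactly (2 precise benefit, 7 imprecise benefit, 3 precise no-or-minimal,
8 imprecise no-or-minimal over the 20 evaluated meta-analyses, with
interpretation changes in 5 of 13 Cochrane and 4 of 7 evaluated
non-Cochrane meta-analyses).

## Corpus-level summaries

Counts are summarized as median and IQR; the median uses the midpoint
convention and quartiles default to type 7 (R's linear interpolation),
configurable because printed IQRs in the literature rarely pin down a
convention — medians, which are convention-robust, are the quantities the
tests assert. Percentages are reported to one decimal,
half-away-from-zero. Assessment times are stored in seconds and rendered
`hh:mm:ss` only at the presentation layer; the per-tier total is the sum
of the six per-domain means. Summing the published per-domain expert means
gives 20:52 where the published total prints 20:51 — the exact sum of
rounded means overshoots by one second, and `feasibility_summary()`
surfaces the discrepancy rather than hiding it.

## The synthetic corpus generator

`simulate_ria_corpus()` makes the whole pipeline testable without any
external data. Its default calibration (versioned in
`inst/extdata/default_calibration.yaml`) emulates a 206-trial COVID-19
screening corpus:

* **Per-domain truth** is multinomial conditional on reaching the domain
  (registration exclusion 51/198, ethics awaiting 62/137, and so on),
  sampled hierarchically so terminal statuses truncate. Cross-domain
  independence is assumed — the joint co-occurrence of issues within a
  trial is not identified by published marginals — and documented here as
  a limitation.
* **Author resolution**: each awaiting domain resolves to no-concern with
  a per-domain probability (e.g. 17/62 for ethics). The domain marginals
  above are interpreted as pre-correspondence values; with the resolution
  step the implied long-run overall frequencies are ≈ 23% / 43% / 29% / 5%
  (no-concern / awaiting / exclude / non-RCT) against the reference 27.7 /
  38.3 / 28.6 / 5.3 — all within the ±7-point tolerance the calibration
  check uses. Without the resolution step the no-concern frequency would
  fall to ≈ 17%, which is why correspondence is part of the generating
  model.
* **Assessor error** is a 3×3 row-stochastic confusion matrix per
  expertise tier; the beginner profile shifts mass from `no_concern`
  toward `awaiting` (over-flagging), the senior profile is the identity
  and acts as the reference standard in adjudication.
* **Outcomes** are per-arm binomial draws with control risk 0.2 and a
  per-review true log risk ratio (default 0); arm sizes are lognormal
  around a 160-participant trial median. **RoB labels** are drawn
  independently of integrity status. **Time logs** are lognormal with
  tier-by-domain means matching the published feasibility table.
* **Seeding** is hierarchical: each review derives a deterministic
  substream from the global seed, so enlarging the corpus never perturbs
  earlier reviews, and a fixed spec + seed is bit-reproducible.

What passing the simulation tests does *not* show: real assessors are not
conditionally independent given a per-domain truth, integrity issues
co-occur within trials, and real effect sizes are heterogeneous across
reviews. The generator validates the pipeline's statistical machinery, not
the field behaviour of the screening tool.

## Problem sizes used in the test suite

Distributional checks use sizes chosen to keep Monte-Carlo error well
inside the asserted tolerances: 5,000 rating pairs for kappa recovery
(≈ 3 standard errors), 500 replicate meta-analyses of 30 trials at 400 per
arm for DL coverage (tolerance 93% against nominal 95%), and a ~4,600-trial
corpus for the calibration frequencies (Monte-Carlo error below one
point). Exact-agreement oracle checks run over 1,000 random confusion
matrices and 200 random study sets.

## Known limitations

* Only two pooling methods (fixed-effect inverse-variance, DL
  random-effects); reviews using Peto, Hartung–Knapp or network methods
  are accepted as metadata but not re-fitted.
* The reliability module is strictly two-rater, three-category; no Fleiss
  kappa or Krippendorff alpha.
* The adjudication engine does not model the order-dependence that arises
  when an earlier-domain re-rating un-excludes a study mid-adjudication;
  such domains surface on the worklist instead of being resolved
  implicitly.
* Published per-review medians that depend on the quartile convention or
  on merging two-intervention reviews are deliberately not asserted; the
  unit of analysis defaults to one row per intervention.
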