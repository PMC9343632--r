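---
title: "Methods: conversational thought recording, tiered feedback, and the trial machinery"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: conversational thought recording, tiered feedback, and the trial machinery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thoughtrec)
```

## What this package models

`thoughtrec` implements the full software side of a two-session experiment
in which a conversational agent guides people with subclinical depression
symptoms through cognitive-therapy *thought records*, and the richness of
the feedback the agent gives is experimentally manipulated:

* **low** richness — the agent acknowledges the completed record and
  reminds the user that more records can reveal thought patterns;
* **medium** — low, plus a chart of the number of downward-arrow steps in
  each record so far, situated in a reference distribution from a previous
  study;
* **high** — medium, plus a nine-axis spider chart of the core-belief
  *schemas* an NLP scorer detects in the recorded thoughts, with the
  aggregate of previous records shown alongside.

The scientific questions attached to that design — does richer feedback
motivate users (a count of voluntarily completed records; engagement in
self-reflection), is the effect mediated by gained insight, and is it
moderated by the need for self-reflection — define the analysis pipeline
and the power simulation in this package.

## The dialogue engine

The conversation is a deterministic finite-state machine. Free text is
accepted only for the four core record fields (situation, emotion,
automatic thought, behavior) and inside the downward-arrow loop; every
other interaction is a button token (`ready`, `ok`, `yes`, `no`, and the
arrow's stop token), which keeps the engine interface-agnostic and exactly
replayable. Session 1 always produces two scenario-based records, one
scenario drawn uniformly from each of two five-scenario sets
(interpersonal and achievement-related), with the category order
randomized per participant to avoid an order confound. Session 2 starts
directly with a personal record and allows any number of records ≥ 1.

Design choices the underlying protocol leaves open:

* **Downward-arrow termination.** No stop rule is published; we use an
  explicit stop token plus a configurable maximum depth (default 25) as a
  safety bound. At the bound the engine closes the record without
  appending further steps.
* **Probe wording.** The classic downward-arrow phrasing "If that were
  true, what would that mean about you?" is the default and is
  configurable; onboarding/instruction texts are likewise configurable
  placeholders.
* **Timestamps** are a logical event counter, not wall-clock time, so that
  identical (seed, script) pairs replay byte-identically — the property
  the replay tests assert.

## Schema scoring

The original deployment used nine recurrent neural networks, one per
schema, to score each thought. Those weights are out of scope here; the
package instead defines a scorer *interface* (deterministic map from text
to nine activations in [0, 1]) with two implementations: a keyword
`lexicon_scorer()` and a trainable `train_baseline_scorer()` — nine
one-vs-rest ridge-penalized logistic regressions on binary bag-of-words
features, fit by IRLS with the intercept unpenalized (ridge λ = 1 on word
weights). Training has no random initialisation, so the model is fully
reproducible from the corpus alone and serializes to a single JSON file.

Activations map to the ordinal presence scale 0–3 through equal-width
half-open bins ([0, .25), [.25, .5), [.5, .75), [.75, 1]); the original
mapping is unpublished, so the bin edges are configurable. The utterances
scored are the automatic thought and every downward-arrow step — not the
situation/emotion/behavior fields — and a record's nine-vector is the
element-wise **maximum** over its scored utterances: any single thought
revealing a schema marks it present for the record, matching the
"one or multiple schemas may have been activated" semantics. Frequency
distributions over schemas are computed per utterance after recoding the
ordinal labels to presence/absence (0 stays 0, anything positive becomes
1).

## Feedback composition

Feedback bundles are structured data, not pixels; rendering is left to the
caller. Invariants asserted throughout: the text of a lower tier is a
prefix of every higher tier, the step chart appears from medium upward,
the spider only at high. Two conventions were open:

* the step-count percentile uses the *strictly fewer* convention
  (percentage of reference people with fewer steps than the current
  record), documented and monotone in the step count;
* the orange "aggregate" spider dots are the element-wise **mean** of the
  per-record vectors of *previous* records only (the published description
  shows one aggregate dot per axis and says "previous thought records";
  the current record is excluded).

The historical step-count histogram is not published; the package ships a
synthetic right-skewed default (`default_reference_distribution()`),
replaceable by a YAML file.

## Screening, bucketing, and minimization

Eligibility uses the PHQ-9 subclinical window 4 < score < 8 (strict on
both sides: 5–7 eligible). Need-for-self-reflection (NSR) scores are cut
into low/medium/high buckets by two half-open cut-points — defaults are
the tertiles of a supplied reference sample because the study's boundaries
are unpublished. Condition assignment is single-variate minimization: each
participant joins the arm with the fewest previous assignments in their
NSR bucket, ties broken uniformly at random. Tie-break draws come from a
decision-indexed substream of the state's seed, so a persisted allocation
state resumes deterministically. A biased-coin variant (take the
minimizing arm with probability p < 1) sits behind a flag; plain
minimization is the default. Under the plain rule the within-bucket
max−min arm spread can never exceed 1, which the property tests verify
over thousands of random streams.

## Measures

Subscale scores are plain item sums (engagement: 6 items on 1–6, so 6–36).
Cronbach's α uses the standard variance decomposition; its confidence
interval uses Feldt's F-distribution method (df `n−1` and `(n−1)(k−1)`),
chosen because it is parametric and tight at trial-size n, with a
bootstrap interval behind a flag. The Box-Cox λ is the maximizer of the
usual normal profile log-likelihood, found with `stats::optimize` on
(−5, 10); λ is estimated **once** on the outcome vector and reused across
models rather than re-estimated per model. Values of |λ| < 1e−5 fall back
to the log to keep the transform continuous at the removable singularity.

## The analysis pipeline

The mediation logic follows the stepwise (Baron–Kenny) sequence with
treatment coding and **low** richness as the reference level:

1. direct effects — Poisson GLM (log link) for the voluntary-record count,
   linear model on Box-Cox-transformed engagement;
2. a-path — linear model `insight ~ condition`;
3. b-paths — `outcome ~ insight + condition` (Poisson for the count, with
   `exp(b_insight)` reported as a rate ratio; linear for engagement);
4. moderation — `outcome ~ condition × nsr`. The analysis plan describes
   these as *linear* regressions for both outcomes, so the count outcome
   is modelled linearly by default, with a Poisson variant behind a flag;
   the discrepancy is deliberate and documented here.

`run_baron_kenny()` fits everything, records a decision trail (was the
a-path significant; was mediation supported; moderated mediation is not
tested when mediation is absent), and never drops a model. α = 0.05
two-sided throughout, no multiple-testing correction, and degrees of
freedom are computed from the data rather than copied from anywhere.
Agreement statistics for the content labels are Cohen's κ with
marginal-product chance agreement (undefined and reported as `NA` when
both coders are constant and identical) and per-label mean relative
frequency, defined as the mean of the two coders' label frequencies (the
reconciliation rule behind published MRF values is unstated; the mean is
the symmetric choice and is configurable).

## The power simulation

The sample-size question: how many participants does the three-arm design
need for 80% power to detect the indirect (mediated) effect at α = 0.05,
when condition explains 13% of mediator variance (a-path) and the mediator
explains 13% of latent outcome variance given condition (b-path)?

The generator solves its coefficients from those explained variances:

* condition arms are balanced with equally spaced mediator means
  (−d, 0, d) and unit residual SD, so `R²_a = (2d²/3)/(2d²/3 + 1)` gives
  `d = sqrt(3 R²_a / (2 (1 − R²_a)))`;
* the count outcome is Poisson with log-rate `b₀ + b₁ M + u`,
  `u ~ N(0, 1)` mirroring the mediator equation; the partial-R² definition
  with `Var(M | condition) = 1` gives `b₁ = sqrt(R²_b / (1 − R²_b))`;
* `b₀` is solved in closed form (lognormal moments) so the marginal count
  mean equals the configured baseline rate, default 1.6 — the observed
  mean number of session-2 records.

The test statistic is the bias-corrected (BC) bootstrap interval for the
product `a·b`, where `a` is the condition contrast in the a-path linear
model and `b` the mediator coefficient in the b-path Poisson model; the
default contrast is maximum richness vs reference, with the adjacent
contrast available. Per bootstrap resample both models are refit (via
fast fixed-design fitters, cross-checked against `glm`/`lm` in the unit
tests); the bias factor `z₀ = Φ⁻¹(fraction of bootstrap estimates below
the point estimate)` shifts the percentile interval. Degenerate resamples
(an arm lost, constant mediator) are redrawn with a bound. Power at n is
the fraction of replicates whose interval excludes zero; `find_min_n()`
scans the configured grid and reports the smallest n at or above the
target, or an explicit "increase the grid" result.

Two properties of this estimand deserve emphasis because they shape what
calibration checks can show. First, with both paths at a realistic 13%,
the a-path is detected essentially always at trial sizes, so the power
curve is driven by the b-path and rises quickly; on the default grid
(250–350) the curve is already above the 0.80 target at the grid floor.
Second, under the *joint* null (both paths ≈ 0) the product statistic is
conservative — the interval rejects far less often than α, a known
property of product-of-coefficients tests — so nominal-α behaviour should
be expected (and is asserted in the tests) under moderate effects, not
under the joint null.

Problem sizes used by the shipped checks: the desk-scale preset runs 200
replicates × 500 bootstrap resamples per grid point over six grid points;
coverage checks use 1,000 replicates at n = 150 with B = 300; estimator
recovery uses n = 5,000. These sizes give Monte-Carlo SEs of ~0.03 on a
power estimate near 0.8 and were chosen as the smallest runs that keep
those SEs informative.

## The synthetic-participant simulator

Everything above is exercised without any external data:

* **Transcript scripts** drive the engine to completion: personas carry a
  schema mixture profile, a chain-depth distribution (geometric by
  default), an early-stop probability, and a verbosity level. Utterance
  text is assembled from schema-specific keyword templates, so the
  ordinal label of each generated utterance is known by construction
  (template strength 1–3 = ordinal code).
* **Likert generation** uses a one-factor model with the loading solved
  from the target α via the Spearman–Brown identity, then *inflated* by
  the analytically computed attenuation caused by discretizing to the
  response scale, so the realized α of the discrete data matches the
  target.
* **Study tables** wire the pieces together: NSR scores → tertile buckets
  → minimization assignment → insight, engagement and counts from
  configurable structural equations. Counts are 1-truncated Poisson
  (session 2 mandated a record), so tables satisfy the ≥ 1 invariant by
  construction; engagement is rounded and clipped to 6–36, which produces
  the ceiling skew of the real measure when the intercept sits near the
  ceiling. Because the analysis pipeline fits a *plain* Poisson GLM (as
  the analysis plan specifies) to a truncated count, the b-path
  coefficient recovered from truncated tables is attenuated relative to
  the generating value; the tests account for this, and the power module
  generates untruncated counts as its own generator specifies.

What the simulator does *not* emulate: the linguistic register of real
participants (template text is deliberately artificial), missing data,
attention-check failures, or drop-out between sessions. Passing tests
therefore demonstrate the correctness of the machinery and the internal
consistency of the statistics, not linguistic validity of the scorer on
real text.

## Known limitations

* The three unnamed schemas in the default `schema_set()` are placeholder
  labels; supply the canonical nine when available.
* The baseline scorer is a linear bag-of-words model; it deliberately does
  not reproduce the original networks' accuracy, only the pipeline role.
* The deposited trial dataset is not shipped; the reproduction path in the
  acceptance tests activates only when that table is placed at the
  documented location.
* Reported percentile/aggregation conventions (strictly-fewer, mean
  aggregation, mean-of-coders MRF) are documented choices where the
  published description is silent; all are configurable or clearly
  isolated.
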