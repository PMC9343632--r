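# thoughtrec

Conversational thought recording with tiered feedback, plus the full trial
machinery around it.

## The problem

Thought records are the core homework exercise of cognitive therapy: in an
emotionally difficult situation the patient writes down what happened
(situation), how it felt (emotion), what went through their mind (the
automatic thought), and what they did (behavior), and then uses the
*downward-arrow technique* — repeatedly asking what the thought would mean
about them — to surface the underlying core belief (*schema*). Adherence
to this homework is notoriously poor, and one candidate remedy is a
conversational agent that collects thought records in dialogue and gives
increasingly rich feedback: a simple acknowledgment (low), a chart of the
user's downward-arrow step counts against a reference distribution
(medium), or a nine-axis spider chart of the schemas an NLP scorer detects
in the recorded thoughts (high).

`thoughtrec` is for researchers building or evaluating such a system. It
provides:

* a deterministic, replayable **dialogue engine** for the two-session
  protocol (two mandatory scenario-based practice records, then personal
  records at will, at least one);
* a pluggable nine-schema **utterance scorer** with a transparent
  bag-of-words baseline (nine one-vs-rest ridge logistic regressions);
* **feedback composition** for the three richness tiers, as structured
  data with strict low ⊂ medium ⊂ high nesting;
* **screening and randomization**: the PHQ-9 subclinical window
  4 < score < 8, need-for-self-reflection (NSR) bucketing, and
  single-variate minimization with random tie-breaks;
* **measures**: Likert subscale sums, Cronbach's α with a Feldt interval,
  Box-Cox transformation with maximum-likelihood λ;
* the **analysis pipeline**: the stepwise (Baron–Kenny) mediation
  sequence — Poisson GLM for the count of voluntarily completed records,
  linear models for Box-Cox-transformed engagement, insight as mediator,
  NSR moderation checks — with a machine-readable decision trail;
* a **power simulation** for the 3-arm/mediator/Poisson-outcome design
  using bias-corrected bootstrap intervals for the indirect effect
  `a·b`, with per-path effect sizes given as explained variance;
* a **synthetic-participant simulator** (scripted chat users, labelled
  corpora, Likert data with target reliability, full study tables) so
  every module is testable end to end without any data download.

## The statistics at the core

With condition *X* (low/medium/high feedback richness, low = reference),
mediator *M* (insight), count outcome *Y₁* (voluntary thought records) and
continuous outcome *Y₂* (engagement, Box-Cox transformed):

* direct: `Y₁ ~ Poisson(exp(β₀ + βX))`, `bc(Y₂) = β₀ + βX + ε`
* a-path: `M = α₀ + aX + ε`
* b-path: `Y ~ insight + condition`, with `exp(b)` reported as the rate
  ratio per insight point for the count outcome
* indirect effect `a·b`, tested by the bias-corrected bootstrap interval:
  resample rows, refit both paths, shift the percentile interval by
  `z₀ = Φ⁻¹(#{boot < estimate}/B)`.

The power generator solves its coefficients from per-path explained
variance (default 13% on each path, the "medium effect" the design is
powered for): arm means `(−d, 0, d)` with
`d = √(3R²ₐ / 2(1−R²ₐ))` and unit mediator noise, and Poisson log-rate
`b₀ + b₁M + u` with `b₁ = √(R²_b/(1−R²_b))`, `u ~ N(0,1)`, `b₀` calibrated
so the marginal count mean is 1.6.

## Worked example

```r
library(thoughtrec)

# a full synthetic trial: NSR -> buckets -> minimization -> outcomes
cfg <- study_gen_config(n = 306, b_count = 0.03, b_engagement = 0.4, seed = 11)
tab <- generate_study_table(cfg)
mean(tab$n_voluntary_records)
#> [1] 1.68

rep <- run_baron_kenny(tab)
rep$models$bpath_count
#> <model_report 'b-path: voluntary records ~ insight + condition'> family=poisson, n=306, residual df=302
#>             term estimate     se      z     p
#>      (Intercept)  0.43100 0.3030  1.420 0.155
#>          insight  0.00466 0.0114  0.410 0.682
#>  conditionmedium -0.06500 0.1080 -0.602 0.547
#>    conditionhigh -0.02750 0.1070 -0.257 0.797
#>   rate ratio per insight point: exp(b) = 1.005
rep$decisions[1:2]
#> [1] "a-path (condition -> insight) not significant at alpha = 0.05"
#> [2] "direct effect on count not significant; b-path (insight) not significant"
```

The mean of 1.68 voluntary records per participant and the near-1 rate
ratio mirror the structure of a trial in which feedback richness has no
effect: the generator's defaults encode exactly that null configuration,
and the decision trail shows the pipeline correctly declining to pursue
mediation. Setting `a_path = c(0, 1.5, 3)` (insight points per arm) or a
larger `b_count` produces tables where the trail reports mediation
support instead.

Driving the chatbot itself:

```r
res <- start_session(1, "high", seed = 7)      # onboarding + first scenario
persona <- persona_config(schema_profile = c(1, rep(0, 8)))  # attachment themes
script <- generate_transcript_script(persona, session_index = 1, seed = 3)
final <- run_script(res$state, script)
length(final$completed_records)                # 2 scenario records
final$last_feedback                            # spider + step chart + text
```

A thin CLI over the same functions lives at `inst/cli/thoughtrec.R`
(subcommands `chat`, `score`, `allocate`, `analyze`, `power`, `synth`).

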