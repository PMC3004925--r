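---
title: "Non-functional distractors and option reduction: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Non-functional distractors and option reduction: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(distractlab)
```

## The problem

High-stakes medical examinations typically use one-best-answer items with
five options: one correct answer and four distractors. A distractor only
does its job if candidates with knowledge gaps actually choose it. In
practice many distractors are so implausible that almost nobody selects
them; these are called **non-functional distractors (NF-D)**, convention-
ally defined by a selection rate strictly below 1% (conservative) or 5%
(lenient) of the candidate group. `distractlab` answers three questions
about them:

1. How common are NF-Ds, and how does their frequency relate to item
   difficulty and discrimination?
2. What would happen to the exam's psychometric quality if the rarely
   chosen distractors were dropped (reducing items from 4 distractors to
   3 or 2)?
3. Can experts prospectively identify NF-Ds by judging plausibility, and
   what happens if the *panel's* recommendation drives the reduction?

## Statistics used

For a response matrix of `n` candidates by `k` items scored 0/1 against
the key:

* **Difficulty (P-value):** percent correct per item; omissions count as
  incorrect, so the denominator is always the full candidate group.
* **Discrimination (selectivity, r):** Pearson correlation between the
  item's correctness vector and the *rest score* (total minus the item's
  own point). The item-rest form is the default because the item-total
  form is inflated by self-correlation on exams of this length; an
  `type = "item-total"` option is provided. Items with a constant
  correctness vector (P = 0 or 100) have undefined discrimination and are
  reported as `NA`.
* **Cronbach's alpha:** `k/(k-1) * (1 - sum(var_i)/var_total)` on the 0/1
  scores. Population (n-denominator) variances are used consistently; the
  convention cancels in the ratio but fixing it makes intermediate output
  reproducible.
* **Pooled discrimination:** correlations are averaged after Fisher-Z
  transformation, `tanh(mean(atanh(r)))`. Undefined values and `|r| = 1`
  (where `atanh` diverges) are excluded from the pool — pooling must stay
  finite and both cases carry no usable information about the mean.
* **Standard reliability:** the Spearman-Brown prophecy
  `k*rho / (1 + (k-1)*rho)` with `k = 100/n_items` projects alpha to a
  common 100-item length so exams of 41-57 items can be compared.

## Distractor analyses

`option_selection_rates()` counts every option over all candidates.
Thresholding is **strict**: a distractor selected by exactly 1% is
functional at the `<1%` threshold. This makes NF-D sets nested across
thresholds and matches the usual "selected by fewer than t%" reading.

The **delta-median** of a distractor is the median total score of the
candidates who selected it minus the median total score of the whole
group, in raw number-correct points (the midpoint-of-two convention is
used for even-sized sets). A distractor with a strongly negative
delta-median attracts specifically low-performing candidates — the
defining virtue of a good distractor, and notably a property that even
rarely selected distractors can retain. Records exist only for
distractors with at least one selector; a never-chosen distractor has no
delta-median rather than a zero one. We deliberately provide no
per-distractor discrimination indices: the selector samples are small and
their score distributions skewed, so such indices would be noise.

## The option-reduction simulation

`statistics_plan()` identifies, per item and from the *original* matrix,
the least and second-least chosen distractors (ties broken by option
label, for reproducibility). `eliminate()` then removes them sequentially
and reallocates every candidate who chose a removed distractor under one
of two extreme behavioural assumptions:

* **CORRECT** — the candidate had been oscillating between the removed
  distractor and the right answer and now picks the right answer. This is
  the upper bound on the induced easiness.
* **RANDOM** — the candidate picks uniformly at random among the options
  remaining *after that removal* (4 after the first, 3 after the second).
  This is the lower bound; real candidates use educated guessing and land
  somewhere between the two.

The four models are A (1 removal, random), B (1, correct), C (2, random)
and D (2, correct). Removal of a distractor nobody chose changes no
responses — such items pass through bit-identically. Under RANDOM mode a
candidate reallocated onto the second-least distractor in step one is
reallocated again in step two; both removal targets are fixed from the
original counts before any reallocation. All randomness is driven by an
explicit seed.

One semantic subtlety is configurable: `random_over_five = TRUE`
reproduces a literal uniform draw over all five original option codes, in
which a candidate may be "reallocated" onto the removed option or back
onto their own choice. The default draws over the remaining options only,
which is what "allocated to one of the remaining options by chance"
means; the flag exists to quantify how little the choice matters.

`run_models()` assembles the comparison table: the untouched
"4 distractors" row plus one row per model, each with mean P, pooled
discrimination, alpha and the 100-item standard reliability. An optional
`nfd_only` plan restricts removals to classified NF-Ds, yielding variable
distractor counts per item and, as expected, effects bounded by the full
least/second-least plan.

## Expert survey analysis

Experts mark, per item, the most obviously wrong option (rank 1) and the
next most obviously wrong (rank 2); two rank-1 marks declare a tie. A
**hit** is a rank-1 mark landing on a distractor that truly is an NF-D by
selection rate; tied marks are resolved by a fair seeded coin before
testing (`expert_hit()` derives a per-(expert, item) stream from the base
seed so results do not depend on processing order). Hit analysis is
restricted to items with at least one NF-D, and the association between
per-item hit proportion and NF-D count is a plain Pearson correlation.

The **panel** decision (`panel_mode()`) operationalizes "mode of the
experts" for *two* removals: options are scored 2 points per rank-1 and 1
point per rank-2 mark, and the top two scores give the first and second
removal (ties broken by label and flagged). The weighted score is a
design choice — the mode is only defined for the least-plausible pick —
and `second_from_rank2_mode = TRUE` offers the alternative of taking the
plain mode of the rank-2 marks. `panel_plan()` turns the panel columns
into an elimination plan so the option-reduction table can be recomputed
under expert guidance instead of item statistics.

## The synthetic exam generator

Real licensing-exam responses are confidential, so `generate_exam()`
produces exams with the statistical structure the analyses assume, from a
nominal-response (softmax) choice model: candidate `c` with ability
`theta_c ~ N(0,1)` chooses option `k` of item `i` with probability
proportional to `exp(alpha_k * theta_c + beta_k)`.

* The correct option has slope `a_i ~ N(0.5, 0.125)` (truncated at 0.3)
  and intercept `b_i ~ N(2.6, 0.8)`; the intercept sets easiness.
* Functional distractors have `beta ~ N(0, 0.4)` and a mildly negative
  ability loading (-0.15), so their selectors sit somewhat below the
  median.
* Designed NF-Ds have `beta ~ N(-4.5, 0.4)` and a strongly negative
  loading (-1.0): they are rare, and the few candidates they attract are
  weak — which is exactly the delta-median contrast the analysis should
  detect. A fraction (12%) receive `beta = -30`, numerically never
  selected.
* The number of designed NF-Ds per item is drawn with probabilities
  (0.303, 0.319, 0.231, 0.113, 0.035) for 0-4, mirroring the mix reported
  for large medical examinations.

A softmax model was preferred over a knowledge-or-guess mixture because
it controls selection rates and ability gradients continuously with few
parameters. The defaults were fixed once against the study-scale
conditions — 620 candidates, 55 items, mean P in the high 70s, about a
third of distractors below 1% — and produce mean P ≈ 78, pooled r ≈ 0.22,
alpha ≈ 0.78 and delta-medians of about -3 (functional) versus -8
(non-functional) points.

What the generator does **not** emulate: omissions are off by default
(the emulated exams were compulsory; an `omit_rate` knob exists), items
are conditionally independent given ability (no content clustering or
cueing), there is no testwiseness or educated guessing, and the
never-selected share runs near 14% of distractors rather than the ~7%
seen in real data — with 620 candidates, NF-D rates low enough to be
reliably classified below 1% inevitably produce more chance zeros.
Passing tests therefore show the pipeline recovers a *known* design; they
do not certify any particular real exam's NF-D frequency.

`generate_ratings()` simulates the survey: items are split into two
blocks with 18 experts each; an expert of accuracy `p` rank-1-marks the
truly least plausible distractor (lowest generating `beta`) with
probability `p`, otherwise a random other distractor, analogously for
rank 2, with ties injected at a configured probability. Accuracy 0.25 is
exactly chance over four distractors, giving the analytic `k/4` hit
probability for items with `k` NF-Ds.

## Numerical conventions and test scale

Ties anywhere (removal ranking, panel votes, plausibility ordering) break
by option-label order. Thresholds are strict (`rate < t`). Medians use
the midpoint convention. Percentages print to one decimal and
reliabilities to two, matching standard report precision; nearest-percent
rounding is used for hit rates. The test suite exercises the pipeline on
100 random small matrices against brute-force oracles, 20 replicates of
the full 620 x 55 design for recovery and model-ordering properties, and
1000 seeded replicates of a 100 x 20 exam for the binomial reallocation
expectation — sizes chosen to make Monte-Carlo error small relative to
the tested effects.

## Limitations

Classical test theory ties every statistic to the sample at hand; the
simulation inherits that. The two reallocation models are deliberate
extremes, not behavioural predictions. Rasch-based re-equating of pass
marks after option reduction is out of scope, as are inter-rater
reliability coefficients for the expert survey.
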