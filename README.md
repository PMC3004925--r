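# distractlab

Distractor analysis and option-reduction simulation for one-best-answer
multiple-choice examinations.

Large medical exams typically present five options per item, yet many of
the four distractors are so implausible that almost no candidate picks
them. `distractlab` is for psychometricians and assessment units who want
to know, from a response matrix and an answer key:

* which distractors are **non-functional** (NF-D) — selected by fewer
  than 1% (or 5%) of candidates — and how NF-D frequency relates to item
  difficulty and discrimination;
* whether rarely selected distractors still attract specifically
  low-performing candidates (**delta-medians**: median total score of a
  distractor's selectors minus the whole-group median);
* what would happen to difficulty, discrimination and reliability if the
  least-chosen distractors were removed, bracketed by two extreme
  candidate behaviours (random reallocation vs. switching to the correct
  answer — models A–D);
* how well **experts** judging option plausibility, individually and as a
  majority panel, recover the NF-Ds, and what an expert-driven reduction
  would do to the same statistics.

The classical-test-theory core: item difficulty `P` (percent correct),
item-rest point-biserial discrimination `r`, Cronbach's alpha
`α = k/(k−1)·(1 − Σσ²ᵢ/σ²ₜ)`, Fisher-Z pooling `tanh(mean(atanh r))`, and
Spearman-Brown standardization to 100 items
`α₁₀₀ = kα/(1+(k−1)α)`, `k = 100/n_items`.

A nominal-response (softmax) simulator generates realistic synthetic
exams — ability-linked option choice, designed NF-Ds, low-ability loading
on implausible distractors — plus synthetic expert ratings, so the entire
pipeline is testable without confidential examination data.

## Worked example

```r
library(distractlab)

ex <- generate_exam(exam_config(), seed = 2026)   # 620 candidates x 55 items

nfd_count_distribution(ex$responses, ex$key, threshold = 1)
#>   n_nfd n_items pct_items
#> 1     0      17 30.909091
#> 2     1      17 30.909091
#> 3     2      14 25.454545
#> 4     3       6 10.909091
#> 5     4       1  1.818182

delta_median_summary(ex$responses, ex$key, threshold = 1)
#>   class   n median   min max
#> 1   F-D 153  -3.00  -8.0   1
#> 2  NF-D  38  -6.25 -16.5   6

tab <- run_models(ex$responses, ex$key, seed = 1)
round_df <- function(d) { d[-1] <- round(d[-1], 2); d }
round_df(tab)
#>                            model pct_correct discrimination reliability std_reliability_100
#> 1                  4 distractors       79.22           0.20        0.76                0.85
#> 2       A) 3 distractors, random       79.58           0.20        0.76                0.85
#> 3 B) 3 distractors, right answer       80.73           0.19        0.75                0.84
#> 4       C) 2 distractors, random       80.78           0.19        0.74                0.84
#> 5 D) 2 distractors, right answer       84.26           0.16        0.70                0.81
```

Read the table as: about 69% of items have at least one NF-D below the 1%
threshold; NF-D selectors sit roughly twice as far below the group median
(−6.25 points) as selectors of functional distractors (−3.00); and
dropping one or even two rarely chosen distractors barely moves
discrimination or standardized reliability — only model D (two removals
*and* every affected candidate switching to the correct answer) makes the
exam markedly easier (+5 points of mean P) and less reliable.

The expert side, with the default simulated panel:

```r
ratings <- generate_ratings(ex$truth, ex$key, rating_config(), seed = 3)
panel   <- panel_ratings(ratings, ex$key)
panel_hit_rate(panel, ex$responses, ex$key, threshold = 1)
#> $n_hits   38
#> $n_items  38
#> $pct      100
```

CSV input/output for responses (long or wide), keys, expert ratings and
fixed-format report tables is in `read_responses()`, `read_key()`,
`read_expert_ratings()` and `write_table()`.

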