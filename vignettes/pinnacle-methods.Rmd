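---
title: "PINNACLE: model, design decisions and numerical methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{PINNACLE: model, design decisions and numerical methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pinnacle)
```

## The model

PINNACLE is a dual-system account of visual category learning. Two
decision-bound learners watch the same two-dimensional stimulus stream
(x = spatial frequency, y = orientation, arbitrary units in a
`[0, 300]` square):

* the **rule-based (RB) system** carries a one-parameter vertical
  boundary: its signed distance to a stimulus is `x - b_RB`;
* the **information-integration (II) system** carries a slope-1 diagonal
  boundary `y = x + b_II`: its signed distance is
  `(y - x - b_II) / sqrt(2)`.

Negative distances are the category-A side. Each system also carries a
*perceptual-shaping* parameter `ps`, the spread of an isotropic Gaussian
centred on the stimulus; the probability the system assigns to category
A is the mass of that Gaussian on the A side of its boundary, which
reduces to a normal CDF of `-distance / ps`
(`category_probability()`). The CDF is deliberately the classical
four-constant rational-polynomial approximation (absolute error below
2.5e-4), implemented in `std_normal_cdf()`; it is the model's
probability primitive, not a numerical shortcut, so it is hand-rolled
and oracle-tested against numeric integration rather than replaced by
`pnorm()`.

On every trial both systems predict, and their confidences
(`max(p, 1 - p)`) are converted to betting odds `conf / (1 - conf)`
(`odds()`). A Gaussian noise term with standard deviation `dm_noise` is
added to the RB system's odds, and the larger noisy odds wins the
competition (`select_system()`). The winner's p(A) then produces the
overt response by **probability matching** (`emit_response()`): the
response is sampled, not arg-maxed, so a system 80% sure of category A
answers A on about 80% of such trials.

Feedback is routed by one of twelve policies (`feedback_policies()`,
`route_feedback()`): the winner only, both systems, correct trials only,
error trials only, and the asymmetric combinations in between. Policy 2
(both systems learn on every trial) is the package default, being the
policy the model's original group calibration selected. Each *routed*
system updates against its **own** prediction, not the overt response:
when its prediction was right its `ps` shrinks by `1 - ps_lr`
(confidence grows); when wrong its boundary moves by
`lr * |signed distance|` toward the stimulus's true side and `ps` grows
by `1 + ps_lr` (`apply_feedback()`). Boundaries initialize to the
average position of the first two stimuli (`init_boundaries()`), like a
participant with no prior knowledge.

## Parameters and defaults

`model_params()` defaults to the reference operating point obtained by
group fitting under policy 2: `rb_lr = 0.1703`, `ii_lr = 0.0288`,
`ps_lr = 0.5382`, `ps_init = 145932`, `dm_noise = 1.2043`. Two points
deserve comment.

* **`ps_init` is not scaled to the stimulus space.** One might expect
  the starting shaping value to sit at the extent of the space (~300).
  In practice the dynamics depend on `ps_init` only logarithmically —
  `ps` shrinks geometrically by `1 - ps_lr` per correct trial — and an
  extent-scale start collapses to confident responding within a few
  trials, producing a flat, near-ceiling learning curve. The large
  reference value encodes near-total starting *un*certainty and yields
  the gradual, human-shaped rising curves the simulator is meant to
  emulate.
* **`single_lr_mode`** constrains the two boundary learning rates to be
  equal, giving the 4-parameter variant used as the nested comparison
  model: data generated with distinct rates cannot be matched by it,
  which the test suite asserts.

## The stimulus generator

`make_structure()` defines the two classic conditions: RB (vertical
bound at 150) and II (diagonal `y = x`). Category means sit at
perpendicular offset `width/6 = 50` on either side of the bound, and
stimuli are drawn in bound-aligned coordinates with standard deviation
20 perpendicular to the bound and `elongation = 4` times that along it,
with rejection of draws that leave the space or cross the bound (labels
are therefore noiseless).

The elongation is essential, not cosmetic. With isotropic categories the
diagonal condition is ~96% solvable by a single-dimension vertical rule,
which contradicts the defining property of an information-integration
structure; with elongation 4 the best single-dimension rule reaches only
~74% while the perpendicular separation is untouched. This mirrors the
elongated Gabor-set geometry standard in this literature.

`generate_sequence()` balances categories within each 80-trial block and
stamps stimulus onsets from the trial timing (0.75 s fixation + 2 s
stimulus + 0.5 s mask + 0.75 s feedback = 4 s per trial) plus zero to
five uniformly drawn 4-second null periods, the jittered spacing an
event-related design needs.

## Group fitting

`run_group()` simulates `n_runs` seeded sessions per condition and
summarizes the 8 block-accuracy means and 8 SDs. `fit_group()` minimizes
the weighted sum of squares (SD discrepancies down-weighted by
`sd_weight = 0.001`) by Nelder-Mead downhill simplex (`stats::optim`) on
transformed scales: log for the learning rates, `ps_init`, and
`dm_noise`; **logit for `ps_lr`**, which must stay below 1 for `ps` to
remain positive after correct-trial updates — a plain log transform
would not enforce the upper bound. The logit back-transform is clamped
at `1 - 1e-9` because large optimizer steps otherwise round to exactly
1 in double precision. A soft quadratic box penalty steers the simplex
away from numerically degenerate territory (runaway rates or shaping
scales) without hard walls.

Every objective evaluation reuses the same per-run seeds (common random
numbers), so the optimizer sees a deterministic surface and the
self-fit objective is exactly zero. `compare_feedback_models()` runs the
same fit once per policy and returns the leaderboard.

## Individual fitting

`fit_individual()` fits a participant's trial table by maximum
likelihood under a deterministic replay (`replay_subject()`): on each
trial the system whose prediction better matches the observed choice is
imputed as responsible, the trial likelihood is that matched probability
(floored at 1e-6), and feedback routes by the responsible system and the
observed correctness. Missing responses contribute no likelihood and
trigger no update. Two consequences shape the implementation:

* **`dm_noise` is structurally unidentifiable** here — no winner is ever
  sampled during replay — so the simplex runs over 4 parameters and
  `dm_noise` passes through from the starting values.
* **A single session mainly identifies the dominant system's learning
  rate.** Under the max-match rule the off-system rarely wins the
  match, so its rate barely enters the likelihood. `fit_individual()`
  therefore accepts a *list* of sessions (for example one RB-condition
  and one II-condition session of the same subject) and sums their
  log-likelihoods; joint fits identify both rates.

Likelihood information is concentrated in each session's early learning
transient: once `ps` has collapsed, predictions saturate and most trials
contribute essentially zero log-likelihood. The parameter-recovery study
shipped in the acceptance tests therefore uses the paired cohort design
of `cohort_spec(paired = TRUE, n_sessions = 4)`: 20 synthetic subjects,
each completing 4 RB and 4 II sessions with per-subject jittered rates,
fitted jointly with two simplex restarts. Under that design rank
correlations between true and recovered rates exceed 0.9 and median
relative errors are below 10% across master seeds.

## Trial classification

Given a replay at fitted parameters, `classify_competition()` labels
each trial high-competition (`C`: both systems more than 75% confident
with different predictions), non-competition (`NC`: exactly one system
confident) or `undefined`; the threshold is a strict inequality.
`best_fit_blocks()` ranks blocks by summed trial log-likelihood and
keeps the top third (ceiling, ties toward the lower block id).
`tag_off_system()` scores the losing system's covert prediction against
the truth, and `write_events()` lays these labels out in an events table
(onset/duration first, in seconds) ready for GLM regressor construction.

## Numerical conventions

* Category A is the negative side of every signed distance; exact ties
  (a stimulus on the bound, p(A) = 0.5) resolve to B everywhere.
* Responsible-system ties in the replay resolve to RB.
* Confidences are clamped to `1 - 1e-12` before the odds ratio; `ps` is
  floored at 1e-300 so it can never reach exactly zero.
* One selection-noise draw is consumed per trial even when
  `dm_noise = 0`, so traces are reproducible across noise settings; the
  per-trial draw order is fixed (selection noise, tie-break if needed,
  response draw), and the compiled C++ loop consumes R's own RNG stream,
  making it byte-identical to the pure-R reference engine
  (`engine = "r"`).
* All derived seeds stay below 2^31; `run_group()`,
  `pregenerate_sequences()` and `generate_cohort()` derive per-run seeds
  from a base seed and a purpose-specific lane so sequence randomness,
  session randomness and jitter never alias.

## Problem sizes

A 320-trial session simulates in well under a millisecond in the
compiled engine; 1,000-session group summaries take about a second, so
group fits and the 12-policy tournament run in tens of seconds, and the
full 20-subject recovery study in a few seconds. The pure-R engine is
~100x slower and exists as the readable reference implementation.

## Limitations

The package emulates the *generating conditions* of the original
behavioral calibration (stimulus geometry, timing, cohort sizes); it
does not ship human data, so published fit values, accuracies and
reaction times are not reproduction targets. Reaction times are carried
through the IO layer when present but no RT model is implemented.
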