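# pinnacle

Simulation, fitting and trial-classification machinery for **PINNACLE**,
a dual-system decision-bound model of visual category learning.

Human category learning appears to draw on (at least) two systems: an
explicit, rule-based (RB) learner that tests verbalizable
single-dimension rules, and an implicit, information-integration (II)
learner that combines stimulus dimensions pre-decisionally. PINNACLE
instantiates both as decision-bound learners that run *in parallel* on
the same trials and compete to produce each response, which makes it
possible to ask questions that single-system models cannot: which
system produced a given trial's response, what the losing system would
have said, and how feedback should be shared between them.

## The model in brief

Stimuli live in a 2-D space (x = spatial frequency, y = orientation).
Each system carries a one-parameter boundary and a perceptual-shaping
spread `ps`:

* RB: signed distance `x − b_RB` (vertical bound);
* II: signed distance `(y − x − b_II) / √2` (slope-1 diagonal bound);
* p(A) = Φ*(−distance / ps), where Φ* is the classical four-constant
  normal-CDF approximation (|error| < 2.5e−4) — negative distances are
  the category-A side;
* each system's confidence `max(p, 1−p)` becomes odds
  `conf / (1 − conf)`; Gaussian noise (sd `dm_noise`) is added to the RB
  odds and the larger noisy odds drives the response, which is sampled
  from the winner's p(A) (probability matching);
* routed systems update from feedback against their own predictions:
  correct → `ps` shrinks by `1 − ps_lr`; wrong → the boundary moves
  `lr·|distance|` toward the stimulus's true side and `ps` grows by
  `1 + ps_lr`. Twelve routing policies (winner-only, both systems,
  valence-gated, and asymmetric mixtures) are implemented; policy 2
  (both systems learn on every trial) is the default.

Boundaries initialize to the average position of the first two stimuli,
so the model starts naive. The default parameters are the model's
reference calibration (`rb_lr = 0.1703`, `ii_lr = 0.0288`,
`ps_lr = 0.5382`, `ps_init = 145932`, `dm_noise = 1.2043`).

## Worked example

Simulate one session of the information-integration condition and look
at the learning curve:

```r
library(pinnacle)

structure_ii <- make_structure("II")
sequence <- generate_sequence(structure_ii, n_trials = 320,
                              block_size = 80, seed = 1)
session <- run_session(model_params(), sequence, seed = 2)
session
#> <session_result> 320 trials, block accuracy: 0.925 0.975 0.963 0.988
round(session$rb_win_fraction, 3)   # the II system takes over quickly
#> [1] 0.038 0.000 0.000 0.000
```

Summarize a simulated group, the quantity group fitting targets:

```r
structs <- list(RB = make_structure("RB"), II = make_structure("II"))
run_group(model_params(), structs, n_runs = 200, base_seed = 1)
#>   condition block mean_acc sd_acc
#> 1        RB     1    0.876 0.0634
#> 2        RB     2    0.971 0.0281
#> 3        RB     3    0.981 0.0205
#> 4        RB     4    0.987 0.0161
#> 5        II     1    0.830 0.1210
#> 6        II     2    0.906 0.0997
#> 7        II     3    0.923 0.0811
#> 8        II     4    0.934 0.0651
```

Fit one synthetic participant by maximum likelihood. Both learning
rates are identified only when sessions from both conditions are fitted
jointly, so the cohort generator has a paired design:

```r
truth <- model_params(rb_lr = 0.25, ii_lr = 0.04, dm_noise = 0.1)
spec <- cohort_spec(params = truth, lr_jitter = 0, master_seed = 1,
                    paired = TRUE, n_paired = 1, n_sessions = 4)
subject <- generate_cohort(spec)$behavior[[1]]   # 8 sessions, 4 RB + 4 II
fit <- fit_individual(subject, model_params(dm_noise = 0.1),
                      individual_fit_config(restarts = 2))
fit
#> <fit_result> objective = 58.4795 after 302 evaluations (converged)
#> <model_params> rb_lr = 0.235971, ii_lr = 0.0369877, ps_lr = 0.772413,
#>   ps_init = 32642.2, dm_noise = 0.1, feedback_model = 2
```

Classify trials post hoc (high-competition `C` versus non-competition
`NC`), select best-fit blocks, and write a model-based events table:

```r
replay <- replay_subject(subject$II1, fit$best_params)
table(classify_competition(replay$p_a_rb, replay$p_a_ii))
best_fit_blocks(replay$block, log(replay$likelihood))
write_events(replay, "sub-01_events.tsv")
```

See `vignettes/pinnacle-methods.Rmd` for the full account of the model
equations, the stimulus-generator geometry, the fitting transforms, and
the identifiability analysis behind the paired recovery design.

## Tests

```sh
Rscript -e 'testthat::test_dir("tests/testthat", package = "pinnacle",
                               load_package = "installed")'
```

The suite covers every module plus nine acceptance tests
(`tests/testthat/test-acceptance.R`): probability matching, the CDF
approximation against numeric integration, bisected-Gaussian mass by
Monte Carlo, decision determinism and the Gaussian race, the 48-cell
feedback-routing truth table, rising learning curves with system
switching, 20-subject parameter recovery, the feedback-model tournament
with the nested single-learning-rate comparison, and the trial
classification partition.

## Reproducing results

`scripts/acceptance.R` recomputes the package's quantitative acceptance
target against the installed package and writes it as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out acceptance.json
#> t1: 79.9590% category-A responses (expected 80 +/- 0.3) -> PASS
```

Target `t1` is the long-run percentage of category-A responses emitted
by the probability-matching response rule at p(A) = 0.8, over 100,000
seeded draws (accepted within ±0.3 percentage points, ≈3 binomial
standard errors).
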