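structs <- list(RB = make_structure("RB"), II = make_structure("II"))

test_that("group_objective is zero against its own simulation", {
  cfg <- group_fit_config(structs, n_runs = 10, base_seed = 5)
  target <- run_group(model_params(), structs, n_runs = 10, base_seed = 5)
  expect_equal(group_objective(model_params(), target, cfg), 0)
})

test_that("group_objective grows away from the generating parameters", {
  cfg <- group_fit_config(structs, n_runs = 30, base_seed = 5)
  target <- run_group(model_params(), structs, n_runs = 30, base_seed = 5)
  near <- group_objective(model_params(rb_lr = 0.1703 * 1.2), target, cfg)
  far <- group_objective(model_params(rb_lr = 0.1703 * 4), target, cfg)
  expect_gt(near, 0)
  expect_gt(far, near)
})

test_that("sd_weight = 0 ignores the SD discrepancies", {
  cfg <- group_fit_config(structs, n_runs = 10, base_seed = 5,
                          sd_weight = 0)
  target <- run_group(model_params(), structs, n_runs = 10, base_seed = 5)
  warped <- target
  warped$sd_acc <- warped$sd_acc + 0.5
  p <- model_params(rb_lr = 0.3)
  expect_equal(group_objective(p, target, cfg),
               group_objective(p, warped, cfg))
})

test_that("fit_group recovers a self-generated target", {
  cfg <- group_fit_config(structs, n_runs = 20, base_seed = 5,
                          maxit = 120)
  target <- run_group(model_params(), structs, n_runs = 20, base_seed = 5)
  fit <- fit_group(target, model_params(rb_lr = 0.25, ii_lr = 0.02), cfg)
  expect_s3_class(fit, "fit_result")
  expect_lt(fit$objective_value, 5e-4)
  expect_gt(fit$n_evaluations, 10)
})

test_that("trial_likelihood applies the max-match rule", {
  expect_equal(trial_likelihood(0.8, 0.3, "A")$likelihood, 0.8)
  expect_equal(trial_likelihood(0.8, 0.3, "A")$responsible, "RB")
  expect_equal(trial_likelihood(0.8, 0.3, "B")$likelihood, 0.7)
  expect_equal(trial_likelihood(0.8, 0.3, "B")$responsible, "II")
  # ties resolve to RB; the floor binds only from below
  expect_equal(trial_likelihood(0.6, 0.6, "A")$responsible, "RB")
  expect_equal(trial_likelihood(1e-9, 1e-8, "A")$likelihood, 1e-6)
})

test_that("replaying a random responder gives a coin-flip likelihood", {
  sq <- generate_sequence(make_structure("RB"), 160, 80, seed = 13)
  beh <- sq
  set.seed(14)
  beh$response <- sample(c("A", "B"), 160, replace = TRUE)
  # no learning and a huge shaping value keep both p(A) pinned near 0.5
  p <- model_params(rb_lr = 0, ii_lr = 0, ps_lr = 0, ps_init = 1e8)
  rep <- replay_subject(beh, p)
  expect_equal(sum(log(rep$likelihood)), 160 * log(0.5), tolerance = 1e-3)
})

test_that("missing responses contribute no likelihood and no update", {
  beh <- simulate_behavior(make_structure("RB"), model_params(), 15, 16,
                           n_trials = 80, block_size = 80)
  beh2 <- beh
  beh2$response[10] <- NA
  r1 <- replay_subject(beh, model_params())
  r2 <- replay_subject(beh2, model_params())
  expect_true(is.na(r2$likelihood[10]))
  expect_true(is.na(r2$responsible[10]))
  # states at the missing trial carry forward: trial 11 sees the same
  # system probabilities as if trial 10 had updated... it must NOT have
  expect_equal(r2$p_a_rb[10], r1$p_a_rb[10])
  expect_false(isTRUE(all.equal(r2$p_a_rb[11], r1$p_a_rb[11])) &&
                 isTRUE(all.equal(r2$p_a_ii[11], r1$p_a_ii[11])))
})

test_that("replay is deterministic and matches the forward trace", {
  p <- model_params(dm_noise = 0.05, feedback_model = 2)
  beh <- simulate_behavior(make_structure("RB"), p, 17, 18,
                           n_trials = 160, block_size = 80)
  r1 <- replay_subject(beh, p)
  r2 <- replay_subject(beh, p)
  expect_identical(r1, r2)
  # policy 2 routes feedback identically regardless of the imputed winner,
  # so the replayed system probabilities equal the forward simulation's
  tr <- attr(beh, "session")$trace
  expect_equal(r1$p_a_rb, tr$p_a_rb)
  expect_equal(r1$p_a_ii, tr$p_a_ii)
})

test_that("fit_individual improves on the starting parameters", {
  truth <- model_params(rb_lr = 0.3, ii_lr = 0.05, dm_noise = 0.1)
  beh <- simulate_behavior(make_structure("RB"), truth, 19, 20)
  start <- model_params(rb_lr = 0.05, ii_lr = 0.01, dm_noise = 0.1)
  nll0 <- -sum(log(replay_subject(beh, start)$likelihood), na.rm = TRUE)
  fit <- fit_individual(beh, start, individual_fit_config())
  expect_lt(fit$objective_value, nll0)
  expect_s3_class(fit$best_params, "model_params")
  # dm_noise is not identified by the replay and passes through unchanged
  expect_equal(fit$best_params$dm_noise, 0.1)
  expect_s3_class(fit$trial_fits, "data.frame")
})

test_that("fit_individual accepts several sessions jointly", {
  truth <- model_params(dm_noise = 0.1)
  b1 <- simulate_behavior(make_structure("RB"), truth, 21, 22)
  b2 <- simulate_behavior(make_structure("II"), truth, 23, 24)
  fit <- fit_individual(list(b1, b2), truth,
                        individual_fit_config(maxit = 200))
  joint <- -sum(log(replay_subject(b1, fit$best_params)$likelihood),
                na.rm = TRUE) -
    sum(log(replay_subject(b2, fit$best_params)$likelihood), na.rm = TRUE)
  expect_equal(fit$objective_value, joint, tolerance = 1e-8)
  expect_length(fit$trial_fits, 2)
})

test_that("extra simplex restarts never worsen the best value", {
  truth <- model_params(dm_noise = 0.1)
  beh <- simulate_behavior(make_structure("RB"), truth, 25, 26,
                           n_trials = 160, block_size = 80)
  f1 <- fit_individual(beh, truth, individual_fit_config(restarts = 1))
  f2 <- fit_individual(beh, truth, individual_fit_config(restarts = 2))
  expect_lte(f2$objective_value, f1$objective_value)
})

test_that("compare_feedback_models returns a sorted 12-row leaderboard", {
  target <- run_group(model_params(), structs, n_runs = 10, base_seed = 31)
  cfg <- group_fit_config(structs, n_runs = 10, base_seed = 31, maxit = 15)
  lb <- compare_feedback_models(target, cfg)
  expect_equal(nrow(lb), 12)
  expect_setequal(lb$feedback, 1:12)
  expect_true(!is.unsorted(lb$fit_value))
  expect_true(all(c("rb_lr", "ii_lr", "ps_lr", "ps", "dm_noise") %in%
                    names(lb)))
})
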