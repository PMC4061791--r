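#' Configuration for group-level fitting
#'
#' Group fitting matches the simulated 8 block-accuracy means and 8 SDs
#' (4 blocks x 2 conditions) to an observed group summary by weighted sum
#' of squares, minimized by downhill simplex. The same per-run seeds are
#' reused on every objective evaluation (common random numbers), so the
#' optimizer sees a deterministic surface.
#'
#' @param structures Named list (`RB`, `II`) of [make_structure()] objects
#'   defining the stimulus distributions used for simulation.
#' @param n_runs Simulated sessions per condition per objective evaluation.
#' @param base_seed Integer seed anchoring all simulation randomness.
#' @param sd_weight Weight on the squared SD discrepancies relative to the
#'   squared mean discrepancies (default 0.001, so means dominate).
#' @param n_trials,block_size Session design.
#' @param reltol,maxit Simplex convergence tolerance and evaluation budget.
#' @param restarts Number of simplex starts (first from the supplied
#'   initial parameters, the rest jittered); the best result is returned.
#' @return A list of class `group_fit_config`.
#' @export
group_fit_config <- function(structures, n_runs = 1000, base_seed = 1,
                             sd_weight = 0.001, n_trials = 320,
                             block_size = 80, reltol = 1e-4, maxit = 2000,
                             restarts = 1) {
  stopifnot(all(c("RB", "II") %in% names(structures)),
            n_runs >= 2, sd_weight >= 0, restarts >= 1)
  .assert_seed(base_seed)
  structure(
    list(structures = structures, n_runs = n_runs, base_seed = base_seed,
         sd_weight = sd_weight, n_trials = n_trials,
         block_size = block_size, reltol = reltol, maxit = maxit,
         restarts = restarts),
    class = "group_fit_config"
  )
}

.align_summaries <- function(sim, human) {
  key <- paste(human$condition, human$block)
  idx <- match(key, paste(sim$condition, sim$block))
  if (anyNA(idx)) stop("group summaries do not cover the same condition/block cells")
  sim[idx, , drop = FALSE]
}

#' Weighted sum-of-squares objective for group fitting
#'
#' Simulates a group under `params` and returns the squared discrepancy
#' from `human_summary` over the 8 mean-accuracy points plus
#' `sd_weight` times the squared discrepancy over the 8 SD points.
#' Bit-reproducible given `(params, cfg$base_seed, cfg$n_runs)`.
#'
#' @param params A [model_params()].
#' @param human_summary A `group_summary` (from [run_group()] or
#'   [read_summary()]).
#' @param cfg A [group_fit_config()].
#' @param sequences Optional pre-generated sequences
#'   ([pregenerate_sequences()]) to avoid regenerating them per call.
#' @return The scalar weighted sum of squares.
#' @export
group_objective <- function(params, human_summary, cfg, sequences = NULL) {
  stopifnot(inherits(cfg, "group_fit_config"),
            all(c("condition", "block", "mean_acc", "sd_acc") %in%
                  names(human_summary)))
  sim <- run_group(params, cfg$structures, cfg$n_runs, cfg$base_seed,
                   cfg$n_trials, cfg$block_size, sequences = sequences)
  sim <- .align_summaries(sim, human_summary)
  sum((sim$mean_acc - human_summary$mean_acc)^2) +
    cfg$sd_weight * sum((sim$sd_acc - human_summary$sd_acc)^2)
}

# soft box penalty keeping the simplex out of numerically degenerate
# territory (runaway learning rates / shaping scales); returns 0 inside
# the box and grows quadratically outside so the simplex is steered back
.box_penalty <- function(p) {
  excess <- c(max(log(p$rb_lr / 100), 0), max(log(p$ii_lr / 100), 0),
              max(log(p$ps_init / 1e9), 0), max(log(p$dm_noise / 1e6), 0))
  1e3 * sum(excess^2)
}

# parameter transforms: positive rates and scales on log, ps_lr on logit
.encode_params <- function(p) {
  dm <- max(p$dm_noise, 1e-8)
  if (p$single_lr_mode) {
    c(log(p$rb_lr), qlogis(p$ps_lr), log(p$ps_init), log(dm))
  } else {
    c(log(p$rb_lr), log(p$ii_lr), qlogis(p$ps_lr), log(p$ps_init), log(dm))
  }
}

# logit-decoded ps_lr is kept strictly below 1 at double precision
.decode_pslr <- function(t) min(plogis(t), 1 - 1e-9)

.decode_params <- function(theta, template) {
  if (template$single_lr_mode) {
    model_params(rb_lr = exp(theta[1]), ii_lr = exp(theta[1]),
                 ps_lr = .decode_pslr(theta[2]), ps_init = exp(theta[3]),
                 dm_noise = exp(theta[4]),
                 feedback_model = template$feedback_model,
                 single_lr_mode = TRUE)
  } else {
    model_params(rb_lr = exp(theta[1]), ii_lr = exp(theta[2]),
                 ps_lr = .decode_pslr(theta[3]), ps_init = exp(theta[4]),
                 dm_noise = exp(theta[5]),
                 feedback_model = template$feedback_model,
                 single_lr_mode = FALSE)
  }
}

.simplex <- function(fn, theta0, cfg, jitter_seed_lane) {
  best <- NULL
  n_eval <- 0L
  for (r in seq_len(cfg$restarts)) {
    start <- theta0
    if (r > 1L) {
      set.seed(.run_seed(cfg$base_seed, jitter_seed_lane, r))
      start <- theta0 + rnorm(length(theta0), 0, 0.3)
    }
    f0 <- fn(start)
    if (!is.finite(f0)) stop("objective is not finite at the starting point")
    res <- optim(start, fn, method = "Nelder-Mead",
                 control = list(reltol = cfg$reltol, maxit = cfg$maxit))
    n_eval <- n_eval + res$counts[["function"]]
    if (is.null(best) || res$value < best$value) best <- res
  }
  best$n_eval <- n_eval
  best
}

#' Fit the model to a group summary by downhill simplex
#'
#' Minimizes [group_objective()] over the free parameters (5 in full mode,
#' 4 when `init_params$single_lr_mode` constrains the two boundary
#' learning rates to be equal) with Nelder-Mead on transformed scales
#' (log for rates, the starting shaping value and the decision noise;
#' logit for the shaping learning rate, which must stay below 1).
#' Deterministic given the configuration seeds.
#'
#' @param human_summary The observed `group_summary` to fit.
#' @param init_params Starting [model_params()]; also fixes the feedback
#'   policy and full/single-lr mode of the fitted model.
#' @param cfg A [group_fit_config()].
#' @return A list of class `fit_result`: `best_params`, `objective_value`
#'   (the weighted sum of squares), `n_evaluations`, `converged`.
#' @export
fit_group <- function(human_summary, init_params = model_params(), cfg) {
  stopifnot(inherits(init_params, "model_params"),
            inherits(cfg, "group_fit_config"))
  sequences <- pregenerate_sequences(cfg$structures, cfg$n_runs,
                                     cfg$base_seed, cfg$n_trials,
                                     cfg$block_size)
  fn <- function(theta) {
    p <- .decode_params(theta, init_params)
    pen <- .box_penalty(p)
    if (pen > 0) return(1e6 + pen)
    group_objective(p, human_summary, cfg, sequences = sequences)
  }
  res <- .simplex(fn, .encode_params(init_params), cfg, jitter_seed_lane = 7)
  structure(
    list(best_params = .decode_params(res$par, init_params),
         objective_value = res$value,
         n_evaluations = res$n_eval,
         converged = res$convergence == 0),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> objective = %.6g after %d evaluations (%s)\n",
              x$objective_value, x$n_evaluations,
              if (x$converged) "converged" else "evaluation budget reached"))
  print(x$best_params)
  invisible(x)
}

#' Per-trial likelihood of an observed choice under the max-match rule
#'
#' The system whose prediction most closely matches the observed choice is
#' imputed as responsible for it, and the trial's likelihood is that
#' system's probability of the chosen category (the closer to 1, the
#' better the model accounts for the trial), floored at `floor`. Ties
#' resolve to the RB system.
#'
#' @param p_a_rb,p_a_ii Each system's p(A) on the trial (vectorized).
#' @param chosen The observed choice, `"A"` or `"B"`.
#' @param floor Lower bound on the returned likelihood.
#' @return A list with `likelihood` and `responsible` (`"RB"`/`"II"`).
#' @export
#' @examples
#' trial_likelihood(0.8, 0.3, "A")  # 0.8, RB
#' trial_likelihood(0.8, 0.3, "B")  # 0.7, II
trial_likelihood <- function(p_a_rb, p_a_ii, chosen, floor = 1e-6) {
  stopifnot(all(chosen %in% .CATEGORIES))
  lik_rb <- ifelse(chosen == "A", p_a_rb, 1 - p_a_rb)
  lik_ii <- ifelse(chosen == "A", p_a_ii, 1 - p_a_ii)
  list(likelihood = pmax(pmax(lik_rb, lik_ii), floor),
       responsible = ifelse(lik_rb >= lik_ii, "RB", "II"))
}

#' Replay an observed trial table under fixed parameters
#'
#' Deterministically replays a participant's stimuli in their original
#' order: on each trial both systems predict, the better-matching system
#' is imputed responsible for the observed choice ([trial_likelihood()]),
#' and feedback for the observed outcome routes by `policy` with each
#' routed system updating against its own prediction versus the true
#' category. Trials with a missing response contribute no likelihood and
#' trigger no update.
#'
#' @param behavior A behavior table with columns `trial`, `block`, `x`,
#'   `y`, `true_category`, `response` (and optionally `correct`).
#' @param params A [model_params()] (its `dm_noise` plays no role in the
#'   replay: no winner is sampled).
#' @param policy Feedback policy used during replay; defaults to the
#'   policy in `params`.
#' @param lik_floor Floor for per-trial likelihoods.
#' @return A data.frame: the behavior columns plus `p_a_rb`, `p_a_ii`,
#'   `likelihood`, `responsible` (imputed winner), with the final system
#'   states in attribute `"final_states"`.
#' @export
replay_subject <- function(behavior, params,
                           policy = params$feedback_model,
                           lik_floor = 1e-6) {
  stopifnot(inherits(params, "model_params"),
            all(c("x", "y", "true_category", "response") %in%
                  names(behavior)))
  resp_int <- match(behavior$response, .CATEGORIES)
  resp_int[is.na(resp_int)] <- 0L
  raw <- cpp_replay(behavior$x, behavior$y,
                    match(behavior$true_category, .CATEGORIES),
                    resp_int,
                    params$rb_lr, params$ii_lr, params$ps_lr,
                    params$ps_init, params$ps_init, policy, lik_floor)
  out <- behavior
  out$p_a_rb <- raw$p_a_rb
  out$p_a_ii <- raw$p_a_ii
  out$likelihood <- raw$likelihood
  out$responsible <- ifelse(is.na(raw$responsible), NA_character_,
                            c("RB", "II")[raw$responsible])
  attr(out, "final_states") <- list(
    rb = system_state("RB", raw$final_rb_boundary, raw$final_rb_ps),
    ii = system_state("II", raw$final_ii_boundary, raw$final_ii_ps)
  )
  out
}

#' Configuration for individual maximum-likelihood fitting
#'
#' @param reltol,maxit Simplex settings.
#' @param restarts Simplex starts (first unjittered, the rest jittered).
#' @param base_seed Seed for restart jitter.
#' @param feedback_model Feedback policy used during replay (default 2,
#'   the policy in which both systems learn on every trial).
#' @param lik_floor Floor for per-trial likelihoods.
#' @return A list of class `individual_fit_config`.
#' @export
individual_fit_config <- function(reltol = 1e-4, maxit = 2000, restarts = 1,
                                  base_seed = 1, feedback_model = 2,
                                  lik_floor = 1e-6) {
  stopifnot(restarts >= 1, feedback_model %in% 1:12)
  .assert_seed(base_seed)
  structure(
    list(reltol = reltol, maxit = maxit, restarts = restarts,
         base_seed = base_seed, feedback_model = feedback_model,
         lik_floor = lik_floor),
    class = "individual_fit_config"
  )
}

#' Fit the model to one participant's trial table by maximum likelihood
#'
#' The likelihood of the data is the product over trials of
#' [trial_likelihood()] under the deterministic replay
#' ([replay_subject()]); the negative log-likelihood is minimized by
#' downhill simplex over the boundary learning rates, the shaping learning
#' rate and the starting shaping value. The decision-noise parameter does
#' not enter the replay likelihood (the responsible system is imputed, not
#' sampled) and is carried through unchanged from `init_params`.
#'
#' When `behavior` is a list of trial tables (several sessions of the
#' same participant, e.g. one RB-condition and one II-condition session),
#' each session is replayed independently from fresh starting boundaries
#' and the negative log-likelihoods are summed, so one parameter set must
#' account for all sessions jointly. Both boundary learning rates are
#' well identified only in such joint fits: a single session mainly
#' constrains the learning rate of the system that dominates it.
#'
#' @param behavior A behavior table (see [replay_subject()]), or a list
#'   of behavior tables fitted jointly.
#' @param init_params Starting [model_params()].
#' @param cfg An [individual_fit_config()].
#' @return A `fit_result` with `best_params`, `objective_value` (negative
#'   log-likelihood), `n_evaluations`, `converged`, and `trial_fits` (the
#'   replay trace at the optimum, including per-trial likelihoods; a list
#'   of traces when `behavior` is a list).
#' @export
fit_individual <- function(behavior, init_params = model_params(),
                           cfg = individual_fit_config()) {
  stopifnot(inherits(init_params, "model_params"),
            inherits(cfg, "individual_fit_config"))
  single <- is.data.frame(behavior)
  sessions <- if (single) list(behavior) else behavior
  stopifnot(length(sessions) >= 1, all(vapply(sessions, is.data.frame,
                                              logical(1))))
  prepped <- lapply(sessions, function(b) {
    resp_int <- match(b$response, .CATEGORIES)
    resp_int[is.na(resp_int)] <- 0L
    list(x = b$x, y = b$y, true_int = match(b$true_category, .CATEGORIES),
         resp_int = resp_int)
  })

  nll <- function(theta) {
    rb_lr <- exp(theta[1]); ii_lr <- exp(theta[2])
    ps_lr <- .decode_pslr(theta[3]); ps_init <- exp(theta[4])
    pen <- max(log(rb_lr / 100), 0)^2 + max(log(ii_lr / 100), 0)^2 +
      max(log(ps_init / 1e9), 0)^2
    if (pen > 0) return(1e6 + 1e3 * pen)
    total <- 0
    for (s in prepped) {
      raw <- cpp_replay(s$x, s$y, s$true_int, s$resp_int,
                        rb_lr, ii_lr, ps_lr, ps_init, ps_init,
                        cfg$feedback_model, cfg$lik_floor)
      total <- total - sum(log(raw$likelihood), na.rm = TRUE)
    }
    total
  }
  theta0 <- c(log(init_params$rb_lr), log(init_params$ii_lr),
              qlogis(init_params$ps_lr), log(init_params$ps_init))
  scfg <- list(base_seed = cfg$base_seed, restarts = cfg$restarts,
               reltol = cfg$reltol, maxit = cfg$maxit)
  res <- .simplex(nll, theta0, scfg, jitter_seed_lane = 8)
  best <- model_params(rb_lr = exp(res$par[1]), ii_lr = exp(res$par[2]),
                       ps_lr = .decode_pslr(res$par[3]),
                       ps_init = exp(res$par[4]),
                       dm_noise = init_params$dm_noise,
                       feedback_model = cfg$feedback_model)
  replays <- lapply(sessions, replay_subject, params = best,
                    policy = cfg$feedback_model, lik_floor = cfg$lik_floor)
  trial_fits <- if (single) replays[[1]] else replays
  structure(
    list(best_params = best, objective_value = res$value,
         n_evaluations = res$n_eval, converged = res$convergence == 0,
         trial_fits = trial_fits),
    class = "fit_result"
  )
}

#' Tournament over the twelve feedback-routing policies
#'
#' Fits the model to `human_summary` once per policy (same simplex
#' configuration and seeds for all twelve) and returns the leaderboard
#' sorted by fit value, best first.
#'
#' @param human_summary The observed `group_summary`.
#' @param cfg A [group_fit_config()].
#' @param init_params Starting parameters (the `feedback_model` field is
#'   overridden per candidate policy).
#' @return A data.frame with one row per policy, columns `feedback`,
#'   `fit_value`, `rb_lr`, `ii_lr`, `ps_lr`, `ps`, `dm_noise`, sorted by
#'   ascending `fit_value`.
#' @export
compare_feedback_models <- function(human_summary, cfg,
                                    init_params = model_params()) {
  rows <- lapply(1:12, function(k) {
    init_k <- model_params(init_params$rb_lr, init_params$ii_lr,
                           init_params$ps_lr, init_params$ps_init,
                           init_params$dm_noise, feedback_model = k,
                           single_lr_mode = init_params$single_lr_mode)
    fit <- fit_group(human_summary, init_k, cfg)
    p <- fit$best_params
    data.frame(feedback = k, fit_value = fit$objective_value,
               rb_lr = p$rb_lr, ii_lr = p$ii_lr, ps_lr = p$ps_lr,
               ps = p$ps_init, dm_noise = p$dm_noise)
  })
  board <- do.call(rbind, rows)
  board <- board[order(board$fit_value), ]
  rownames(board) <- NULL
  board
}
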