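#' Full parameter set for the dual-system model
#'
#' The five free parameters plus the feedback-routing policy. Defaults are
#' the package's reference operating point: the full parameter set
#' recovered by group fitting of the model's original behavioral
#' calibration under the winning feedback policy (policy 2). The large
#' default `ps_init` encodes the near-total lack of starting confidence
#' that produces gradual, human-like learning curves; learning dynamics
#' depend on it only logarithmically, so it need not be rescaled to the
#' stimulus-space extent.
#'
#' @param rb_lr,ii_lr Boundary learning rates for the RB and II systems
#'   (>= 0).
#' @param ps_lr Shaping-parameter learning rate in `[0, 1)`.
#' @param ps_init Starting perceptual-shaping value shared by both systems
#'   (> 0); a high value encodes initial lack of confidence.
#' @param dm_noise Standard deviation of the decision-selection noise
#'   (>= 0).
#' @param feedback_model Feedback-routing policy id, 1 to 12 (see
#'   [feedback_policies()]); default 2 (both systems learn on every trial).
#' @param single_lr_mode Logical; if `TRUE` the two boundary learning rates
#'   are constrained equal (`rb_lr` is used for both), giving the
#'   4-parameter variant of the model.
#' @return An object of class `model_params`.
#' @export
model_params <- function(rb_lr = 0.1703, ii_lr = 0.0288, ps_lr = 0.5382,
                         ps_init = 145932, dm_noise = 1.2043,
                         feedback_model = 2, single_lr_mode = FALSE) {
  if (isTRUE(single_lr_mode)) ii_lr <- rb_lr
  lr <- learning_rates(rb_lr, ii_lr, ps_lr) # validates rates
  if (!is.finite(ps_init) || ps_init <= 0) stop("ps_init must be > 0")
  if (!is.finite(dm_noise) || dm_noise < 0) stop("dm_noise must be >= 0")
  if (!feedback_model %in% 1:12) stop("feedback_model must be in 1..12")
  structure(
    list(rb_lr = lr$rb_lr, ii_lr = lr$ii_lr, ps_lr = lr$ps_lr,
         ps_init = ps_init, dm_noise = dm_noise,
         feedback_model = as.integer(feedback_model),
         single_lr_mode = isTRUE(single_lr_mode)),
    class = "model_params"
  )
}

#' @export
print.model_params <- function(x, ...) {
  cat(sprintf(paste0("<model_params> rb_lr = %g, ii_lr = %g, ps_lr = %g, ",
                     "ps_init = %g, dm_noise = %g, feedback_model = %d%s\n"),
              x$rb_lr, x$ii_lr, x$ps_lr, x$ps_init, x$dm_noise,
              x$feedback_model,
              if (x$single_lr_mode) " (single-lr mode)" else ""))
  invisible(x)
}

#' Initialize both boundaries from the first two stimuli
#'
#' Like a naive participant, the model starts with no knowledge of the
#' category structure: the RB boundary is the mean frequency of the first
#' two stimuli encountered, and the II intercept is the mean of their
#' `y - x` offsets, so both starting bounds pass through the "average" of
#' the first evidence seen.
#'
#' @param x,y Length-2 coordinate vectors of the first two stimuli.
#' @return A list with `rb_boundary` and `ii_boundary`.
#' @export
init_boundaries <- function(x, y) {
  stopifnot(length(x) == 2L, length(y) == 2L,
            all(is.finite(x)), all(is.finite(y)))
  list(rb_boundary = mean(x), ii_boundary = mean(y - x))
}

# own predicted category under the fixed tie rule (p(A) == 0.5 -> "B")
.predicted_category <- function(p_a) ifelse(p_a > 0.5, "A", "B")

#' Run a single trial of the closed loop
#'
#' Both systems evaluate the stimulus; confidences are converted to odds;
#' the noisy competition picks a winner; a response is emitted by
#' probability matching from the winner's p(A); the feedback policy routes
#' the outcome; each routed system updates against its own prediction.
#' Consumes RNG draws in the fixed order (selection noise, tie-break if
#' needed, response draw).
#'
#' @param states A list with elements `rb` and `ii`, each a
#'   [system_state()].
#' @param x,y Stimulus coordinates (scalars).
#' @param true_cat The stimulus's true category, `"A"` or `"B"`.
#' @param params A [model_params()].
#' @return A list with `state` (one-row data.frame of the trial record) and
#'   `states` (the updated system states).
#' @export
run_trial <- function(states, x, y, true_cat, params) {
  stopifnot(inherits(params, "model_params"), true_cat %in% .CATEGORIES)
  p_rb <- category_probability(states$rb, x, y)
  p_ii <- category_probability(states$ii, x, y)
  conf_rb <- max(p_rb, 1 - p_rb)
  conf_ii <- max(p_ii, 1 - p_ii)
  odds_rb <- odds(conf_rb)
  odds_ii <- odds(conf_ii)

  sel <- select_system(odds_rb, odds_ii, params$dm_noise)
  p_sel <- if (sel$winner == "RB") p_rb else p_ii
  response <- emit_response(p_sel)
  correct <- response == true_cat

  routed <- route_feedback(params$feedback_model, sel$winner, correct)
  lr <- learning_rates(params$rb_lr, params$ii_lr, params$ps_lr)
  if ("RB" %in% routed) {
    states$rb <- apply_feedback(states$rb, x, y,
                                .predicted_category(p_rb), true_cat, lr)
  }
  if ("II" %in% routed) {
    states$ii <- apply_feedback(states$ii, x, y,
                                .predicted_category(p_ii), true_cat, lr)
  }

  rec <- data.frame(
    p_a_rb = p_rb, p_a_ii = p_ii,
    conf_rb = conf_rb, conf_ii = conf_ii,
    odds_rb = odds_rb, odds_ii = odds_ii,
    epsilon = sel$epsilon, winner = sel$winner,
    response = response, correct = correct,
    fb_rb = "RB" %in% routed, fb_ii = "II" %in% routed,
    stringsAsFactors = FALSE
  )
  list(state = rec, states = states)
}

#' Simulate one full session
#'
#' Initializes both boundaries from the first two stimuli of the sequence
#' and both shaping values from `ps_init` (optionally biased per system),
#' then iterates [run_trial()] over the sequence. Deterministic given
#' `seed`. The default engine is the compiled loop; `engine = "r"` runs the
#' pure-R reference implementation, which consumes the identical RNG stream
#' and produces byte-identical traces.
#'
#' @param params A [model_params()].
#' @param sequence A trial sequence from [generate_sequence()] (or any
#'   data.frame with columns `trial`, `block`, `x`, `y`, `true_category`).
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @param ps_init_rb,ps_init_ii Per-system starting shaping values;
#'   default `params$ps_init` for both. Setting `ps_init_rb` below
#'   `ps_init_ii` gives the RB system an initial confidence advantage
#'   (an "RB-favoring" start).
#' @param engine `"cpp"` (compiled, default) or `"r"` (reference).
#' @return An object of class `session_result`: a list with `trace`
#'   (per-trial data.frame), `block_accuracy`, `rb_win_fraction` (per-block
#'   fraction of RB-winner trials), `final_states`, `params`, `seed`.
#' @export
#' @examples
#' s <- make_structure("RB", 150, sd = 20)
#' sq <- generate_sequence(s, 320, 80, seed = 1)
#' res <- run_session(model_params(), sq, seed = 2)
#' res$block_accuracy
run_session <- function(params, sequence, seed = NULL,
                        ps_init_rb = params$ps_init,
                        ps_init_ii = params$ps_init,
                        engine = c("cpp", "r")) {
  stopifnot(inherits(params, "model_params"), is.data.frame(sequence),
            all(c("x", "y", "true_category", "block") %in% names(sequence)))
  engine <- match.arg(engine)
  .assert_seed(seed)
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(sequence)
  block_size <- sum(sequence$block == sequence$block[1])
  true_int <- match(sequence$true_category, .CATEGORIES)

  if (engine == "cpp") {
    raw <- cpp_run_session(sequence$x, sequence$y, true_int, block_size,
                           params$rb_lr, params$ii_lr, params$ps_lr,
                           ps_init_rb, ps_init_ii, params$dm_noise,
                           params$feedback_model, TRUE)
    trace <- data.frame(
      trial = sequence$trial, block = sequence$block,
      x = sequence$x, y = sequence$y,
      true_category = sequence$true_category,
      p_a_rb = raw$p_a_rb, p_a_ii = raw$p_a_ii,
      conf_rb = pmax(raw$p_a_rb, 1 - raw$p_a_rb),
      conf_ii = pmax(raw$p_a_ii, 1 - raw$p_a_ii),
      odds_rb = raw$odds_rb, odds_ii = raw$odds_ii,
      epsilon = raw$epsilon,
      winner = c("RB", "II")[raw$winner],
      response = .CATEGORIES[raw$response],
      correct = raw$correct,
      fb_rb = raw$fb_rb, fb_ii = raw$fb_ii,
      stringsAsFactors = FALSE
    )
    final_states <- list(
      rb = system_state("RB", raw$final_rb_boundary, raw$final_rb_ps),
      ii = system_state("II", raw$final_ii_boundary, raw$final_ii_ps)
    )
    block_acc <- raw$block_accuracy
    rb_win <- raw$rb_win_fraction
  } else {
    b0 <- init_boundaries(sequence$x[1:2], sequence$y[1:2])
    states <- list(rb = system_state("RB", b0$rb_boundary, ps_init_rb),
                   ii = system_state("II", b0$ii_boundary, ps_init_ii))
    recs <- vector("list", n)
    for (i in seq_len(n)) {
      step <- run_trial(states, sequence$x[i], sequence$y[i],
                        sequence$true_category[i], params)
      recs[[i]] <- step$state
      states <- step$states
    }
    trace <- cbind(
      sequence[, c("trial", "block", "x", "y", "true_category")],
      do.call(rbind, recs)
    )
    rownames(trace) <- NULL
    block_acc <- as.numeric(tapply(trace$correct, trace$block, mean))
    rb_win <- as.numeric(tapply(trace$winner == "RB", trace$block, mean))
    final_states <- states
  }
  if ("onset_s" %in% names(sequence)) trace$onset_s <- sequence$onset_s

  structure(
    list(trace = trace, block_accuracy = block_acc,
         rb_win_fraction = rb_win, final_states = final_states,
         params = params, seed = seed),
    class = "session_result"
  )
}

#' @export
print.session_result <- function(x, ...) {
  cat(sprintf("<session_result> %d trials, block accuracy: %s\n",
              nrow(x$trace),
              paste(sprintf("%.3f", x$block_accuracy), collapse = " ")))
  invisible(x)
}

# seeds for the runs of one group simulation; lane separates purposes
# (sequence generation vs session randomness) and conditions
.run_seed <- function(base_seed, lane, run) {
  s <- base_seed + lane * 1000003 + run
  if (s >= 2^31) stop("base_seed too large for the derived seed scheme")
  s
}

#' Simulate a group of sessions in both conditions
#'
#' Runs `n_runs` independent seeded sessions per condition (fresh stimulus
#' sequence and fresh session randomness per run) and summarizes accuracy
#' per block: the 8 mean points and 8 SD points (4 blocks x 2 conditions)
#' that group fitting targets.
#'
#' @param params A [model_params()].
#' @param structures Named list with elements `RB` and `II`, each a
#'   [make_structure()] object.
#' @param n_runs Sessions per condition (>= 2 so SDs are defined).
#' @param base_seed Integer; all per-run seeds derive from it, so the
#'   summary is fully reproducible.
#' @param n_trials,block_size Session design (default 320 trials in 4
#'   blocks of 80).
#' @param sequences Optional pre-generated sequences, a named list
#'   (`RB`, `II`) of lists of sequence data.frames, as produced by
#'   [pregenerate_sequences()]; used by the fitting routines to hold the
#'   stimulus stream fixed across objective evaluations.
#' @return A `group_summary`: data.frame with columns `condition`, `block`,
#'   `mean_acc`, `sd_acc` and attribute `n_runs`.
#' @export
run_group <- function(params, structures, n_runs = 1000, base_seed = 1,
                      n_trials = 320, block_size = 80, sequences = NULL) {
  stopifnot(inherits(params, "model_params"),
            all(c("RB", "II") %in% names(structures)), n_runs >= 2)
  .assert_seed(base_seed)
  if (is.null(sequences)) {
    sequences <- pregenerate_sequences(structures, n_runs, base_seed,
                                       n_trials, block_size)
  }
  out <- vector("list", 2)
  for (k in 1:2) {
    cond <- c("RB", "II")[k]
    n_blocks <- n_trials %/% block_size
    acc <- matrix(NA_real_, n_runs, n_blocks)
    for (r in seq_len(n_runs)) {
      sq <- sequences[[cond]][[r]]
      set.seed(.run_seed(base_seed, 2 + k, r))
      raw <- cpp_run_session(sq$x, sq$y, match(sq$true_category, .CATEGORIES),
                             block_size, params$rb_lr, params$ii_lr,
                             params$ps_lr, params$ps_init, params$ps_init,
                             params$dm_noise, params$feedback_model, FALSE)
      acc[r, ] <- raw$block_accuracy
    }
    out[[k]] <- data.frame(
      condition = cond, block = seq_len(n_blocks),
      mean_acc = colMeans(acc), sd_acc = apply(acc, 2, sd),
      stringsAsFactors = FALSE
    )
  }
  summary <- do.call(rbind, out)
  rownames(summary) <- NULL
  attr(summary, "n_runs") <- n_runs
  class(summary) <- c("group_summary", "data.frame")
  summary
}

#' Pre-generate the stimulus sequences for a group simulation
#'
#' Sequence randomness is separated from session randomness so that fitting
#' can reuse one fixed set of sequences across objective evaluations
#' (common random numbers).
#'
#' @inheritParams run_group
#' @return Named list (`RB`, `II`) of lists of sequence data.frames.
#' @export
pregenerate_sequences <- function(structures, n_runs, base_seed = 1,
                                  n_trials = 320, block_size = 80) {
  stopifnot(all(c("RB", "II") %in% names(structures)))
  .assert_seed(base_seed)
  lapply(structure(c("RB", "II"), names = c("RB", "II")), function(cond) {
    lane <- if (cond == "RB") 0 else 1
    lapply(seq_len(n_runs), function(r) {
      generate_sequence(structures[[cond]], n_trials, block_size,
                        seed = .run_seed(base_seed, lane, r))
    })
  })
}
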