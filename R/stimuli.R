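#' Trial timing configuration
#'
#' Event durations for one categorization trial: a fixation cross, the
#' stimulus (response window), a visual mask, and the feedback display.
#' Fixation-only null periods of `null_unit_s` seconds may be interspersed
#' between trials (up to `max_null_units` per trial) for event separability.
#'
#' @param fixation_ms Fixation-cross duration, milliseconds.
#' @param stimulus_ms Stimulus / response-window duration, milliseconds.
#' @param mask_ms Visual-mask duration, milliseconds.
#' @param feedback_ms Feedback display duration, milliseconds.
#' @param null_unit_s Duration of one interspersed null period, seconds.
#' @param max_null_units Maximum number of null units after any one trial.
#' @return An object of class `timing_config`.
#' @export
timing_config <- function(fixation_ms = 750, stimulus_ms = 2000,
                          mask_ms = 500, feedback_ms = 750,
                          null_unit_s = 4, max_null_units = 5) {
  durs <- c(fixation_ms, stimulus_ms, mask_ms, feedback_ms, null_unit_s)
  if (any(!is.finite(durs)) || any(durs <= 0)) {
    stop("all timing durations must be positive and finite")
  }
  if (max_null_units < 0) stop("max_null_units must be >= 0")
  structure(
    list(fixation_ms = fixation_ms, stimulus_ms = stimulus_ms,
         mask_ms = mask_ms, feedback_ms = feedback_ms,
         null_unit_s = null_unit_s, max_null_units = max_null_units),
    class = "timing_config"
  )
}

#' Define a two-category structure in the 2-D stimulus space
#'
#' Stimuli live in a 2-D perceptual space (x = spatial frequency,
#' y = orientation, arbitrary units). A rule-based (`"RB"`) structure splits
#' the space by a vertical line at `bound` (frequency alone determines
#' category); an information-integration (`"II"`) structure splits it by a
#' slope-1 diagonal with intercept `bound` (y = x + bound), so both
#' dimensions must be integrated. Category A occupies the negative side of
#' the signed boundary value (low frequency for RB; below the diagonal for
#' II). Category means sit symmetrically on either side of the bound at
#' perpendicular offset `mean_offset`; stimuli are drawn from truncated
#' independent Gaussians (`sd` per dimension) around those means, with any
#' draw that crosses the bound or leaves `extent` rejected, so the stored
#' labels are noiseless.
#'
#' Categories are elongated along the bound (standard deviation
#' `elongation * sd` in the bound-parallel direction versus `sd`
#' perpendicular), the classic design property that makes the diagonal
#' structure genuinely require integration: no single-dimension rule can
#' classify it well, while the elongation leaves the perpendicular
#' separation untouched.
#'
#' @param condition `"RB"` or `"II"`.
#' @param bound Vertical-bound frequency (RB) or diagonal intercept (II).
#' @param sd Within-category standard deviation perpendicular to the bound
#'   (> 0). Larger values emulate stimulus sets sampled over a wider range
#'   of the space.
#' @param extent Numeric length-2, the `[min, max]` extent of each dimension.
#' @param mean_offset Perpendicular distance from the bound to each category
#'   mean; defaults to one sixth of the extent width.
#' @param elongation Ratio of the bound-parallel to the perpendicular
#'   standard deviation (>= 1).
#' @return An object of class `category_structure` with elements
#'   `condition`, `bound`, `sd`, `elongation`, `extent`, `means` (2 x 2
#'   matrix, rows `"A"`/`"B"`, columns `x`/`y`).
#' @export
#' @examples
#' make_structure("RB", bound = 150, sd = 20)
make_structure <- function(condition = c("RB", "II"), bound = NULL, sd = 20,
                           extent = c(0, 300), mean_offset = NULL,
                           elongation = 4) {
  condition <- match.arg(condition)
  stopifnot(length(extent) == 2L, is.finite(extent), extent[2] > extent[1])
  width <- extent[2] - extent[1]
  mid <- mean(extent)
  if (is.null(bound)) bound <- if (condition == "RB") mid else 0
  if (!is.finite(sd) || sd <= 0) stop("sd must be > 0")
  if (!is.finite(elongation) || elongation < 1) stop("elongation must be >= 1")
  if (is.null(mean_offset)) mean_offset <- width / 6
  if (mean_offset <= 0) stop("mean_offset must be > 0")

  if (condition == "RB") {
    if (bound <= extent[1] || bound >= extent[2]) {
      stop("RB bound must lie strictly inside the extent")
    }
    means <- rbind(A = c(bound - mean_offset, mid),
                   B = c(bound + mean_offset, mid))
  } else {
    # intercept of y = x + bound must cross the square extent
    if (bound <= extent[1] - extent[2] || bound >= extent[2] - extent[1]) {
      stop("II intercept must lie strictly inside the reachable range")
    }
    # centre of the bound segment inside the square, offset perpendicular
    # to the slope-1 line (unit normal (1, -1)/sqrt(2) points to the A side)
    cx <- mid - bound / 2
    cy <- mid + bound / 2
    u <- mean_offset / sqrt(2)
    means <- rbind(A = c(cx + u, cy - u), B = c(cx - u, cy + u))
  }
  colnames(means) <- c("x", "y")
  structure(
    list(condition = condition, bound = bound, sd = sd,
         elongation = elongation, mean_offset = mean_offset,
         extent = as.numeric(extent), means = means),
    class = "category_structure"
  )
}

#' @export
print.category_structure <- function(x, ...) {
  cat(sprintf("<category_structure> %s condition, bound = %g, sd = %g, extent = [%g, %g]\n",
              x$condition, x$bound, x$sd, x$extent[1], x$extent[2]))
  invisible(x)
}

# signed boundary value; negative = A side, positive = B side
.structure_signed <- function(structure, x, y) {
  if (structure$condition == "RB") x - structure$bound
  else y - x - structure$bound
}

#' True category of stimuli under a structure
#'
#' Labels by signed side of the true bound: category A on the negative side
#' (RB: frequency below the bound; II: below the diagonal). A stimulus
#' exactly on the bound resolves to `"B"` (fixed tie rule; the generator
#' never emits such stimuli).
#'
#' @param structure A [make_structure()] object.
#' @param x,y Stimulus coordinates (vectorized).
#' @return Character vector of `"A"`/`"B"`.
#' @export
true_label <- function(structure, x, y) {
  stopifnot(inherits(structure, "category_structure"),
            length(x) == length(y), all(is.finite(x)), all(is.finite(y)))
  ifelse(.structure_signed(structure, x, y) < 0, "A", "B")
}

#' Generate a trial sequence for one session
#'
#' Produces `n_trials` stimuli in blocks of `block_size`, with category
#' assignment balanced within each block (equal A and B counts, shuffled),
#' coordinates drawn from the structure's truncated per-category Gaussians,
#' and stimulus-onset times computed from `timing` with 0 to
#' `max_null_units` four-second null periods drawn uniformly after each
#' trial.
#'
#' @param structure A [make_structure()] object.
#' @param n_trials Total number of trials; must be divisible by
#'   `block_size`, and each block must be even for A/B balance.
#' @param block_size Trials per block.
#' @param timing A [timing_config()].
#' @param seed Integer seed; `NULL` continues the current RNG stream.
#' @return A data.frame with columns `trial`, `block`, `onset_s`, `x`, `y`,
#'   `true_category`, carrying the structure as attribute `"structure"`.
#' @export
#' @examples
#' s <- make_structure("RB", 150, sd = 20)
#' seq1 <- generate_sequence(s, n_trials = 320, block_size = 80, seed = 1)
#' table(seq1$block, seq1$true_category)
generate_sequence <- function(structure, n_trials = 320, block_size = 80,
                              timing = timing_config(), seed = NULL) {
  stopifnot(inherits(structure, "category_structure"),
            inherits(timing, "timing_config"))
  if (n_trials %% block_size != 0) {
    stop("n_trials must be divisible by block_size")
  }
  if (block_size %% 2 != 0) stop("block_size must be even for A/B balance")
  .assert_seed(seed)
  if (!is.null(seed)) set.seed(seed)

  n_blocks <- n_trials %/% block_size
  cats <- unlist(lapply(seq_len(n_blocks), function(b) {
    sample(rep(.CATEGORIES, block_size / 2))
  }))

  # sample in bound-aligned coordinates: perpendicular offset v around the
  # category mean (sd), position u along the bound (sd * elongation)
  sd_perp <- structure$sd
  sd_along <- structure$sd * structure$elongation
  mid <- mean(structure$extent)
  x <- numeric(n_trials)
  y <- numeric(n_trials)
  for (cat in .CATEGORIES) {
    idx <- which(cats == cat)
    v_mu <- if (cat == "A") -structure$mean_offset else structure$mean_offset
    n_left <- length(idx)
    xs <- numeric(0); ys <- numeric(0)
    while (n_left > 0L) {
      u <- rnorm(n_left, 0, sd_along)
      v <- rnorm(n_left, v_mu, sd_perp)
      if (structure$condition == "RB") {
        cx <- structure$bound + v
        cy <- mid + u
      } else {
        cx <- (mid - structure$bound / 2) + (u - v) / sqrt(2)
        cy <- (mid + structure$bound / 2) + (u + v) / sqrt(2)
      }
      ok <- cx > structure$extent[1] & cx < structure$extent[2] &
        cy > structure$extent[1] & cy < structure$extent[2] &
        true_label(structure, cx, cy) == cat &
        .structure_signed(structure, cx, cy) != 0
      xs <- c(xs, cx[ok]); ys <- c(ys, cy[ok])
      n_left <- n_left - sum(ok)
    }
    x[idx] <- xs
    y[idx] <- ys
  }

  # onsets: fixation precedes each stimulus; trial footprint is
  # fixation + stimulus + mask + feedback, plus 0..max_null null units
  per_trial_s <- (timing$fixation_ms + timing$stimulus_ms +
                    timing$mask_ms + timing$feedback_ms) / 1000
  n_null <- sample(0:timing$max_null_units, n_trials, replace = TRUE)
  gaps <- per_trial_s + n_null * timing$null_unit_s
  onset <- timing$fixation_ms / 1000 + c(0, cumsum(gaps[-n_trials]))

  out <- data.frame(
    trial = seq_len(n_trials),
    block = rep(seq_len(n_blocks), each = block_size),
    onset_s = onset,
    x = x, y = y,
    true_category = cats,
    stringsAsFactors = FALSE
  )
  attr(out, "structure") <- structure
  out
}
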