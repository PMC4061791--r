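#' Convert a system's confidence to betting odds
#'
#' Confidence is the larger of a system's two category probabilities,
#' `max(p, 1 - p)`, so it lies in `[0.5, 1)`. Odds are
#' `conf / (1 - conf)`, monotone increasing in confidence, with a minimum
#' of 1 at complete uncertainty. Saturated confidences are clamped to
#' `1 - 1e-12` before the ratio so odds stay finite.
#'
#' @param conf Confidence values in `[0.5, 1]` (vectorized).
#' @return Odds values `>= 1`.
#' @export
#' @examples
#' odds(c(0.5, 0.75, 0.8))  # 1, 3, 4
odds <- function(conf) {
  stopifnot(all(is.finite(conf)))
  if (any(conf < 0.5)) stop("conf must be >= 0.5 (the max of p and 1 - p)")
  conf <- pmin(conf, 1 - 1e-12)
  conf / (1 - conf)
}

#' Resolve the competition between the two systems
#'
#' A Gaussian noise term with standard deviation `dm_noise` is added to the
#' RB system's odds; the system with the larger noisy odds drives the
#' response. With `dm_noise = 0` this is a strict argmax; an exact tie is
#' broken uniformly at random. One normal draw is always consumed (even at
#' `dm_noise = 0`) so runs are reproducible irrespective of the noise
#' setting.
#'
#' @param odds_rb,odds_ii Odds for the two systems (each `>= 1`).
#' @param dm_noise Standard deviation of the selection noise, `>= 0`.
#' @return A list with `winner` (`"RB"` or `"II"`) and `epsilon` (the drawn
#'   noise value, for logging).
#' @export
select_system <- function(odds_rb, odds_ii, dm_noise) {
  stopifnot(is.finite(odds_rb), is.finite(odds_ii),
            odds_rb >= 1, odds_ii >= 1,
            is.finite(dm_noise), dm_noise >= 0)
  eps <- rnorm(1) * dm_noise
  noisy_rb <- odds_rb + eps
  winner <- if (noisy_rb > odds_ii) "RB"
  else if (noisy_rb < odds_ii) "II"
  else if (runif(1) < 0.5) "RB" else "II"
  list(winner = winner, epsilon = eps)
}

#' Emit a category response by probability matching
#'
#' The response is sampled from the selected system's predicted category
#' distribution: `"A"` with probability `p_a`, else `"B"`, rather than a
#' deterministic argmax. A predicted p(A) of 0.8 therefore yields category
#' A on about 80 percent of trials in the long run.
#'
#' @param p_a The selected system's probability of category A, in `[0, 1]`.
#' @return `"A"` or `"B"`.
#' @export
emit_response <- function(p_a) {
  stopifnot(is.finite(p_a), p_a >= 0, p_a <= 1)
  if (runif(1) < p_a) "A" else "B"
}
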