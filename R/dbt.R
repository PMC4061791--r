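#' One decision-bound learner's state
#'
#' Each system maintains a one-parameter category boundary and a
#' perceptual-shaping spread `ps`. The RB system's boundary is a vertical
#' line at frequency `boundary`; the II system's is a slope-1 diagonal with
#' intercept `boundary` (y = x + boundary). `ps` (same units as the
#' stimulus space) is the spread of the isotropic Gaussian whose mass on
#' either side of the boundary gives the category probabilities: large `ps`
#' pushes probabilities toward 0.5 (low confidence), small `ps` sharpens
#' them.
#'
#' @param system_id `"RB"` or `"II"`.
#' @param boundary Boundary parameter (finite scalar).
#' @param ps Perceptual-shaping spread, > 0.
#' @return An object of class `system_state`.
#' @export
system_state <- function(system_id = c("RB", "II"), boundary, ps) {
  system_id <- match.arg(system_id)
  if (!is.finite(boundary)) stop("boundary must be finite")
  if (!is.finite(ps) || ps <= 0) stop("ps must be > 0")
  structure(list(system_id = system_id, boundary = boundary, ps = ps),
            class = "system_state")
}

#' @export
print.system_state <- function(x, ...) {
  cat(sprintf("<system_state> %s: boundary = %g, ps = %g\n",
              x$system_id, x$boundary, x$ps))
  invisible(x)
}

#' Learning rates for the two boundaries and the shaping parameter
#'
#' @param rb_lr,ii_lr Boundary learning rates (>= 0) for the RB and II
#'   systems: the fraction of the stimulus-to-bound distance the boundary
#'   moves after an error.
#' @param ps_lr Shaping-parameter learning rate in `[0, 1)`: `ps` is
#'   multiplied by `1 - ps_lr` after a correct prediction and `1 + ps_lr`
#'   after an error, so `ps` stays positive.
#' @return An object of class `learning_rates`.
#' @export
learning_rates <- function(rb_lr, ii_lr, ps_lr) {
  v <- c(rb_lr, ii_lr, ps_lr)
  if (any(!is.finite(v)) || any(v < 0)) {
    stop("learning rates must be finite and non-negative")
  }
  if (ps_lr >= 1) stop("ps_lr must be < 1 so ps stays positive")
  structure(list(rb_lr = rb_lr, ii_lr = ii_lr, ps_lr = ps_lr),
            class = "learning_rates")
}

#' Signed distance from a stimulus to a system's boundary
#'
#' RB: `x - boundary`. II: perpendicular distance to the slope-1 line,
#' `(y - x - boundary) / sqrt(2)`. Positive values are the category-B side.
#'
#' @param state A [system_state()].
#' @param x,y Stimulus coordinates (vectorized).
#' @return Numeric signed distances.
#' @export
signed_distance <- function(state, x, y) {
  stopifnot(inherits(state, "system_state"), length(x) == length(y))
  if (state$system_id == "RB") x - state$boundary
  else (y - x - state$boundary) / sqrt(2)
}

#' Four-constant polynomial approximation of the standard normal CDF
#'
#' The model's probability machinery uses a classical four-constant
#' rational-polynomial approximation of the standard normal distribution
#' function (absolute error below 2.5e-4) rather than an exact CDF, with
#' the symmetry identity for negative arguments.
#'
#' @param z Numeric vector of quantiles.
#' @return Approximate `P(Z <= z)` in (0, 1).
#' @export
#' @examples
#' std_normal_cdf(0)    # 0.5
#' std_normal_cdf(1)    # ~0.8413
std_normal_cdf <- function(z) {
  stopifnot(all(is.finite(z)))
  a1 <- 0.196854; a2 <- 0.115194; a3 <- 0.000344; a4 <- 0.019527
  za <- abs(z)
  upper <- 1 - 0.5 / (1 + a1 * za + a2 * za^2 + a3 * za^3 + a4 * za^4)^4
  ifelse(z >= 0, upper, 1 - upper)
}

#' Probability that a stimulus belongs to category A
#'
#' The shaping parameter `ps` defines the spread of an isotropic Gaussian
#' centred on the stimulus; the probability of category A is the mass of
#' that Gaussian on the A side of the boundary, which reduces in closed
#' form to the (approximate) normal CDF of `-signed_distance / ps`. The
#' probability of B is the complement.
#'
#' @param state A [system_state()].
#' @param x,y Stimulus coordinates (vectorized).
#' @return `p(A)` in (0, 1).
#' @export
category_probability <- function(state, x, y) {
  stopifnot(inherits(state, "system_state"))
  if (state$ps <= 0) stop("invalid state: ps must be > 0")
  std_normal_cdf(-signed_distance(state, x, y) / state$ps)
}

#' Update one system's state from trial feedback
#'
#' If the system's own prediction matched the true category, the boundary
#' is trusted and confidence grows: `ps` shrinks to `ps * (1 - ps_lr)`. If
#' the prediction was wrong, the boundary moves by
#' `lr * |signed_distance|` in the direction that places the stimulus
#' deeper inside its true category's region (strictly increasing the
#' probability the system assigns the true category, provided the step does
#' not overshoot past the stimulus), and `ps` grows to `ps * (1 + ps_lr)`.
#'
#' @param state A [system_state()].
#' @param x,y The trial's stimulus coordinates (scalars).
#' @param predicted The system's own predicted category (`"A"` iff its
#'   `p(A) > 0.5`; exactly 0.5 predicts `"B"`).
#' @param actual The true category.
#' @param lr A [learning_rates()] object.
#' @return The updated `system_state`.
#' @export
apply_feedback <- function(state, x, y, predicted, actual, lr) {
  stopifnot(inherits(state, "system_state"), inherits(lr, "learning_rates"),
            predicted %in% .CATEGORIES, actual %in% .CATEGORIES)
  if (predicted == actual) {
    # numerical floor keeps ps strictly positive at double precision
    state$ps <- max(state$ps * (1 - lr$ps_lr), 1e-300)
  } else {
    rate <- if (state$system_id == "RB") lr$rb_lr else lr$ii_lr
    step <- rate * abs(signed_distance(state, x, y))
    # signed distance is decreasing in the boundary parameter for both
    # systems, so moving the boundary up pushes the stimulus toward A
    state$boundary <- state$boundary + if (actual == "A") step else -step
    state$ps <- state$ps * (1 + lr$ps_lr)
  }
  state
}
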