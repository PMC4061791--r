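test_that("system_state and learning_rates validate their fields", {
  expect_error(system_state("RB", Inf, 1), "finite")
  expect_error(system_state("RB", 0, 0), "ps")
  expect_error(learning_rates(-0.1, 0.1, 0.5), "non-negative")
  expect_error(learning_rates(0.1, 0.1, 1), "ps_lr")
  lr <- learning_rates(0.1, 0.2, 0.5)
  expect_s3_class(lr, "learning_rates")
})

test_that("signed distance: vertical for RB, perpendicular for II", {
  rb <- system_state("RB", 150, 10)
  expect_equal(signed_distance(rb, 180, 999), 30)
  expect_equal(signed_distance(rb, 120, 0), -30)
  ii <- system_state("II", 0, 10)
  expect_equal(signed_distance(ii, 100, 120), 20 / sqrt(2))
  expect_equal(signed_distance(ii, 120, 100), -20 / sqrt(2))
  # II distance is invariant along the boundary direction
  expect_equal(signed_distance(ii, 100, 120), signed_distance(ii, 160, 180))
})

test_that("four-constant CDF approximation has the right shape", {
  expect_equal(std_normal_cdf(0), 0.5)
  z <- seq(-5, 5, by = 0.1)
  expect_equal(std_normal_cdf(z) + std_normal_cdf(-z), rep(1, length(z)))
  expect_true(all(diff(std_normal_cdf(z)) > 0))
  # known reference value Phi(1) = 0.8413447..., within the stated
  # absolute error of the four-constant approximation
  expect_lt(abs(std_normal_cdf(1) - 0.8413447), 2.5e-4)
  expect_error(std_normal_cdf(NaN), "finite")
})

test_that("category_probability is the bisected-Gaussian mass", {
  st <- system_state("RB", 150, 20)
  expect_equal(category_probability(st, 150, 0), 0.5) # on the bound
  expect_gt(category_probability(st, 120, 0), 0.5)    # A side
  expect_lt(category_probability(st, 180, 0), 0.5)    # B side
  # huge spread -> no confidence; tiny spread -> saturation
  expect_equal(category_probability(system_state("RB", 150, 1e6), 120, 0),
               0.5, tolerance = 1e-4)
  expect_gt(category_probability(system_state("RB", 150, 1), 120, 0),
            1 - 1e-9)
})

test_that("correct feedback shrinks ps and leaves the boundary alone", {
  lr <- learning_rates(0.2, 0.2, 0.4)
  st <- system_state("RB", 150, 100)
  up <- apply_feedback(st, 120, 0, "A", "A", lr)
  expect_equal(up$boundary, 150)
  expect_equal(up$ps, 60)
})

test_that("error feedback moves the boundary by lr times the distance", {
  # worked example: boundary 150, stimulus at 180, lr 0.5, truth A
  lr <- learning_rates(0.5, 0.5, 0.4)
  st <- system_state("RB", 150, 100)
  up <- apply_feedback(st, 180, 0, "B", "A", lr)
  expect_equal(up$boundary, 165)
  expect_equal(up$ps, 140)
  # mirrored direction when the truth is B
  st2 <- system_state("RB", 150, 100)
  up2 <- apply_feedback(st2, 120, 0, "A", "B", lr)
  expect_equal(up2$boundary, 135)
})

test_that("error update strictly increases p(true category)", {
  set.seed(42)
  lr <- learning_rates(0.3, 0.3, 0.1)
  for (i in 1:50) {
    sys <- sample(c("RB", "II"), 1)
    st <- system_state(sys, runif(1, 50, 250), runif(1, 5, 200))
    x <- runif(1, 0, 300); y <- runif(1, 0, 300)
    p_a <- category_probability(st, x, y)
    pred <- if (p_a > 0.5) "A" else "B"
    truth <- if (pred == "A") "B" else "A" # force an error trial
    before <- if (truth == "A") p_a else 1 - p_a
    up <- apply_feedback(st, x, y, pred, truth, lr)
    p_a2 <- category_probability(up, x, y)
    after <- if (truth == "A") p_a2 else 1 - p_a2
    expect_gt(after, before)
  }
})

test_that("ps stays strictly positive under extreme shrinking", {
  lr <- learning_rates(0.1, 0.1, 1 - 1e-9)
  st <- system_state("RB", 150, 1e-300)
  up <- apply_feedback(st, 120, 0, "A", "A", lr)
  expect_gt(up$ps, 0)
  expect_silent(category_probability(up, 120, 0))
})
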