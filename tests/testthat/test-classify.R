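test_that("classify_competition reproduces the worked configurations", {
  expect_identical(classify_competition(0.9, 0.1), "C")
  expect_identical(classify_competition(0.9, 0.6), "NC")
  expect_identical(classify_competition(0.9, 0.85), "undefined")
  expect_identical(classify_competition(0.6, 0.6), "undefined")
})

test_that("the confidence threshold is a strict inequality", {
  expect_identical(classify_competition(0.75, 0.9), "NC")
  expect_identical(classify_competition(0.75, 0.75), "undefined")
  # confidence is symmetric around 0.5: p(A)=0.1 is 0.9 confident
  expect_identical(classify_competition(0.1, 0.9), "C")   # confident, differ
  expect_identical(classify_competition(0.1, 0.1), "undefined") # agree
})

test_that("every trial gets exactly one class (partition property)", {
  set.seed(33)
  p_rb <- runif(500); p_ii <- runif(500)
  cls <- classify_competition(p_rb, p_ii)
  expect_true(all(cls %in% c("C", "NC", "undefined")))
  expect_length(cls, 500)
})

test_that("raising the threshold never increases the C count", {
  set.seed(34)
  p_rb <- runif(400); p_ii <- runif(400)
  counts <- sapply(c(0.6, 0.7, 0.8, 0.9),
                   function(th) sum(classify_competition(p_rb, p_ii,
                                                         th) == "C"))
  expect_true(all(diff(counts) <= 0))
})

test_that("best_fit_blocks takes the ceiling of the top fraction", {
  fits <- rep(c(-10, -20, -30, -40, -50, -60), each = 2)
  blocks <- rep(1:6, each = 2)
  expect_equal(best_fit_blocks(blocks, fits), c(1, 2))
  expect_equal(best_fit_blocks(blocks, fits, fraction = 1), 1:6)
  # ties break toward the lower block id
  expect_equal(best_fit_blocks(rep(1:6, each = 2), rep(-1, 12)), c(1, 2))
  expect_equal(best_fit_blocks(1:4, c(-1, -2, -3, -4)), c(1, 2))
  expect_error(best_fit_blocks(numeric(0), numeric(0)), "empty")
})

test_that("tag_off_system scores the loser's covert prediction", {
  tr <- data.frame(trial = 1:3, winner = c("RB", "RB", "II"),
                   p_a_rb = c(0.9, 0.9, 0.2), p_a_ii = c(0.7, 0.3, 0.5),
                   true_category = c("A", "A", "A"))
  tags <- tag_off_system(tr)
  expect_equal(tags$off_system, c("II", "II", "RB"))
  expect_equal(tags$off_system_correct, c(TRUE, FALSE, FALSE))
  # exactly 0.5 predicts B by the global tie rule and is flagged
  tr2 <- data.frame(trial = 1, winner = "RB", p_a_rb = 0.9, p_a_ii = 0.5,
                    true_category = "B")
  tags2 <- tag_off_system(tr2)
  expect_identical(tags2$off_system_prediction, "B")
  expect_true(tags2$off_system_correct)
  expect_true(tags2$off_system_on_bound)
})

test_that("tag_off_system accepts replay tables via 'responsible'", {
  tr <- data.frame(trial = 1, responsible = "II", p_a_rb = 0.8,
                   p_a_ii = 0.9, true_category = "A")
  expect_equal(tag_off_system(tr)$off_system, "RB")
  expect_error(tag_off_system(data.frame(p_a_rb = 1, p_a_ii = 1,
                                         true_category = "A")),
               "winner")
})

test_that("summarize_by_class partitions each block to 100 percent", {
  beh <- simulate_behavior(make_structure("II"), model_params(), 35, 36)
  tags <- tag_off_system(attr(beh, "session")$trace)
  tab <- summarize_by_class(tags, beh)
  expect_equal(names(tab), c("block", "class", "n", "pct", "accuracy",
                             "rt"))
  for (b in unique(tab$block)) {
    expect_equal(sum(tab$pct[tab$block == b]), 100)
  }
  expect_equal(sum(tab$n), nrow(beh))
})

test_that("summarize_by_class keeps empty classes with NA statistics", {
  cls <- data.frame(trial = 1:4, competition_class = rep("NC", 4))
  beh <- data.frame(trial = 1:4, block = 1, correct = c(TRUE, FALSE,
                                                        TRUE, TRUE))
  tab <- summarize_by_class(cls, beh)
  c_row <- tab[tab$class == "C", ]
  expect_equal(c_row$n, 0)
  expect_true(is.na(c_row$accuracy))
  expect_equal(tab$accuracy[tab$class == "NC"], 0.75)
})
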