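test_that("model_params carries the reference defaults and validates", {
  p <- model_params()
  expect_equal(p$rb_lr, 0.1703)
  expect_equal(p$ii_lr, 0.0288)
  expect_equal(p$ps_lr, 0.5382)
  expect_equal(p$ps_init, 145932)
  expect_equal(p$dm_noise, 1.2043)
  expect_equal(p$feedback_model, 2L)
  expect_error(model_params(ps_init = 0), "ps_init")
  expect_error(model_params(dm_noise = -1), "dm_noise")
  expect_error(model_params(feedback_model = 13), "feedback_model")
})

test_that("single_lr_mode constrains the two learning rates to be equal", {
  p <- model_params(rb_lr = 0.2, ii_lr = 0.05, single_lr_mode = TRUE)
  expect_equal(p$ii_lr, 0.2)
})

test_that("boundaries initialize from the first two stimuli", {
  b <- init_boundaries(c(100, 200), c(120, 260))
  expect_equal(b$rb_boundary, 150)
  expect_equal(b$ii_boundary, mean(c(20, 60)))
  expect_error(init_boundaries(1, 2))
})

test_that("compiled and reference engines produce identical traces", {
  sq <- generate_sequence(make_structure("II"), 160, 80, seed = 4)
  p <- model_params()
  a <- run_session(p, sq, seed = 9, engine = "cpp")
  b <- run_session(p, sq, seed = 9, engine = "r")
  shared <- intersect(names(a$trace), names(b$trace))
  expect_equal(a$trace[, shared], b$trace[, shared])
  expect_equal(a$block_accuracy, b$block_accuracy)
  expect_equal(a$rb_win_fraction, b$rb_win_fraction)
  expect_equal(a$final_states$rb$boundary, b$final_states$rb$boundary)
  expect_equal(a$final_states$ii$ps, b$final_states$ii$ps)
})

test_that("sessions are reproducible by seed", {
  sq <- generate_sequence(make_structure("RB"), 160, 80, seed = 4)
  a <- run_session(model_params(), sq, seed = 10)
  b <- run_session(model_params(), sq, seed = 10)
  c <- run_session(model_params(), sq, seed = 11)
  expect_identical(a$trace, b$trace)
  expect_false(identical(a$trace$response, c$trace$response))
})

test_that("a non-learning model stays at chance", {
  sq <- generate_sequence(make_structure("RB"), 320, 80, seed = 6)
  p <- model_params(rb_lr = 0, ii_lr = 0, ps_lr = 0)
  res <- run_session(p, sq, seed = 7)
  # huge ps and no updates: probability matching at ~0.5 throughout
  expect_true(all(abs(res$block_accuracy - 0.5) < 0.15))
  expect_equal(res$final_states$rb$ps, p$ps_init)
})

test_that("a learning model improves across blocks in both conditions", {
  for (cond in c("RB", "II")) {
    sq <- generate_sequence(make_structure(cond), 320, 80, seed = 8)
    res <- run_session(model_params(), sq, seed = 9)
    expect_gt(res$block_accuracy[4], res$block_accuracy[1])
    expect_gt(res$block_accuracy[4], 0.8)
  }
})

test_that("run_group summarizes 4 blocks x 2 conditions reproducibly", {
  structs <- list(RB = make_structure("RB"), II = make_structure("II"))
  g1 <- run_group(model_params(), structs, n_runs = 10, base_seed = 3)
  g2 <- run_group(model_params(), structs, n_runs = 10, base_seed = 3)
  expect_identical(g1, g2)
  expect_equal(nrow(g1), 8)
  expect_setequal(unique(g1$condition), c("RB", "II"))
  expect_equal(attr(g1, "n_runs"), 10)
  expect_true(all(g1$mean_acc >= 0 & g1$mean_acc <= 1))
  expect_true(all(g1$sd_acc >= 0))
})

test_that("pregenerated sequences reproduce run_group exactly", {
  structs <- list(RB = make_structure("RB"), II = make_structure("II"))
  seqs <- pregenerate_sequences(structs, 5, base_seed = 3)
  g1 <- run_group(model_params(), structs, n_runs = 5, base_seed = 3)
  g2 <- run_group(model_params(), structs, n_runs = 5, base_seed = 3,
                  sequences = seqs)
  expect_identical(g1, g2)
})

test_that("derived run seeds stay below 2^31", {
  expect_error(run_group(model_params(),
                         list(RB = make_structure("RB"),
                              II = make_structure("II")),
                         n_runs = 2, base_seed = 2^31 - 1),
               "seed")
})
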