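test_that("published session designs yield exact per-position counts", {
  for (seed in 1:3) {
    # child box design: five boxes, 15 test trials, each box exactly 3x
    sess <- generate_session(session_config(version = "box", cohort = "child",
                                            seed = seed))
    expect_equal(unname(table(sess$box[sess$phase == "test"])),
                 rep(3L, 5), ignore_attr = TRUE)

    # adult hedge retest design: 30 test trials, each of ten bins 3x
    sess <- generate_session(session_config(version = "hedge", cohort = "adult",
                                            mode = "fixed_retest", seed = seed))
    test <- sess[sess$phase == "test", ]
    expect_equal(nrow(test), 30L)
    expect_equal(unname(table(test$bin)), rep(3L, 10), ignore_attr = TRUE)

    # adult box retest design: 32 test trials, each of eight boxes 4x
    sess <- generate_session(session_config(version = "box", cohort = "adult",
                                            mode = "fixed_retest", seed = seed))
    test <- sess[sess$phase == "test", ]
    expect_equal(nrow(test), 32L)
    expect_equal(unname(table(test$box)), rep(4L, 8), ignore_attr = TRUE)
  }
})

test_that("15-trial hedge sessions use each bin once plus one repeat per adjacent pair", {
  for (seed in 1:5) {
    sess <- generate_session(session_config(version = "hedge", cohort = "child",
                                            seed = seed))
    counts <- table(factor(sess$bin[sess$phase == "test"], levels = 0:9))
    expect_equal(sum(counts), 15)
    expect_true(all(counts >= 1 & counts <= 2))
    doubled <- as.integer(names(counts)[counts == 2])
    expect_length(doubled, 5)
    # exactly one doubled bin per pair {0,1}, {2,3}, ..., {8,9}
    expect_equal(unname(table(doubled %/% 2)), rep(1L, 5), ignore_attr = TRUE)
  }
})

test_that("balance and run-length constraints hold across many sessions", {
  withr::with_seed(99, {
    for (i in 1:100) {
      version <- sample(c("hedge", "box"), 1)
      sess <- generate_session(session_config(version = version, seed = NULL))
      test <- sess[sess$phase == "test", ]
      for (col in c("agent", "color", if (version == "hedge") "bin" else "box")) {
        counts <- table(test[[col]])
        expect_lte(max(counts) - min(counts), 1,
                   label = sprintf("%s count spread, %s", col, version))
        expect_lte(max(rle(as.character(test[[col]]))$lengths), 2,
                   label = sprintf("%s run length, %s", col, version))
      }
    }
  })
})

test_that("sessions are deterministic in the seed", {
  cfg <- session_config(version = "hedge", seed = 123)
  expect_identical(generate_session(cfg), generate_session(cfg))
  cfg2 <- session_config(version = "hedge", seed = 124)
  expect_false(identical(generate_session(cfg)$target_x,
                         generate_session(cfg2)$target_x))

  retest_cfg <- session_config(cohort = "adult", mode = "fixed_retest",
                               seed = 11)
  expect_identical(fixed_retest_sequence(retest_cfg),
                   fixed_retest_sequence(retest_cfg))
  expect_error(fixed_retest_sequence(session_config(seed = 1)), "fixed_retest")
})

test_that("target coordinates fall inside their declared bin or box", {
  sess <- generate_session(session_config(version = "hedge", seed = 5))
  expect_true(all(sess$target_x >= sess$bin / 10 &
                    sess$target_x < (sess$bin + 1) / 10))
  sessb <- generate_session(session_config(version = "box", seed = 5))
  layout <- scene_layout(n_boxes = 5)
  expect_true(all(sessb$target_x >= layout$box_edges[sessb$box + 1] &
                    sessb$target_x < layout$box_edges[sessb$box + 2]))
})

test_that("coordinates are uniform within a bin", {
  expect_error(sample_coordinate_in_bin(10, default_layout), "out of range")
  withr::with_seed(8, {
    x <- sample_coordinate_in_bin(rep(3L, 10000), default_layout)
    expect_true(all(x >= 0.3 & x < 0.4))
    ks <- suppressWarnings(stats::ks.test(x, "punif", 0.3, 0.4))
    expect_gt(ks$p.value, 0.01)
  })
})

test_that("training ramps visual access down and flags voice-overs", {
  sess <- generate_session(session_config(seed = 2))
  training <- sess[startsWith(sess$phase, "training"), ]
  expect_equal(training$visibility, c("full", "partial", "partial", "none"))
  # voice-over on the first trial of each phase type present in a session
  expect_equal(which(sess$voiceover), c(1L, 2L, 5L))
  expect_error(training_block(session_config(n_training = 2)), "at least 3")
})

test_that("unsatisfiable run-length constraints fail with a clear error", {
  # a single box cannot avoid runs longer than two
  cfg <- session_config(version = "box", n_boxes = 1, n_test = 15, seed = 1)
  expect_error(generate_session(cfg), "unsatisfiable|runs")
})
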