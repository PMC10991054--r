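noiseless <- function() {
  p <- participant_params(gaze_noise_sd = 1e-9, motor_noise_sd = 0,
                          lapse_rate = 0)
  p
}

test_that("the noiseless limit reproduces the target exactly", {
  sess <- generate_session(session_config(version = "hedge", seed = 4))
  test <- sess[sess$phase == "test", ]
  withr::with_seed(1, {
    clicks <- simulate_click(noiseless(), test, default_layout)
  })
  expect_equal(clicks, test$target_x, tolerance = 1e-6)

  sessb <- generate_session(session_config(version = "box", seed = 4))
  testb <- sessb[sessb$phase == "test", ]
  layout5 <- scene_layout(n_boxes = 5)
  withr::with_seed(1, {
    boxes <- simulate_box_choice(noiseless(), testb, layout5)
  })
  expect_equal(boxes, testb$box)
})

test_that("pure lapsing gives uniform clicks and analytic chance accuracy", {
  lapser <- participant_params(gaze_noise_sd = 1, motor_noise_sd = 0,
                               lapse_rate = 1)
  trials <- tibble::tibble(target_x = rep(0.25, 5000), visibility = "none",
                           box = rep(1L, 5000))
  withr::with_seed(2, {
    clicks <- simulate_click(lapser, trials, default_layout)
    expect_equal(mean(clicks), 0.5, tolerance = 0.03)
    expect_gt(stats::sd(clicks), 0.25)

    layout5 <- scene_layout(n_boxes = 5)
    boxes <- simulate_box_choice(lapser, trials, layout5)
    acc <- mean(boxes == trials$box)
    expect_lt(abs(acc - chance_level(5)), 0.02)
  })
})

test_that("more angular gaze noise means more imprecision, more boxes lower accuracy", {
  target <- tibble::tibble(target_x = runif(4000), visibility = "none")
  imp <- vapply(c(1, 2, 4), function(sd_deg) {
    p <- participant_params(gaze_noise_sd = sd_deg, motor_noise_sd = 0,
                            lapse_rate = 0)
    withr::with_seed(3, {
      clicks <- simulate_click(p, target, default_layout)
    })
    mean(imprecision(clicks, target$target_x, default_layout$target_width))
  }, numeric(1))
  expect_true(all(diff(imp) > 0))

  acc <- vapply(c(5L, 8L), function(k) {
    layout <- scene_layout(n_boxes = k)
    cfg <- session_config(version = "box", n_boxes = k, n_test = 40,
                          cohort = "adult", seed = 6)
    test <- generate_session(cfg, layout)
    test <- test[test$phase == "test", ]
    test <- dplyr::bind_rows(replicate(50, test, simplify = FALSE))
    p <- participant_params(gaze_noise_sd = 4, motor_noise_sd = 0,
                            lapse_rate = 0)
    withr::with_seed(4, {
      boxes <- simulate_box_choice(p, test, layout)
    })
    mean(boxes == test$box)
  }, numeric(1))
  expect_gt(acc[1], acc[2])
})

test_that("cohort simulation bookkeeping and reproducibility", {
  pop <- population_config(n_subjects = 12, n_days = 2, seed = 5)
  cfg <- session_config(version = "hedge", mode = "fixed_retest", seed = 5)
  rec <- simulate_cohort(pop, cfg)
  expect_equal(nrow(rec), 12 * 2 * 15)
  expect_equal(dplyr::n_distinct(rec$subject_id), 12)
  expect_identical(rec, simulate_cohort(pop, cfg))
  # fixed retest: every subject sees the same target sequence on both days
  expect_equal(dplyr::n_distinct(split(rec$target_x, paste(rec$subject_id, rec$day))), 1)

  expect_error(population_config(n_subjects = 1, n_days = 2), "at least 2")
})

test_that("a negative age slope on log gaze noise yields an age-imprecision anticorrelation", {
  pop <- population_config(n_subjects = 200, age_slope = -0.4, seed = 21)
  rec <- score_responses(simulate_cohort(pop, session_config(seed = 21)))
  subj <- rec |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(age = age_months[1], imp = mean(performance))
  expect_lt(stats::cor(subj$age, subj$imp), 0)
})

test_that("without subject-level heterogeneity, between-subject variance matches the within-trial prediction", {
  pop <- population_config(n_subjects = 150, age_slope = 0, noise_sd = 0,
                           lapse_rate = 0, seed = 31)
  rec <- score_responses(simulate_cohort(pop, session_config(seed = 31)))
  per_subj <- rec |>
    dplyr::group_by(subject_id) |>
    dplyr::summarise(m = mean(performance), v = stats::var(performance),
                     n = dplyr::n())
  predicted <- mean(per_subj$v) / mean(per_subj$n)
  observed <- stats::var(per_subj$m)
  expect_lt(observed / predicted, 2.5)
  expect_gt(observed / predicted, 0.4)
})

test_that("model-based recovery cohorts honor their generating structure", {
  d <- simulate_retest_cohort(n_subjects = 50, n_trials = 10, rho = 0.9,
                              seed = 9)
  expect_equal(nrow(d), 50 * 2 * 10)
  expect_identical(d, simulate_retest_cohort(n_subjects = 50, n_trials = 10,
                                             rho = 0.9, seed = 9))
  expect_true(all(d$performance > 0))

  b <- simulate_trajectory_cohort(n_subjects = 40, n_trials = 8,
                                  family = "bernoulli_logit", seed = 9)
  expect_true(all(b$performance %in% 0:1))
  expect_equal(nrow(b), 40 * 8)
})
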