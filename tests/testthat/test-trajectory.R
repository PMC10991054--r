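test_that("lognormal trajectory model recovers its generating age effect", {
  d <- simulate_trajectory_cohort(n_subjects = 150, n_trials = 15, seed = 41)
  fit <- fit_trajectory(d, family = "lognormal")
  td <- tidy(fit)
  age <- td[td$term == "age_z", ]
  expect_true(age$conf.low <= -0.32 && -0.32 <= age$conf.high)
  expect_lt(age$estimate, 0)
  expect_true(glance(fit)$converged)
})

test_that("a zero-effect simulation yields intervals covering zero", {
  d <- simulate_trajectory_cohort(
    n_subjects = 80, n_trials = 10,
    beta = c(intercept = 0.2, age = 0, mode = 0,
             symmetric_position = 0, trial = 0),
    seed = 43)
  td <- tidy(fit_trajectory(d, family = "lognormal"))
  for (term in c("age_z", "mode_remote", "symmetric_position", "trial_z")) {
    row <- td[td$term == term, ]
    expect_true(row$conf.low <= 0 && 0 <= row$conf.high, label = term)
  }
})

test_that("Bernoulli trajectory model recovers the signs of the generating effects", {
  d <- simulate_trajectory_cohort(n_subjects = 150, n_trials = 15,
                                  family = "bernoulli_logit", seed = 47)
  td <- tidy(fit_trajectory(d, family = "bernoulli_logit"))
  # accuracy rises with age and falls for less central targets
  expect_gt(td$estimate[td$term == "age_z"], 0)
  expect_lt(td$estimate[td$term == "symmetric_position"], 0)
})

test_that("predicted trajectories respect the link and the age effect direction", {
  d <- add_covariates(
    simulate_trajectory_cohort(n_subjects = 100, n_trials = 10, seed = 51) |>
      dplyr::mutate(target_x = symmetric_position + 0.5)
  )
  fit <- fit_trajectory(d, family = "lognormal")
  pred <- predict_trajectory(fit, age_months = seq(36, 71, by = 5))
  expect_true(all(diff(pred$predicted) < 0)) # imprecision falls with age
  expect_true(all(pred$conf.low <= pred$predicted &
                    pred$predicted <= pred$conf.high))

  db <- add_covariates(
    simulate_trajectory_cohort(n_subjects = 100, n_trials = 10,
                               family = "bernoulli_logit", seed = 51) |>
      dplyr::mutate(target_x = symmetric_position + 0.5)
  )
  fitb <- fit_trajectory(db, family = "bernoulli_logit")
  predb <- predict_trajectory(fitb, age_months = seq(36, 71, by = 5))
  expect_true(all(diff(predb$predicted) > 0)) # accuracy rises with age
  expect_true(all(predb$predicted >= 0 & predb$predicted <= 1))
})

test_that("the MCMC backend agrees with the Laplace backend on a small fit", {
  d <- simulate_trajectory_cohort(n_subjects = 60, n_trials = 10, seed = 53)
  mcmc <- fit_trajectory(d, family = "lognormal", backend = "mcmc",
                         n_adapt = 300, n_burn = 300, n_iter = 600, seed = 53)
  lap <- fit_trajectory(d, family = "lognormal")
  a_m <- tidy(mcmc)$estimate[tidy(mcmc)$term == "age_z"]
  a_l <- tidy(lap)$estimate[tidy(lap)$term == "age_z"]
  expect_lt(abs(a_m - a_l), 0.15)
  expect_lt(a_m, 0)
})

test_that("lognormal outcomes are validated and zeros handled", {
  d <- simulate_trajectory_cohort(n_subjects = 30, n_trials = 6, seed = 57)
  d$performance[1] <- 0
  expect_silent(suppressWarnings(fit_trajectory(d, family = "lognormal")))
  d$performance[1] <- -1
  expect_error(suppressWarnings(fit_trajectory(d, family = "lognormal")),
               "non-negative")
})
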