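test_that("splitting methods produce the expected part structure", {
  trials <- 0:14
  oe <- split_trials(trials, split_plan("odd_even"))[[1]]
  expect_length(oe$part1, 8)
  expect_length(oe$part2, 7)
  expect_setequal(c(oe$part1, oe$part2), trials)

  fs <- split_trials(trials, split_plan("first_second"))[[1]]
  expect_equal(fs$part1, 0:7)
  expect_equal(fs$part2, 8:14)

  perm <- split_trials(trials, split_plan("permutated", n_replicates = 20))
  expect_length(perm, 20)
  for (sp in perm) {
    expect_length(intersect(sp$part1, sp$part2), 0)
    expect_setequal(c(sp$part1, sp$part2), trials)
    expect_lte(abs(length(sp$part1) - length(sp$part2)), 1)
  }

  mc <- split_trials(trials, split_plan("monte_carlo", n_replicates = 5))
  expect_length(mc, 5)
  expect_length(mc[[1]]$part1, 8) # halves drawn with replacement

  expect_error(split_trials(0L, split_plan("odd_even")), "at least 2")
  expect_error(split_plan("odd_even", n_replicates = 10), "exactly 1")
})

test_that("stratified splits represent every target position in both parts", {
  cfg <- session_config(version = "hedge", cohort = "adult",
                        mode = "fixed_retest", seed = 13)
  test <- dplyr::filter(fixed_retest_sequence(cfg), phase == "test")
  sp <- split_trials(test$index, split_plan("odd_even", stratify = TRUE),
                     strata = test$bin)[[1]]
  bins1 <- test$bin[match(sp$part1, test$index)]
  bins2 <- test$bin[match(sp$part2, test$index)]
  expect_setequal(bins1, 0:9) # 3 trials per bin -> 2 in part 1, 1 in part 2
  expect_setequal(bins2, 0:9)
  expect_error(split_trials(test$index, split_plan("odd_even", stratify = TRUE)),
               "strata")
})

test_that("degenerate split-half inputs are rejected, identical parts correlate perfectly", {
  # identical halves: every subject's parts carry the same score
  d <- tibble::tibble(
    subject_id = rep(sprintf("S%d", 1:10), each = 4),
    trial_index = rep(0:3, 10),
    performance = rep(rnorm(10), each = 4)
  )
  r <- split_half(d, split_plan("odd_even"))
  expect_equal(r$coefficient[!r$corrected], 1)
  expect_equal(r$coefficient[r$corrected], 1)

  constant <- dplyr::mutate(d, performance = 1)
  expect_error(split_half(constant, split_plan("odd_even")), "variance")
  expect_error(split_half(d[d$subject_id %in% c("S1", "S2"), ],
                          split_plan("odd_even")), "3 subjects")
})

test_that("split-half estimates match the analytic intraclass prediction", {
  tau <- 1; sigma <- 2; n_trials <- 30
  expected <- tau^2 / (tau^2 + sigma^2 / (n_trials / 2))
  full <- tau^2 / (tau^2 + sigma^2 / n_trials)
  # average over datasets: the estimator's Monte-Carlo SD is ~0.022 at
  # n = 300, so the mean of three is accurate to ~0.013 (1 SD)
  res <- lapply(101:103, function(s) {
    d <- gaussian_trial_data(300, n_trials, tau, sigma, seed = s)
    split_half(d, split_plan("odd_even"), n_boot = 50)
  })
  raw <- mean(vapply(res, function(r) r$coefficient[!r$corrected], numeric(1)))
  sb <- mean(vapply(res, function(r) r$coefficient[r$corrected], numeric(1)))
  expect_lt(abs(raw - expected), 0.04)
  # the Spearman-Brown projection targets the full-length reliability
  expect_lt(abs(sb - full), 0.04)
})

test_that("Spearman-Brown correction is monotone and never shrinks a positive coefficient", {
  r <- seq(0.05, 0.95, by = 0.1)
  sb <- spearman_brown(r)
  expect_true(all(diff(sb) > 0))
  expect_true(all(sb >= r))
  expect_true(all(sb <= 1))
})

test_that("reliability grows with trial count on simulated data", {
  r_short <- split_half(gaussian_trial_data(250, 10, 1, 2, seed = 55),
                        split_plan("odd_even"))$coefficient[1]
  r_long <- split_half(gaussian_trial_data(250, 40, 1, 2, seed = 55),
                       split_plan("odd_even"))$coefficient[1]
  expect_gt(r_long, r_short)
})

test_that("resampling estimators stabilize as replicates grow", {
  d <- gaussian_trial_data(60, 15, 1, 2, seed = 77)
  r500 <- split_half(d, split_plan("permutated", n_replicates = 500,
                                   seed = 3), n_boot = 10)
  r1000 <- split_half(d, split_plan("permutated", n_replicates = 1000,
                                    seed = 4), n_boot = 10)
  expect_lt(abs(r500$coefficient[1] - r1000$coefficient[1]), 0.01)
})

test_that("test-retest Pearson correlation behaves at the extremes", {
  d1 <- tibble::tibble(subject_id = sprintf("S%d", 1:50), day = 1,
                       performance = rnorm(50))
  same <- dplyr::bind_rows(d1, dplyr::mutate(d1, day = 2))
  expect_equal(test_retest_pearson(same)$coefficient, 1)

  withr::with_seed(5, {
    indep <- dplyr::bind_rows(
      tibble::tibble(subject_id = sprintf("S%d", 1:1000), day = 1,
                     performance = rnorm(1000)),
      tibble::tibble(subject_id = sprintf("S%d", 1:1000), day = 2,
                     performance = rnorm(1000))
    )
  })
  expect_lt(abs(test_retest_pearson(indep)$coefficient), 0.08)
  expect_error(test_retest_pearson(d1), "both test days")
})

test_that("hierarchical retest model agrees with its fast Laplace cross-check", {
  d <- simulate_retest_cohort(n_subjects = 60, n_trials = 8, rho = 0.7,
                              tau = 0.5, sigma = 0.5, seed = 17)
  mcmc <- hierarchical_retest(d, family = "lognormal", backend = "mcmc",
                              n_adapt = 300, n_burn = 300, n_iter = 800,
                              seed = 17)
  lap <- hierarchical_retest(d, family = "lognormal", backend = "laplace")
  expect_lt(abs(mcmc$correlation - lap$correlation), 0.2)
  expect_true(mcmc$ci_low <= mcmc$correlation &&
                mcmc$correlation <= mcmc$ci_high)
  expect_true(abs(mcmc$correlation) <= 1)

  td <- tidy(mcmc)
  expect_true(all(c("rho", "beta_age") %in% td$term))
  g <- glance(mcmc)
  expect_equal(g$n_subjects, 60)
})

test_that("Bernoulli-family retest model runs on accuracy data", {
  d <- simulate_retest_cohort(n_subjects = 60, n_trials = 12, rho = 0.8,
                              tau = 1.2, intercept = 0,
                              family = "bernoulli_logit", seed = 23)
  fit <- hierarchical_retest(d, family = "bernoulli_logit",
                             backend = "laplace")
  expect_true(is.finite(fit$correlation))
  expect_true(abs(fit$correlation) <= 1)
})

test_that("age correction separates shared development from person-specific stability", {
  # person effects only moderately stable, but a strong age effect drives
  # both days: the raw cross-day Pearson correlation inflates above the
  # age-corrected person-effect correlation
  d <- simulate_retest_cohort(n_subjects = 150, n_trials = 15, rho = 0.3,
                              tau = 0.3, sigma = 0.4, beta_age = -1.2,
                              seed = 29)
  pearson <- test_retest_pearson(
    dplyr::mutate(d, performance = log(performance)))$coefficient
  fit <- hierarchical_retest(d, family = "lognormal", backend = "laplace")
  expect_gt(pearson, fit$correlation)
})
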