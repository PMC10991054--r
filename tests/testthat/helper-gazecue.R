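# shared fixtures, all generated in code

default_layout <- scene_layout()

# trial-level Gaussian performance data with known true-score variance
# tau^2 and trial noise sigma^2: the analytic split-half oracle is
# tau^2 / (tau^2 + sigma^2 / (n_trials / 2))
gaussian_trial_data <- function(n_subjects, n_trials, tau, sigma, seed = 1) {
  withr::with_seed(seed, {
    ability <- rnorm(n_subjects, 0, tau)
    tidyr::expand_grid(
      subject = seq_len(n_subjects),
      trial_index = seq_len(n_trials) - 1L
    ) |>
      dplyr::mutate(
        subject_id = sprintf("S%04d", subject),
        performance = ability[subject] + rnorm(dplyr::n(), 0, sigma)
      ) |>
      dplyr::select(subject_id, trial_index, performance)
  })
}

# small scored hedge cohort used by several reliability tests
scored_hedge_cohort <- function(n_subjects = 40, n_days = 1, seed = 7,
                                mode = "randomized") {
  pop <- population_config(n_subjects = n_subjects, n_days = n_days,
                           seed = seed)
  cfg <- session_config(version = "hedge", mode = mode, seed = seed)
  add_covariates(score_responses(simulate_cohort(pop, cfg)))
}
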