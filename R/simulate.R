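#' Latent response parameters for one synthetic participant
#'
#' The response process is deliberately simple and mechanistic: on each
#' trial the participant perceives the agent's gaze direction with
#' independent angular error on each eye (`gaze_noise_sd`, degrees),
#' inverts the perceived gaze geometrically ([infer_ground_x()]), adds
#' Gaussian motor noise to the click, and with probability `lapse_rate`
#' ignores the cue entirely and responds at random. These parameters are
#' testing conventions for the toolkit, not estimates of any human
#' response process.
#'
#' @param subject_id Subject label.
#' @param age_months Age in months.
#' @param mode Data-collection mode, `"in_person"` or `"remote"`.
#' @param gaze_noise_sd Angular SD of the perceived gaze direction per
#'   eye, in degrees (> 0).
#' @param motor_noise_sd SD of click motor noise, viewport units.
#' @param lapse_rate Probability of a random-response lapse, in `[0, 1]`.
#' @param day_shift Multiplicative factor applied to `gaze_noise_sd` on
#'   test day 2 (1 = identical precision on both days).
#' @return A one-row tibble of class `participant_params`.
#' @export
participant_params <- function(subject_id = "S001",
                               age_months = 54,
                               mode = c("in_person", "remote"),
                               gaze_noise_sd = 3,
                               motor_noise_sd = 0.01,
                               lapse_rate = 0.05,
                               day_shift = 1) {
  mode <- match.arg(mode)
  if (gaze_noise_sd <= 0) abort("`gaze_noise_sd` must be positive.")
  if (lapse_rate < 0 || lapse_rate > 1) abort("`lapse_rate` must be in [0, 1].")
  out <- tibble(
    subject_id = subject_id, age_months = age_months, mode = mode,
    gaze_noise_sd = gaze_noise_sd, motor_noise_sd = motor_noise_sd,
    lapse_rate = lapse_rate, day_shift = day_shift
  )
  class(out) <- c("participant_params", class(out))
  out
}

#' Population model for a synthetic cohort
#'
#' Subject-level gaze noise follows a log-linear age model:
#' `log(gaze_noise_sd) = log_noise_intercept + age_slope * age_z +
#' mode_effect * [remote] + N(0, noise_sd)`, where `age_z` is age in
#' months z-scored within the simulated sample. The log link keeps noise
#' positive and gives diminishing returns with age. Defaults emulate the
#' study conditions: 120 children aged 36-71 months, about half tested
#' remotely, two test days for retest designs.
#'
#' @param n_subjects Number of subjects (>= 2 when `n_days = 2`).
#' @param age_range Length-2 integer range of ages in months, inclusive.
#' @param log_noise_intercept Intercept of log gaze noise (log degrees)
#'   at the sample's mean age.
#' @param age_slope Slope of log gaze noise per SD of age (negative =
#'   older children are more precise).
#' @param noise_sd Between-subject SD of log gaze noise (tau, >= 0).
#' @param mode_effect Additive effect of remote testing on log gaze
#'   noise.
#' @param prop_remote Proportion of subjects tested remotely.
#' @param lapse_rate Shared lapse probability.
#' @param motor_noise_sd Shared motor noise SD (viewport units).
#' @param day_shift Multiplicative day-2 factor on gaze noise.
#' @param n_days 1 or 2 test days (retest designs use 2, nominally
#'   14 +/- 3 days apart).
#' @param seed Integer seed for the whole cohort simulation.
#' @return An object of class `population_config`.
#' @export
population_config <- function(n_subjects = 120,
                              age_range = c(36, 71),
                              log_noise_intercept = log(6),
                              age_slope = -0.4,
                              noise_sd = 0.4,
                              mode_effect = 0,
                              prop_remote = 0.5,
                              lapse_rate = 0.03,
                              motor_noise_sd = 0.01,
                              day_shift = 1,
                              n_days = 1,
                              seed = 1L) {
  if (!n_days %in% c(1L, 2L)) abort("`n_days` must be 1 or 2.")
  if (noise_sd < 0) abort("`noise_sd` (tau) must be non-negative.")
  if (n_subjects < 2 && n_days == 2) {
    abort("Reliability designs (`n_days = 2`) need at least 2 subjects.")
  }
  structure(
    list(
      n_subjects = as.integer(n_subjects), age_range = as.integer(age_range),
      log_noise_intercept = log_noise_intercept, age_slope = age_slope,
      noise_sd = noise_sd, mode_effect = mode_effect,
      prop_remote = prop_remote, lapse_rate = lapse_rate,
      motor_noise_sd = motor_noise_sd, day_shift = day_shift,
      n_days = as.integer(n_days), seed = as.integer(seed)
    ),
    class = "population_config"
  )
}

## vectorized click core: angular noise on each eye's gaze ray, geometric
## inversion, motor noise, lapses, clamped to the viewport
simulate_clicks_core <- function(target_x, layout, gaze_noise_sd,
                                 motor_noise_sd, lapse_rate) {
  n <- length(target_x)
  gy <- layout$ground_y
  xs <- matrix(NA_real_, n, 2)
  for (e in 1:2) {
    ex <- layout$eye_centers[e, 1]
    ey <- layout$eye_centers[e, 2]
    theta <- atan2(gy - ey, target_x - ex) +
      rnorm(n, 0, gaze_noise_sd * pi / 180)
    dy <- sin(theta)
    dx <- cos(theta)
    x <- ex + (gy - ey) / dy * dx
    # a perturbed ray pointing upward or parallel never meets the ground;
    # the cue then degenerates to the ray's lateral direction
    bad <- dy >= 0
    x[bad] <- ifelse(dx[bad] >= 0, 1e6, -1e6)
    xs[, e] <- pmin(pmax(x, -1e6), 1e6)
  }
  click <- rowMeans(xs) + rnorm(n, 0, motor_noise_sd)
  lapse <- runif(n) < lapse_rate
  click[lapse] <- runif(sum(lapse))
  pmin(pmax(click, 0), 1)
}

#' Simulate click responses for one participant
#'
#' For each trial, the true gaze angle of each eye toward the target is
#' perturbed by Gaussian angular noise, the perturbed rays are intersected
#' with the ground line and averaged (the same inversion as
#' [infer_ground_x()]), Gaussian motor noise is added, and the click is
#' clamped to the viewport. With probability `lapse_rate` the click is
#' instead uniform on `[0, 1]`.
#'
#' @param params A [participant_params()] row (or named list with fields
#'   `gaze_noise_sd`, `motor_noise_sd`, `lapse_rate`).
#' @param trials A trial tibble (e.g. from [generate_session()]); only
#'   trials without full visual access are simulated.
#' @param layout A [scene_layout()].
#' @return Numeric vector of click x-coordinates, one per trial row.
#' @export
simulate_click <- function(params, trials, layout) {
  stopifnot(inherits(layout, "scene_layout"))
  if (any(trials$visibility == "full")) {
    abort("Click simulation applies to trials with partial or no visual access.")
  }
  simulate_clicks_core(trials$target_x, layout,
                       params$gaze_noise_sd, params$motor_noise_sd,
                       params$lapse_rate)
}

#' Simulate box choices for one participant
#'
#' The simulated click ([simulate_click()]) is mapped to the box interval
#' containing it; on lapse trials a box is chosen uniformly at random.
#'
#' @inheritParams simulate_click
#' @return Integer vector of 0-based box indices.
#' @export
simulate_box_choice <- function(params, trials, layout) {
  stopifnot(inherits(layout, "scene_layout"))
  if (any(is.na(trials$box))) {
    abort("Box choice simulation requires box-version trials.")
  }
  n <- nrow(trials)
  clicks <- simulate_clicks_core(trials$target_x, layout,
                                 params$gaze_noise_sd, params$motor_noise_sd,
                                 lapse_rate = 0)
  boxes <- findInterval(clicks, layout$box_edges,
                        rightmost.closed = TRUE, all.inside = TRUE) - 1L
  lapse <- runif(n) < params$lapse_rate
  boxes[lapse] <- sample.int(layout$n_boxes, sum(lapse), replace = TRUE) - 1L
  boxes
}

#' Simulate a full cohort of synthetic participants
#'
#' Draws subject-level parameters once per subject from the population
#' model, generates a session per subject and day (or reuses the fixed
#' retest sequence), and simulates one response per subject x day x test
#' trial. Day-2 gaze noise is day-1 noise times `day_shift`. Fully
#' reproducible from `pop$seed`.
#'
#' @param pop A [population_config()].
#' @param config A [session_config()]; in `fixed_retest` mode the same
#'   sequence (from `config$seed`) is used for every subject and day.
#' @param layout A [scene_layout()]; defaults to one matching the config.
#' @return A tibble with one row per subject x day x test trial:
#'   `subject_id`, `age_months`, `mode`, `day`, `trial_index`, `version`,
#'   `agent`, `color`, `bin`, `box`, `target_x`, `target_width`,
#'   `voiceover`, and `click_x` (hedge) or `chosen_box` (box). The drawn
#'   subject parameters are attached as attribute `"participants"`.
#' @examples
#' pop <- population_config(n_subjects = 4, seed = 2)
#' cfg <- session_config(seed = 2)
#' records <- simulate_cohort(pop, cfg)
#' nrow(records) # 4 subjects x 15 test trials
#' @export
simulate_cohort <- function(pop, config, layout = NULL) {
  stopifnot(inherits(pop, "population_config"), inherits(config, "session_config"))
  layout <- layout %||%
    scene_layout(n_bins = config$n_bins, n_boxes = config$n_boxes)
  withr::with_seed(pop$seed, {
    ages <- sample(seq(pop$age_range[1], pop$age_range[2]), pop$n_subjects,
                   replace = TRUE)
    age_z <- if (sd(ages) > 0) (ages - mean(ages)) / sd(ages) else rep(0, length(ages))
    remote <- runif(pop$n_subjects) < pop$prop_remote
    gaze_sd <- exp(pop$log_noise_intercept + pop$age_slope * age_z +
                     pop$mode_effect * remote +
                     rnorm(pop$n_subjects, 0, pop$noise_sd))
    participants <- tibble(
      subject_id = sprintf("S%03d", seq_len(pop$n_subjects)),
      age_months = ages,
      mode = ifelse(remote, "remote", "in_person"),
      gaze_noise_sd = gaze_sd,
      motor_noise_sd = pop$motor_noise_sd,
      lapse_rate = pop$lapse_rate,
      day_shift = pop$day_shift
    )
    fixed_session <- if (config$mode == "fixed_retest") {
      sess <- fixed_retest_sequence(config, layout)
      sess[sess$phase == "test", ]
    } else NULL
    rows <- purrr::map(seq_len(pop$n_subjects), function(i) {
      purrr::map(seq_len(pop$n_days), function(d) {
        trials <- fixed_session %||% {
          cfg_i <- config
          cfg_i$seed <- NULL # consume the cohort RNG stream
          sess <- generate_session(cfg_i, layout)
          sess[sess$phase == "test", ]
        }
        p <- participants[i, ]
        p$gaze_noise_sd <- p$gaze_noise_sd * p$day_shift^(d - 1)
        resp <- tibble(
          subject_id = p$subject_id,
          age_months = p$age_months,
          mode = p$mode,
          day = d,
          trial_index = trials$index,
          version = config$version,
          agent = trials$agent,
          color = trials$color,
          bin = trials$bin,
          box = trials$box,
          target_x = trials$target_x,
          target_width = layout$target_width,
          voiceover = trials$voiceover
        )
        if (config$version == "hedge") {
          resp$click_x <- simulate_click(p, trials, layout)
          resp$chosen_box <- NA_integer_
        } else {
          resp$click_x <- NA_real_
          resp$chosen_box <- simulate_box_choice(p, trials, layout)
        }
        resp
      })
    })
    out <- dplyr::bind_rows(purrr::flatten(rows))
    attr(out, "participants") <- participants
    out
  })
}

#' Model-based retest cohort for parameter recovery
#'
#' Generates trial-level performance from the generative model underlying
#' [hierarchical_retest()]: each subject has a pair of day-specific person
#' effects drawn from a bivariate normal with SD `tau` and correlation
#' `rho`; trial performance is lognormal (or Bernoulli via the logit link)
#' around `intercept + beta_age * age_z + person effect`. Used to verify
#' that the retest model recovers a known person-effect correlation.
#'
#' @param n_subjects,n_trials Cohort dimensions (trials per day).
#' @param rho True correlation between day-1 and day-2 person effects.
#' @param tau SD of the person effects.
#' @param sigma Residual SD on the log scale (lognormal family only).
#' @param intercept,beta_age Fixed effects on the model's link scale.
#' @param family `"lognormal"` (imprecision-like outcome) or
#'   `"bernoulli_logit"` (accuracy-like outcome).
#' @param age_range Age range in months, sampled uniformly.
#' @param seed Integer seed.
#' @return Tibble with `subject_id`, `age_months`, `age_z`, `day`,
#'   `trial_index`, `performance`; generating values in attribute
#'   `"truth"`.
#' @export
simulate_retest_cohort <- function(n_subjects = 120, n_trials = 15,
                                   rho = 0.9, tau = 0.5, sigma = 0.6,
                                   intercept = 0, beta_age = -0.3,
                                   family = c("lognormal", "bernoulli_logit"),
                                   age_range = c(36, 71), seed = 1L) {
  family <- match.arg(family)
  if (abs(rho) > 1) abort("`rho` must be in [-1, 1].")
  withr::with_seed(seed, {
    ages <- sample(seq(age_range[1], age_range[2]), n_subjects, replace = TRUE)
    age_z <- if (sd(ages) > 0) (ages - mean(ages)) / sd(ages) else rep(0, n_subjects)
    cov <- matrix(c(tau^2, rho * tau^2, rho * tau^2, tau^2), 2)
    b <- matrix(rnorm(n_subjects * 2), n_subjects) %*% chol(cov)
    d <- tidyr::expand_grid(
      subject = seq_len(n_subjects), day = 1:2,
      trial_index = seq_len(n_trials) - 1L
    )
    mu <- intercept + beta_age * age_z[d$subject] + b[cbind(d$subject, d$day)]
    performance <- if (family == "lognormal") {
      rlnorm(nrow(d), mu, sigma)
    } else {
      rbinom(nrow(d), 1, plogis(mu))
    }
    out <- tibble(
      subject_id = sprintf("S%03d", d$subject),
      age_months = ages[d$subject],
      age_z = age_z[d$subject],
      day = d$day,
      trial_index = d$trial_index,
      performance = performance
    )
    attr(out, "truth") <- list(rho = rho, tau = tau, sigma = sigma,
                               intercept = intercept, beta_age = beta_age,
                               family = family)
    out
  })
}

#' Model-based trajectory cohort for parameter recovery
#'
#' Generates trial-level performance from the generative model underlying
#' [fit_trajectory()]: fixed effects of z-scored age, data-collection
#' mode, symmetric target position and z-scored trial number, plus
#' subject-level random intercepts and random slopes for symmetric
#' position and trial number. Defaults use the published coefficient
#' estimates as generating values (hedge/lognormal: age -0.32, mode
#' -0.31, symmetric position 0.47, trial 0; box/Bernoulli: age 0.68,
#' mode 1.10, symmetric position -1.59, trial -0.02).
#'
#' @param n_subjects,n_trials Cohort dimensions.
#' @param beta Named numeric vector of generating fixed effects:
#'   `intercept`, `age`, `mode`, `symmetric_position`, `trial`.
#' @param tau Length-3 SDs of the random intercept and the two random
#'   slopes (symmetric position, trial number).
#' @param sigma Residual SD on the log scale (lognormal family).
#' @param family Outcome family, as in [simulate_retest_cohort()].
#' @param prop_remote Proportion of remote-mode subjects.
#' @param age_range Age range in months.
#' @param seed Integer seed.
#' @return Tibble with `subject_id`, `age_months`, `age_z`, `mode`,
#'   `symmetric_position`, `trial_index`, `trial_z`, `performance`;
#'   generating values in attribute `"truth"`.
#' @export
simulate_trajectory_cohort <- function(n_subjects = 250, n_trials = 15,
                                       beta = NULL,
                                       tau = c(0.4, 0.2, 0.1), sigma = 0.6,
                                       family = c("lognormal", "bernoulli_logit"),
                                       prop_remote = 0.5,
                                       age_range = c(36, 71), seed = 1L) {
  family <- match.arg(family)
  beta <- beta %||% if (family == "lognormal") {
    c(intercept = 0.2, age = -0.32, mode = -0.31,
      symmetric_position = 0.47, trial = 0)
  } else {
    c(intercept = 0.5, age = 0.68, mode = 1.10,
      symmetric_position = -1.59, trial = -0.02)
  }
  stopifnot(length(beta) == 5, length(tau) == 3)
  withr::with_seed(seed, {
    ages <- sample(seq(age_range[1], age_range[2]), n_subjects, replace = TRUE)
    age_z <- if (sd(ages) > 0) (ages - mean(ages)) / sd(ages) else rep(0, n_subjects)
    remote <- runif(n_subjects) < prop_remote
    b <- cbind(rnorm(n_subjects, 0, tau[1]),
               rnorm(n_subjects, 0, tau[2]),
               rnorm(n_subjects, 0, tau[3]))
    d <- tidyr::expand_grid(subject = seq_len(n_subjects),
                            trial_index = seq_len(n_trials) - 1L)
    d$symmetric_position <- abs(runif(nrow(d)) - 0.5)
    trial_z <- as.numeric(scale(d$trial_index))
    mu <- beta[1] + beta[2] * age_z[d$subject] + beta[3] * remote[d$subject] +
      (beta[4] + b[d$subject, 2]) * d$symmetric_position +
      (beta[5] + b[d$subject, 3]) * trial_z +
      b[d$subject, 1]
    performance <- if (family == "lognormal") {
      rlnorm(nrow(d), mu, sigma)
    } else {
      rbinom(nrow(d), 1, plogis(mu))
    }
    out <- tibble(
      subject_id = sprintf("S%03d", d$subject),
      age_months = ages[d$subject],
      age_z = age_z[d$subject],
      mode = factor(ifelse(remote[d$subject], "remote", "in_person"),
                    levels = c("in_person", "remote")),
      symmetric_position = d$symmetric_position,
      trial_index = d$trial_index,
      trial_z = trial_z,
      performance = performance
    )
    attr(out, "truth") <- list(beta = beta, tau = tau, sigma = sigma,
                               family = family)
    out
  })
}
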