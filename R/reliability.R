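#' Plan for splitting trials into two halves
#'
#' Four splitting methods are supported. `first_second` and `odd_even`
#' are single-sample methods (each subject gets a single pair of part
#' scores); `permutated` (random partition without replacement) and
#' `monte_carlo` (halves drawn with replacement) are resampling methods
#' averaged over `n_replicates` splits. With `stratify = TRUE` the split
#' is applied within each target-position stratum (bin or box) and the
#' parts are pooled, so both halves sample the full range of target
#' positions.
#'
#' @param method Splitting method.
#' @param n_replicates Number of replicate splits for the resampling
#'   methods (default 1000); must be 1 for single-sample methods.
#' @param stratify Stratify by target position?
#' @param seed Integer seed for the resampling methods.
#' @return An object of class `split_plan`.
#' @export
split_plan <- function(method = c("first_second", "odd_even",
                                  "permutated", "monte_carlo"),
                       n_replicates = NULL,
                       stratify = FALSE,
                       seed = 1L) {
  method <- match.arg(method)
  single <- method %in% c("first_second", "odd_even")
  n_replicates <- n_replicates %||% if (single) 1L else 1000L
  n_replicates <- as.integer(n_replicates)
  if (n_replicates < 1) abort("`n_replicates` must be at least 1.")
  if (single && n_replicates != 1) {
    abort("Single-sample methods (first_second, odd_even) have exactly 1 replicate.")
  }
  structure(
    list(method = method, n_replicates = n_replicates,
         stratify = isTRUE(stratify), seed = as.integer(seed)),
    class = "split_plan"
  )
}

## split the ordered positions 1..n into two parts by `method`; the
## resampling methods consume the current RNG stream
split_positions <- function(n, method) {
  half <- ceiling(n / 2)
  switch(
    method,
    first_second = list(part1 = seq_len(half),
                        part2 = seq_len(n)[-seq_len(half)]),
    odd_even = list(part1 = seq(1, n, by = 2),
                    part2 = if (n >= 2) seq(2, n, by = 2) else integer(0)),
    permutated = {
      perm <- sample.int(n)
      list(part1 = sort(perm[seq_len(half)]),
           part2 = sort(perm[-seq_len(half)]))
    },
    monte_carlo = list(
      part1 = sample.int(n, half, replace = TRUE),
      part2 = sample.int(n, n - half, replace = TRUE)
    )
  )
}

## stratified split: apply the method within each stratum's ordered
## positions, then pool. A single-trial stratum contributes to part 1.
split_positions_stratified <- function(strata, method) {
  idx_by <- split(seq_along(strata), strata, drop = TRUE)
  parts <- lapply(idx_by, function(idx) {
    sp <- split_positions(length(idx), method)
    list(part1 = idx[sp$part1], part2 = idx[sp$part2])
  })
  list(part1 = sort(unlist(lapply(parts, `[[`, "part1"), use.names = FALSE)),
       part2 = sort(unlist(lapply(parts, `[[`, "part2"), use.names = FALSE)))
}

#' Split a sequence of trials into two halves
#'
#' Applies a [split_plan()] to an ordered set of trial identifiers,
#' returning one `(part1, part2)` pair per replicate. Without
#' stratification the parts partition the trials (Monte-Carlo halves are
#' drawn with replacement instead); with stratification the split is
#' performed within each stratum and pooled.
#'
#' @param trials Vector of trial identifiers, in presentation order.
#' @param plan A [split_plan()].
#' @param strata Optional vector of stratum labels (same length as
#'   `trials`), required when `plan$stratify` is `TRUE`.
#' @return A list of length `plan$n_replicates`; each element has
#'   `part1` and `part2` vectors of trial identifiers.
#' @examples
#' split_trials(0:14, split_plan("odd_even"))
#' @export
split_trials <- function(trials, plan, strata = NULL) {
  stopifnot(inherits(plan, "split_plan"))
  n <- length(trials)
  if (n < 2) abort("Need at least 2 trials to split.")
  if (plan$stratify) {
    if (is.null(strata)) abort("Stratified splitting needs `strata` labels.")
    if (length(strata) != n) abort("`strata` must match `trials` in length.")
  }
  one <- function() {
    sp <- if (plan$stratify) {
      split_positions_stratified(strata, plan$method)
    } else {
      split_positions(n, plan$method)
    }
    list(part1 = trials[sp$part1], part2 = trials[sp$part2])
  }
  run <- function() lapply(seq_len(plan$n_replicates), function(i) one())
  if (plan$method %in% c("permutated", "monte_carlo") && !is.null(plan$seed)) {
    withr::with_seed(plan$seed, run())
  } else {
    run()
  }
}

#' Spearman-Brown prophecy correction
#'
#' Projects a half-test correlation to the reliability of the full-length
#' test: `2 r / (1 + r)`. Monotone in `r` and never below `r` for
#' non-negative coefficients.
#'
#' @param r Half-test correlation(s).
#' @return Corrected coefficient(s).
#' @examples
#' spearman_brown(0.6)
#' @export
spearman_brown <- function(r) {
  2 * r / (1 + r)
}

## correlations between corresponding columns of two matrices
pairwise_col_cor <- function(x, y) {
  x <- sweep(x, 2, colMeans(x))
  y <- sweep(y, 2, colMeans(y))
  colSums(x * y) / sqrt(colSums(x^2) * colSums(y^2))
}

#' Split-half reliability coefficient
#'
#' For each subject, trials are split into two parts according to the
#' plan and performance is aggregated (arithmetic mean) within each part;
#' the part scores are then correlated across subjects with Pearson's r.
#' Resampling methods report the mean coefficient over replicates. Both
#' the raw half-test coefficient and its Spearman-Brown correction are
#' returned, each with a nonparametric bootstrap 95% CI over subjects.
#'
#' @param data Trial-level tibble with `subject_id`, `performance`, and
#'   (optionally) `trial_index` for ordering. For stratified plans a
#'   stratum column is required: `stratum` if present, else `bin`, else
#'   `box`.
#' @param plan A [split_plan()].
#' @param n_boot Bootstrap resamples for the CI (default 500).
#' @return A two-row tibble (raw and corrected) with columns `method`,
#'   `stratified`, `corrected`, `coefficient`, `ci_low`, `ci_high`,
#'   `n_subjects`, `n_replicates`.
#' @export
split_half <- function(data, plan, n_boot = 500) {
  stopifnot(inherits(plan, "split_plan"))
  if (!all(c("subject_id", "performance") %in% names(data))) {
    abort("`data` needs `subject_id` and `performance` columns.")
  }
  if ("trial_index" %in% names(data)) {
    data <- dplyr::arrange(data, .data$subject_id, .data$trial_index)
  }
  stratum_col <- if (plan$stratify) {
    cand <- intersect(c("stratum", "bin", "box"), names(data))
    cand <- cand[vapply(cand, function(cc) !all(is.na(data[[cc]])), logical(1))]
    if (length(cand) == 0) {
      abort("Stratified splitting needs a `stratum`, `bin` or `box` column.")
    }
    cand[1]
  } else NULL
  by_subj <- split(data, data$subject_id)
  n_trials <- vapply(by_subj, nrow, integer(1))
  if (any(n_trials < 2)) abort("Every subject needs at least 2 trials.")
  n_subj <- length(by_subj)
  if (n_subj < 3) abort("Need at least 3 subjects.")

  R <- plan$n_replicates
  m1 <- matrix(NA_real_, n_subj, R)
  m2 <- matrix(NA_real_, n_subj, R)
  withr::with_seed(plan$seed, {
    for (s in seq_len(n_subj)) {
      perf <- by_subj[[s]]$performance
      strata <- if (!is.null(stratum_col)) by_subj[[s]][[stratum_col]] else NULL
      for (r in seq_len(R)) {
        sp <- if (plan$stratify) {
          split_positions_stratified(strata, plan$method)
        } else {
          split_positions(length(perf), plan$method)
        }
        m1[s, r] <- mean(perf[sp$part1])
        m2[s, r] <- mean(perf[sp$part2])
      }
    }
  })
  if (any(apply(m1, 2, sd) == 0) || any(apply(m2, 2, sd) == 0)) {
    abort("Zero variance across subjects in a split part; correlation undefined.")
  }
  r_rep <- pairwise_col_cor(m1, m2)
  coef_raw <- mean(r_rep)

  boot <- withr::with_seed(plan$seed + 1L, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n_subj, replace = TRUE)
      mean(pairwise_col_cor(m1[idx, , drop = FALSE], m2[idx, , drop = FALSE]))
    }, numeric(1))
  })
  boot <- boot[is.finite(boot)]
  ci_raw <- quantile(boot, c(0.025, 0.975), names = FALSE)
  ci_sb <- quantile(spearman_brown(boot), c(0.025, 0.975), names = FALSE)

  tibble(
    method = plan$method,
    stratified = plan$stratify,
    corrected = c(FALSE, TRUE),
    coefficient = c(coef_raw, spearman_brown(coef_raw)),
    ci_low = c(ci_raw[1], ci_sb[1]),
    ci_high = c(ci_raw[2], ci_sb[2]),
    n_subjects = n_subj,
    n_replicates = R
  )
}

#' Test-retest reliability as a Pearson correlation
#'
#' Aggregates performance per subject within each test day and correlates
#' the day-1 and day-2 scores across subjects, with a bootstrap 95% CI.
#'
#' @param data Trial-level (or already aggregated) tibble with
#'   `subject_id`, `day` (1/2) and `performance`.
#' @param n_boot Bootstrap resamples (default 500).
#' @param seed Seed for the bootstrap.
#' @return A one-row tibble with `method`, `coefficient`, `ci_low`,
#'   `ci_high`, `n_subjects`.
#' @export
test_retest_pearson <- function(data, n_boot = 500, seed = 1L) {
  stopifnot(all(c("subject_id", "day", "performance") %in% names(data)))
  wide <- data |>
    dplyr::group_by(.data$subject_id, .data$day) |>
    dplyr::summarise(score = mean(.data$performance), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "day", values_from = "score",
                       names_prefix = "day")
  if (!all(c("day1", "day2") %in% names(wide))) {
    abort("Need observations on both test days.")
  }
  wide <- wide[complete.cases(wide), ]
  n <- nrow(wide)
  if (n < 3) abort("Need at least 3 subjects with both test days.")
  if (sd(wide$day1) == 0 || sd(wide$day2) == 0) {
    abort("Zero variance in a test day; correlation undefined.")
  }
  r <- cor(wide$day1, wide$day2)
  boot <- withr::with_seed(seed, {
    vapply(seq_len(n_boot), function(b) {
      idx <- sample.int(n, replace = TRUE)
      suppressWarnings(cor(wide$day1[idx], wide$day2[idx]))
    }, numeric(1))
  })
  boot <- boot[is.finite(boot)]
  tibble(
    method = "test_retest_pearson",
    coefficient = r,
    ci_low = quantile(boot, 0.025, names = FALSE),
    ci_high = quantile(boot, 0.975, names = FALSE),
    n_subjects = n
  )
}

## lognormal outcomes: zeros are replaced by half the smallest positive
## value so the log-scale likelihood is defined
fix_lognormal_zeros <- function(y) {
  if (any(y < 0)) abort("Lognormal outcomes must be non-negative.")
  if (all(y == 0)) abort("All outcomes are zero; lognormal fit impossible.")
  if (any(y == 0)) y[y == 0] <- min(y[y > 0]) / 2
  y
}

retest_jags_model <- function(family) {
  likelihood <- if (family == "lognormal") {
    "y[i] ~ dlnorm(mu[i], prec_e)"
  } else {
    "y[i] ~ dbern(ilogit(mu[i]))"
  }
  resid <- if (family == "lognormal") {
    "sigma_e ~ dnorm(0, 0.25) T(0,)\n  prec_e <- pow(sigma_e, -2)"
  } else {
    ""
  }
  sprintf("
model {
  for (i in 1:N) {
    mu[i] <- alpha + beta_age * age[subj[i]] + b[subj[i], day[i]]
    %s
  }
  for (s in 1:S) {
    b[s, 1:2] ~ dmnorm(zero[1:2], Omega[1:2, 1:2])
  }
  Sigma[1, 1] <- sd1 * sd1
  Sigma[2, 2] <- sd2 * sd2
  Sigma[1, 2] <- rho * sd1 * sd2
  Sigma[2, 1] <- Sigma[1, 2]
  Omega <- inverse(Sigma)
  alpha ~ dnorm(0, 0.04)
  beta_age ~ dnorm(0, 0.04)
  sd1 ~ dnorm(0, 0.25) T(0,)
  sd2 ~ dnorm(0, 0.25) T(0,)
  rho ~ dunif(-1, 1)
  %s
}", likelihood, resid)
}

#' Age-corrected hierarchical test-retest reliability
#'
#' Fits trial-by-trial performance with a fixed effect of age and
#' day-specific person effects (a random slope for test day with no
#' random intercept, i.e. `performance ~ age + (0 + day | subject)`),
#' using a lognormal likelihood for imprecision outcomes or a
#' Bernoulli-logit likelihood for accuracy outcomes. The correlation
#' between the day-1 and day-2 person effects is the age-independent
#' test-retest reliability: because age is in the model, a high
#' correlation cannot arise from shared developmental level alone.
#'
#' The default backend is MCMC (JAGS) with weakly informative priors:
#' fixed effects Normal(0, 5), person-effect SDs and the residual SD
#' half-Normal(0, 2), and a uniform prior on the correlation. A fast
#' `"laplace"` backend (glmmTMB maximum likelihood, Wald intervals) is
#' available as a cross-check.
#'
#' @param data Trial-level tibble with `subject_id`, `day` (1/2),
#'   `performance`, and `age_z` (or `age_months`, z-scored internally).
#' @param family `"lognormal"` or `"bernoulli_logit"`.
#' @param backend `"mcmc"` (default) or `"laplace"`.
#' @param n_chains,n_adapt,n_burn,n_iter MCMC settings.
#' @param seed Integer seed (per-chain RNGs are derived from it).
#' @return An object of class `retest_fit`; see [tidy.retest_fit()] and
#'   [glance.retest_fit()].
#' @export
hierarchical_retest <- function(data,
                                family = c("lognormal", "bernoulli_logit"),
                                backend = c("mcmc", "laplace"),
                                n_chains = 2, n_adapt = 500,
                                n_burn = 500, n_iter = 1500,
                                seed = 1L) {
  family <- match.arg(family)
  backend <- match.arg(backend)
  stopifnot(all(c("subject_id", "day", "performance") %in% names(data)))
  if (!all(sort(unique(data$day)) == c(1, 2))) {
    abort("Need trial data from exactly two test days (day = 1, 2).")
  }
  if (!"age_z" %in% names(data)) {
    if (!"age_months" %in% names(data)) {
      abort("Need an `age_z` or `age_months` column.")
    }
    subj_ages <- dplyr::distinct(data, .data$subject_id, .data$age_months)
    s <- sd(subj_ages$age_months)
    data$age_z <- (data$age_months - mean(subj_ages$age_months)) /
      (if (is.finite(s) && s > 0) s else 1)
  }
  y <- data$performance
  if (family == "lognormal") y <- fix_lognormal_zeros(y)
  subj <- as.integer(factor(data$subject_id))
  n_subj <- max(subj)
  if (n_subj < 3) abort("Need at least 3 subjects.")
  age_by_subj <- vapply(split(data$age_z, subj), `[`, numeric(1), 1)

  if (backend == "mcmc") {
    inits <- lapply(seq_len(n_chains), function(ch) {
      list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = (seed * 113L + ch) %% 2147483647L)
    })
    jm <- rjags::jags.model(
      textConnection(retest_jags_model(family)),
      data = list(y = y, subj = subj, day = as.integer(data$day),
                  age = age_by_subj, N = length(y), S = n_subj,
                  zero = c(0, 0)),
      inits = inits, n.chains = n_chains, n.adapt = n_adapt, quiet = TRUE
    )
    update(jm, n_burn, progress.bar = "none")
    monitors <- c("alpha", "beta_age", "rho", "sd1", "sd2",
                  if (family == "lognormal") "sigma_e")
    samples <- rjags::coda.samples(jm, monitors, n.iter = n_iter,
                                   progress.bar = "none")
    draws <- as.matrix(samples)
    est <- colMeans(draws)
    qs <- apply(draws, 2, quantile, c(0.025, 0.975))
    psrf <- tryCatch(
      max(coda::gelman.diag(samples, multivariate = FALSE)$psrf[, 1]),
      error = function(e) NA_real_)
    summary_tbl <- tibble(
      term = colnames(draws),
      estimate = unname(est),
      conf.low = unname(qs[1, ]),
      conf.high = unname(qs[2, ])
    )
    correlation <- est[["rho"]]
    cri <- unname(qs[, "rho"])
    rho_draws <- draws[, "rho"]
  } else {
    d <- data
    d$y <- if (family == "lognormal") log(y) else y
    d$day_f <- factor(paste0("day", d$day))
    fam <- if (family == "lognormal") stats::gaussian() else stats::binomial()
    fit <- glmmTMB::glmmTMB(y ~ age_z + (0 + day_f | subject_id),
                            data = d, family = fam)
    vc <- glmmTMB::VarCorr(fit)$cond$subject_id
    correlation <- attr(vc, "correlation")[1, 2]
    ci <- tryCatch({
      cc <- confint(fit)
      row <- grep("Cor", rownames(cc))
      if (length(row) == 1) unname(cc[row, 1:2]) else c(NA_real_, NA_real_)
    }, error = function(e) c(NA_real_, NA_real_))
    cri <- ci
    fe <- summary(fit)$coefficients$cond
    summary_tbl <- tibble(
      term = c(rownames(fe), "rho"),
      estimate = c(fe[, 1], correlation),
      conf.low = c(fe[, 1] - 1.96 * fe[, 2], cri[1]),
      conf.high = c(fe[, 1] + 1.96 * fe[, 2], cri[2])
    )
    psrf <- NA_real_
    rho_draws <- NULL
  }

  structure(
    list(
      correlation = unname(correlation),
      ci_low = cri[1], ci_high = cri[2],
      summary = summary_tbl,
      family = family, backend = backend,
      n_subjects = n_subj, n_obs = length(y),
      psrf_max = psrf,
      rho_draws = rho_draws
    ),
    class = "retest_fit"
  )
}

#' @export
print.retest_fit <- function(x, ...) {
  cat(sprintf("<retest_fit> %s (%s backend), %d subjects, %d observations\n",
              x$family, x$backend, x$n_subjects, x$n_obs))
  cat(sprintf("  test-retest correlation: %.3f [%.3f, %.3f]\n",
              x$correlation, x$ci_low, x$ci_high))
  if (is.finite(x$psrf_max)) {
    cat(sprintf("  max split-chain PSRF: %.3f\n", x$psrf_max))
  }
  invisible(x)
}

#' Tidy a hierarchical retest fit
#'
#' @param x A `retest_fit`.
#' @param ... Unused.
#' @return A tibble with one row per parameter: `term`, `estimate`,
#'   `conf.low`, `conf.high` (posterior mean and 95% interval for the
#'   MCMC backend).
#' @method tidy retest_fit
#' @export
tidy.retest_fit <- function(x, ...) {
  x$summary
}

#' One-row summary of a hierarchical retest fit
#'
#' @param x A `retest_fit`.
#' @param ... Unused.
#' @return A one-row tibble with the retest correlation, its 95%
#'   interval, family, backend, sample sizes, and convergence
#'   diagnostic.
#' @method glance retest_fit
#' @export
glance.retest_fit <- function(x, ...) {
  tibble(
    correlation = x$correlation,
    ci_low = x$ci_low, ci_high = x$ci_high,
    family = x$family, backend = x$backend,
    n_subjects = x$n_subjects, n_obs = x$n_obs,
    psrf_max = x$psrf_max
  )
}

#' Posterior of the retest correlation
#'
#' Density of the posterior draws of the day-1/day-2 person-effect
#' correlation (MCMC backend only).
#'
#' @param object A `retest_fit` from [hierarchical_retest()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot retest_fit
#' @export
autoplot.retest_fit <- function(object, ...) {
  if (is.null(object$rho_draws)) {
    abort("Posterior draws are only available from the MCMC backend.")
  }
  df <- tibble(rho = as.numeric(object$rho_draws))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$rho)) +
    ggplot2::geom_density(fill = "steelblue", alpha = 0.4) +
    ggplot2::geom_vline(xintercept = object$correlation, linetype = 2) +
    ggplot2::labs(
      x = "test–retest correlation (person effects)",
      y = "posterior density",
      title = sprintf("Age-corrected retest reliability: %.2f [%.2f, %.2f]",
                      object$correlation, object$ci_low, object$ci_high)
    ) +
    ggplot2::theme_minimal()
}

#' Compare split-half reliability across methods
#'
#' Runs [split_half()] for every combination of splitting method and
#' stratification level and plots (or returns) the coefficients with
#' their bootstrap CIs, one panel layout mirroring a method-comparison
#' figure.
#'
#' @param data Trial-level scored data (see [split_half()]).
#' @param n_replicates Replicates for the resampling methods.
#' @param n_boot Bootstrap resamples per estimate.
#' @param seed Integer seed.
#' @return A tibble of reliability results (all methods x stratification
#'   x corrected), suitable for [plot_split_half()].
#' @export
split_half_comparison <- function(data, n_replicates = 1000,
                                  n_boot = 500, seed = 1L) {
  grid <- tidyr::expand_grid(
    method = c("first_second", "odd_even", "permutated", "monte_carlo"),
    stratify = c(FALSE, TRUE)
  )
  purrr::pmap(grid, function(method, stratify) {
    plan <- split_plan(method,
                       n_replicates =
                         if (method %in% c("permutated", "monte_carlo")) {
                           n_replicates
                         } else 1L,
                       stratify = stratify, seed = seed)
    split_half(data, plan, n_boot = n_boot)
  }) |>
    dplyr::bind_rows()
}

#' Plot a split-half comparison table
#'
#' @param results Output of [split_half_comparison()] (or row-bound
#'   [split_half()] results).
#' @param corrected Show Spearman-Brown-corrected coefficients?
#' @return A ggplot object.
#' @export
plot_split_half <- function(results, corrected = FALSE) {
  df <- dplyr::filter(results, .data$corrected == !!corrected)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$method, y = .data$coefficient,
    color = .data$stratified, group = .data$stratified
  )) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$ci_low, ymax = .data$ci_high),
      position = ggplot2::position_dodge(width = 0.4)
    ) +
    ggplot2::ylim(NA, 1) +
    ggplot2::labs(
      x = "splitting method", y = "split-half reliability",
      color = "stratified by\ntarget position",
      title = if (corrected) "Spearman–Brown corrected" else "Raw half-test"
    ) +
    ggplot2::theme_minimal()
}
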