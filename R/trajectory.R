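trajectory_jags_model <- function(family) {
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
    mu[i] <- inprod(X[i, 1:P], beta_f[1:P]) +
      b[subj[i], 1] + b[subj[i], 2] * sympos[i] + b[subj[i], 3] * trialz[i]
    %s
  }
  for (s in 1:S) {
    b[s, 1:3] ~ dmnorm(zero3[1:3], Omega[1:3, 1:3])
  }
  Omega ~ dwish(R3[1:3, 1:3], 4)
  for (k in 1:P) {
    beta_f[k] ~ dnorm(0, 0.04)
  }
  %s
}", likelihood, resid)
}

## normalize coefficient labels across backends
relabel_terms <- function(terms) {
  terms <- sub("^moderemote$", "mode_remote", terms)
  terms
}

#' Fit a developmental-trajectory mixed model
#'
#' Fits the trial-level model `performance ~ age_z + mode +
#' symmetric_position + trial_z + (1 + symmetric_position + trial_z |
#' subject_id)`: fixed effects of z-scored age, data-collection mode
#' (reference: in-person), symmetric target position (absolute distance
#' from the screen center) and z-scored trial number, with subject-level
#' random intercepts and random slopes for symmetric position and trial
#' number (unstructured covariance). Imprecision outcomes use a
#' lognormal likelihood (identity link on the log scale); accuracy
#' outcomes use Bernoulli with a logit link.
#'
#' The default backend maximizes the likelihood with `glmmTMB` (Laplace
#' approximation) and reports Wald 95% intervals; `backend = "mcmc"`
#' fits the same model in JAGS with weakly informative priors (fixed
#' effects Normal(0, 5); residual SD half-Normal(0, 2); Wishart prior,
#' 4 degrees of freedom, on the random-effect precision) and reports
#' posterior means with 95% credible intervals.
#'
#' @param data Trial-level tibble with `subject_id`, `performance`,
#'   `age_z`, `symmetric_position`, `trial_z`, and optionally `mode`
#'   (dropped from the model when absent or constant). See
#'   [add_covariates()] and [simulate_trajectory_cohort()].
#' @param family `"lognormal"` or `"bernoulli_logit"`.
#' @param backend `"laplace"` (default) or `"mcmc"`.
#' @param n_chains,n_adapt,n_burn,n_iter MCMC settings (mcmc backend).
#' @param seed Integer seed (mcmc backend).
#' @return An object of class `trajectory_fit`; see
#'   [tidy.trajectory_fit()], [glance.trajectory_fit()],
#'   [predict_trajectory()] and [autoplot.trajectory_fit()].
#' @export
fit_trajectory <- function(data,
                           family = c("lognormal", "bernoulli_logit"),
                           backend = c("laplace", "mcmc"),
                           n_chains = 2, n_adapt = 300,
                           n_burn = 300, n_iter = 700,
                           seed = 1L) {
  family <- match.arg(family)
  backend <- match.arg(backend)
  needed <- c("subject_id", "performance", "age_z",
              "symmetric_position", "trial_z")
  if (!all(needed %in% names(data))) {
    abort(paste("`data` needs columns:", paste(needed, collapse = ", ")))
  }
  n_subj <- dplyr::n_distinct(data$subject_id)
  if (n_subj < 20) {
    warning("Fewer than 20 subjects; trajectory estimates may be unstable.")
  }
  use_mode <- "mode" %in% names(data) &&
    dplyr::n_distinct(data$mode) > 1
  y <- data$performance
  if (family == "lognormal") y <- fix_lognormal_zeros(y)

  fixed_rhs <- paste(c("age_z", if (use_mode) "mode",
                       "symmetric_position", "trial_z"), collapse = " + ")

  if (backend == "laplace") {
    d <- data
    d$.y <- if (family == "lognormal") log(y) else y
    fam <- if (family == "lognormal") stats::gaussian() else stats::binomial()
    form <- stats::as.formula(paste(
      ".y ~", fixed_rhs,
      "+ (1 + symmetric_position + trial_z | subject_id)"))
    fit <- glmmTMB::glmmTMB(form, data = d, family = fam)
    fe <- summary(fit)$coefficients$cond
    summary_tbl <- tibble(
      term = relabel_terms(rownames(fe)),
      estimate = unname(fe[, 1]),
      std.error = unname(fe[, 2]),
      conf.low = unname(fe[, 1] - 1.96 * fe[, 2]),
      conf.high = unname(fe[, 1] + 1.96 * fe[, 2])
    )
    converged <- isTRUE(fit$sdr$pdHess) && fit$fit$convergence == 0
    sigma_e <- if (family == "lognormal") stats::sigma(fit) else NA_real_
    beta_draws <- NULL
    loglik <- as.numeric(stats::logLik(fit))
    model <- fit
  } else {
    X <- stats::model.matrix(stats::as.formula(paste("~", fixed_rhs)),
                             data = data)
    subj <- as.integer(factor(data$subject_id))
    inits <- lapply(seq_len(n_chains), function(ch) {
      list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = (seed * 131L + ch) %% 2147483647L)
    })
    jm <- rjags::jags.model(
      textConnection(trajectory_jags_model(family)),
      data = list(y = y, X = X, P = ncol(X), subj = subj,
                  sympos = data$symmetric_position, trialz = data$trial_z,
                  N = length(y), S = max(subj),
                  zero3 = rep(0, 3), R3 = diag(3)),
      inits = inits, n.chains = n_chains, n.adapt = n_adapt, quiet = TRUE
    )
    update(jm, n_burn, progress.bar = "none")
    monitors <- c("beta_f", if (family == "lognormal") "sigma_e")
    samples <- rjags::coda.samples(jm, monitors, n.iter = n_iter,
                                   progress.bar = "none")
    draws <- as.matrix(samples)
    beta_cols <- grep("^beta_f", colnames(draws))
    beta_draws <- draws[, beta_cols, drop = FALSE]
    colnames(beta_draws) <- relabel_terms(colnames(X))
    est <- colMeans(beta_draws)
    qs <- apply(beta_draws, 2, quantile, c(0.025, 0.975))
    summary_tbl <- tibble(
      term = names(est),
      estimate = unname(est),
      std.error = unname(apply(beta_draws, 2, sd)),
      conf.low = unname(qs[1, ]),
      conf.high = unname(qs[2, ])
    )
    sigma_e <- if (family == "lognormal") {
      mean(draws[, "sigma_e"])
    } else NA_real_
    converged <- tryCatch(
      max(coda::gelman.diag(samples, multivariate = FALSE)$psrf[, 1]) < 1.2,
      error = function(e) NA)
    loglik <- NA_real_
    model <- NULL
  }

  if (family == "bernoulli_logit" &&
      any(abs(summary_tbl$estimate) > 10, na.rm = TRUE)) {
    warning("Very large logit coefficients; possible separation in the data.")
  }

  structure(
    list(
      summary = summary_tbl,
      family = family, backend = backend,
      sigma = sigma_e,
      converged = converged,
      loglik = loglik,
      n_subjects = n_subj, n_obs = nrow(data),
      use_mode = use_mode,
      age_center = attr(data, "age_center"),
      age_scale = attr(data, "age_scale"),
      sympos_ref = mean(data$symmetric_position),
      model = model,
      beta_draws = beta_draws
    ),
    class = "trajectory_fit"
  )
}

#' @export
print.trajectory_fit <- function(x, ...) {
  cat(sprintf("<trajectory_fit> %s (%s backend), %d subjects, %d observations\n",
              x$family, x$backend, x$n_subjects, x$n_obs))
  print(x$summary)
  invisible(x)
}

#' Tidy a trajectory fit
#'
#' @param x A `trajectory_fit`.
#' @param ... Unused.
#' @return A tibble with one row per fixed effect: `term`, `estimate`,
#'   `std.error`, `conf.low`, `conf.high` (posterior mean and 95%
#'   credible interval for the MCMC backend; ML estimate and Wald 95%
#'   interval for the Laplace backend).
#' @method tidy trajectory_fit
#' @export
tidy.trajectory_fit <- function(x, ...) {
  x$summary
}

#' One-row summary of a trajectory fit
#'
#' @param x A `trajectory_fit`.
#' @param ... Unused.
#' @return A one-row tibble with family, backend, residual SD (lognormal
#'   scale), convergence flag, log-likelihood (Laplace backend) and
#'   sample sizes.
#' @method glance trajectory_fit
#' @export
glance.trajectory_fit <- function(x, ...) {
  tibble(
    family = x$family, backend = x$backend,
    sigma = x$sigma, converged = x$converged, logLik = x$loglik,
    n_subjects = x$n_subjects, n_obs = x$n_obs
  )
}

#' Predicted developmental trajectory
#'
#' Population-level predicted performance over an age grid at reference
#' covariate values (symmetric target position at its sample mean, mean
#' trial number, in-person mode). For the lognormal family the
#' prediction is the expected imprecision `exp(mu + sigma^2 / 2)`; for
#' the Bernoulli family it is the probability of a correct response.
#' Interval bounds propagate the 95% interval of the linear predictor
#' through the inverse link (fixed-effect uncertainty only).
#'
#' @param fit A [fit_trajectory()] result.
#' @param age_months Numeric grid of ages in months. Requires the fit to
#'   know the age transform (fits on [add_covariates()] data do); pass
#'   `age_z` instead otherwise.
#' @param age_z Alternative grid directly on the z-scored age scale.
#' @param mode `"in_person"` or `"remote"` (only if the fit includes a
#'   mode effect).
#' @return A tibble with `age_z` (and `age_months` when available),
#'   `predicted`, `conf.low`, `conf.high`.
#' @export
predict_trajectory <- function(fit, age_months = NULL, age_z = NULL,
                               mode = c("in_person", "remote")) {
  stopifnot(inherits(fit, "trajectory_fit"))
  mode <- match.arg(mode)
  if (is.null(age_z)) {
    if (is.null(age_months)) abort("Supply `age_months` or `age_z`.")
    if (is.null(fit$age_center)) {
      abort("This fit has no stored age transform; pass `age_z` instead.")
    }
    age_z <- (age_months - fit$age_center) / fit$age_scale
  }
  terms <- fit$summary$term
  X <- matrix(0, length(age_z), length(terms),
              dimnames = list(NULL, terms))
  X[, "(Intercept)"] <- 1
  X[, "age_z"] <- age_z
  X[, "symmetric_position"] <- fit$sympos_ref
  if (fit$use_mode && mode == "remote") X[, "mode_remote"] <- 1

  if (!is.null(fit$beta_draws)) {
    mu_draws <- fit$beta_draws %*% t(X)
    mu <- colMeans(mu_draws)
    lo <- apply(mu_draws, 2, quantile, 0.025)
    hi <- apply(mu_draws, 2, quantile, 0.975)
  } else {
    beta <- fit$summary$estimate
    V <- vcov(fit$model)$cond
    mu <- as.numeric(X %*% beta)
    se <- sqrt(rowSums((X %*% V) * X))
    lo <- mu - 1.96 * se
    hi <- mu + 1.96 * se
  }
  inv <- if (fit$family == "lognormal") {
    s2 <- if (is.finite(fit$sigma)) fit$sigma^2 else 0
    function(eta) exp(eta + s2 / 2)
  } else {
    plogis
  }
  out <- tibble(
    age_z = age_z,
    predicted = inv(mu),
    conf.low = inv(lo),
    conf.high = inv(hi)
  )
  if (!is.null(age_months)) out <- dplyr::mutate(out, age_months = age_months,
                                                 .before = 1)
  out
}

#' Plot a predicted developmental trajectory
#'
#' Draws the model-predicted performance over age with its 95% interval
#' ribbon; when `data` is supplied, per-subject mean performance is
#' overlaid as points.
#'
#' @param object A `trajectory_fit`.
#' @param data Optional trial-level data with `age_months` and
#'   `performance` for the overlay.
#' @param age_months Age grid for the prediction line.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot trajectory_fit
#' @export
autoplot.trajectory_fit <- function(object, data = NULL,
                                    age_months = NULL, ...) {
  if (is.null(age_months)) {
    age_months <- if (!is.null(object$age_center)) {
      seq(object$age_center - 2 * object$age_scale,
          object$age_center + 2 * object$age_scale, length.out = 50)
    } else NULL
  }
  pred <- if (!is.null(age_months)) {
    predict_trajectory(object, age_months = age_months)
  } else {
    predict_trajectory(object, age_z = seq(-2, 2, length.out = 50))
  }
  xvar <- if ("age_months" %in% names(pred)) "age_months" else "age_z"
  p <- ggplot2::ggplot(pred, ggplot2::aes(x = .data[[xvar]])) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$conf.low, ymax = .data$conf.high),
      alpha = 0.25, fill = "steelblue") +
    ggplot2::geom_line(ggplot2::aes(y = .data$predicted),
                       color = "steelblue") +
    ggplot2::labs(
      x = if (xvar == "age_months") "age (months)" else "age (z)",
      y = if (object$family == "lognormal") {
        "predicted imprecision (target widths)"
      } else {
        "predicted proportion correct"
      }
    ) +
    ggplot2::theme_minimal()
  if (!is.null(data) && all(c("age_months", "performance") %in% names(data))) {
    subj <- data |>
      dplyr::group_by(.data$subject_id) |>
      dplyr::summarise(age_months = .data$age_months[1],
                       performance = mean(.data$performance),
                       .groups = "drop")
    p <- p + ggplot2::geom_point(
      data = subj,
      ggplot2::aes(x = .data$age_months, y = .data$performance),
      alpha = 0.4, size = 1)
  }
  p
}
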