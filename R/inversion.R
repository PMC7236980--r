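#' Gaussian group prior over model parameters
#'
#' A diagonal Gaussian population distribution over a model's free parameters
#' in unconstrained fitting space (log-linked parameters are Gaussian on the
#' log scale, i.e. log-normal in natural space). Used both as the prior for
#' per-subject inversion and as the object re-estimated by the iterated
#' empirical-Bayes loop.
#'
#' @param mean named numeric vector of prior means (unconstrained space).
#' @param var named numeric vector of prior variances (> 0), same names.
#' @param iteration empirical-Bayes iteration index (0 = initial).
#' @param group_log_evidence summed subject log evidence at this iteration.
#' @return an object of class `imt_group_prior`.
#' @export
group_prior <- function(mean, var, iteration = 0L,
                        group_log_evidence = NA_real_) {
  stopifnot(length(mean) == length(var),
            identical(names(mean), names(var)))
  if (any(var <= 0)) stop("prior variances must be > 0", call. = FALSE)
  structure(list(mean = mean, var = var, iteration = as.integer(iteration),
                 group_log_evidence = group_log_evidence),
            class = "imt_group_prior")
}

#' @export
print.imt_group_prior <- function(x, ...) {
  cat("<imt_group_prior> iteration", x$iteration, "\n")
  print(data.frame(mean = x$mean, sd = sqrt(x$var)))
  invisible(x)
}

#' Default (weakly informative) group prior for a model family
#'
#' Initial prior used before the first empirical-Bayes update. Means are
#' centred on plausible values for normalized effort over a currency-scale
#' reward axis; variances are broad. When the observation-noise log-sd is
#' fitted it carries prior Normal(log 0.1, 1).
#'
#' @param model a [model_spec()].
#' @param fit_noise if `TRUE` (default), include the `log_noise_sd`
#'   auxiliary parameter.
#' @param reward_scale typical reward magnitude of the task variant (1 for
#'   dollars 0.25-2, larger for the cognitive pound ladder); translation
#'   and scale parameter priors are multiplied by it.
#' @return an `imt_group_prior`.
#' @export
default_group_prior <- function(model, fit_noise = TRUE, reward_scale = 1) {
  pm <- switch(model$family,
    linear  = c(m = 0.5 / reward_scale, c = 0),
    sigmoid = c(bias = 1 * reward_scale, sigma = log(0.3 * reward_scale)),
    weibull = c(A = log(0.8), L = log(1 / reward_scale), S = log(1))
  )
  pv <- switch(model$family,
    linear  = c(m = (1 / reward_scale)^2, c = 1),
    sigmoid = c(bias = (2 * reward_scale)^2, sigma = 1),
    weibull = c(A = 0.5, L = 1, S = 1)
  )
  if (fit_noise) {
    pm <- c(pm, log_noise_sd = log(0.1))
    pv <- c(pv, log_noise_sd = 1)
  }
  group_prior(pm, pv)
}

# Split an unconstrained parameter vector into model parameters and noise sd.
split_theta <- function(theta, model, fixed_noise_sd = NULL) {
  pars_nat <- to_natural(model, theta[model$parameter_names])
  noise_sd <- if (is.null(fixed_noise_sd)) exp(theta[["log_noise_sd"]]) else fixed_noise_sd
  list(pars = pars_nat, noise_sd = noise_sd)
}

#' Log joint density of one subject's curve under a model and group prior
#'
#' Gaussian likelihood of the curve's normalized efforts around the model
#' prediction, plus independent Gaussian priors on each unconstrained
#' parameter:
#' `sum_i log N(y_i | f(x_i; theta), sd^2) + sum_j log N(theta_j | mu_j, v_j)`.
#' The observation sd is `exp(theta["log_noise_sd"])` unless a fixed value is
#' supplied.
#'
#' @param theta named parameter vector, unconstrained space (model free
#'   parameters plus `log_noise_sd` unless `fixed_noise_sd` is given).
#' @param curve an [effort_curve()].
#' @param model a [model_spec()].
#' @param prior an `imt_group_prior` covering every entry of `theta`.
#' @param fixed_noise_sd optional fixed observation sd (then `theta` carries
#'   no `log_noise_sd` entry).
#' @return scalar log joint density.
#' @export
log_joint <- function(theta, curve, model, prior, fixed_noise_sd = NULL) {
  stopifnot_finite(theta, "theta")
  sp <- split_theta(theta, model, fixed_noise_sd)
  pred <- predict_effort(model, sp$pars, curve$reward)
  ll <- sum(stats::dnorm(curve$effort, pred, sp$noise_sd, log = TRUE))
  lp <- sum(stats::dnorm(theta, prior$mean[names(theta)],
                         sqrt(prior$var[names(theta)]), log = TRUE))
  ll + lp
}

#' Coefficient of determination of a fitted curve
#'
#' `1 - SS_res / SS_tot` in natural (normalized-effort) space.
#'
#' @param curve an [effort_curve()].
#' @param model a [model_spec()].
#' @param params named free parameters in natural space.
#' @return scalar r-squared, or `NA` (with attribute `undefined = TRUE`) when
#'   the curve's efforts have zero variance.
#' @export
compute_r_squared <- function(curve, model, params) {
  pred <- predict_effort(model, params, curve$reward)
  ss_tot <- sum((curve$effort - mean(curve$effort))^2)
  if (ss_tot == 0) {
    return(structure(NA_real_, undefined = TRUE))
  }
  1 - sum((curve$effort - pred)^2) / ss_tot
}

#' Default per-subject inversion options
#'
#' @param n_restarts number of jittered optimization starts (first start is
#'   the prior mean).
#' @param tol relative convergence tolerance passed to the optimizer.
#' @param max_iter maximum optimizer iterations per start.
#' @param fit_noise fit the observation log-sd as a free parameter.
#' @param noise_sd fixed observation sd used when `fit_noise = FALSE`.
#' @param rng_seed seed for the restart jitter.
#' @return a list of options for [invert_subject()].
#' @export
inversion_opts <- function(n_restarts = 5L, tol = 1e-8, max_iter = 500L,
                           fit_noise = TRUE, noise_sd = 0.1, rng_seed = 1L) {
  list(n_restarts = as.integer(n_restarts), tol = tol,
       max_iter = as.integer(max_iter), fit_noise = fit_noise,
       noise_sd = noise_sd, rng_seed = as.integer(rng_seed))
}

#' Invert one subject's effort curve under a model
#'
#' Maximum-a-posteriori estimation with a Laplace approximation: the
#' posterior mode of [log_joint()] is found by quasi-Newton (BFGS) search
#' from `n_restarts` jittered starts (best optimum kept, ties broken by the
#' first found); the posterior covariance is the inverse of the
#' finite-difference negative Hessian at the mode, ridge-regularized until a
#' Cholesky factorization succeeds; and the log evidence is the Laplace free
#' energy
#' `log_joint(mode) + d/2 * log(2*pi) + 1/2 * log det(cov)`.
#'
#' @param curve an [effort_curve()].
#' @param model a [model_spec()].
#' @param prior an `imt_group_prior` (see [default_group_prior()]).
#' @param opts options from [inversion_opts()].
#' @return an object of class `imt_subject_posterior`: fields `subject_id`,
#'   `condition`, `family`, `mean` (unconstrained space), `mean_natural`,
#'   `cov`, `log_evidence`, `r_squared`, `converged`, `ridge`.
#' @export
invert_subject <- function(curve, model, prior, opts = inversion_opts()) {
  if (length(curve$reward) == 0L) stop("empty curve", call. = FALSE)
  par_names <- model$parameter_names
  if (opts$fit_noise) par_names <- c(par_names, "log_noise_sd")
  missing <- setdiff(par_names, names(prior$mean))
  if (length(missing)) {
    stop("prior does not cover parameter(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  fixed_noise <- if (opts$fit_noise) NULL else opts$noise_sd
  neg_obj <- function(th) {
    names(th) <- par_names
    if (!all(is.finite(th))) return(1e10)
    # a log-link parameter can underflow to 0 during line search, in which
    # case the natural-space validators reject it; treat such points as
    # having negligible joint density rather than aborting the search
    v <- tryCatch(-log_joint(th, curve, model, prior,
                             fixed_noise_sd = fixed_noise),
                  error = function(e) 1e10)
    if (!is.finite(v)) 1e10 else v
  }

  mu0 <- prior$mean[par_names]
  sd0 <- sqrt(prior$var[par_names])
  starts <- with_seed(opts$rng_seed, {
    lapply(seq_len(opts$n_restarts), function(i) {
      if (i == 1L) mu0 else mu0 + stats::rnorm(length(mu0), 0, 0.5 * sd0)
    })
  })

  best <- NULL
  any_converged <- FALSE
  for (st in starts) {
    fit <- tryCatch(
      stats::optim(st, neg_obj, method = "BFGS",
                   control = list(maxit = opts$max_iter, reltol = opts$tol)),
      error = function(e) NULL)
    if (is.null(fit) || !all(is.finite(fit$par)) || !is.finite(fit$value) ||
        fit$value >= 1e10) next
    if (fit$convergence == 0L) any_converged <- TRUE
    if (is.null(best) || fit$value < best$value - 1e-12) best <- fit
  }
  if (is.null(best)) {
    return(structure(list(subject_id = curve$subject_id,
                          condition = curve$condition, family = model$family,
                          mean = mu0, mean_natural = to_natural(model, mu0[model$parameter_names]),
                          cov = diag(prior$var[par_names], length(par_names)),
                          log_evidence = NA_real_, r_squared = NA_real_,
                          converged = FALSE, ridge = NA_real_),
                     class = "imt_subject_posterior"))
  }

  theta_hat <- best$par
  names(theta_hat) <- par_names
  H <- tryCatch(stats::optimHess(theta_hat, neg_obj),
                error = function(e) NULL)
  if (is.null(H) || !all(is.finite(H))) {
    # fall back to the prior curvature; the fit is flagged as unconverged
    H <- diag(1 / prior$var[par_names], length(par_names))
    any_converged <- FALSE
  }
  H <- (H + t(H)) / 2
  # ridge-regularize until positive definite
  ridge <- 0
  repeat {
    ch <- tryCatch(chol(H + diag(ridge, nrow(H))), error = function(e) NULL)
    if (!is.null(ch)) break
    ridge <- if (ridge == 0) 1e-8 else ridge * 10
    if (ridge > 1e6) {
      H <- diag(1 / prior$var[par_names], length(par_names))
      ch <- chol(H)
      any_converged <- FALSE
      break
    }
  }
  cov <- chol2inv(ch)
  dimnames(cov) <- list(par_names, par_names)
  d <- length(par_names)
  logdet_H <- 2 * sum(log(diag(ch)))
  lj <- -best$value
  log_evidence <- lj + 0.5 * d * log(2 * pi) - 0.5 * logdet_H

  mean_natural <- to_natural(model, theta_hat[model$parameter_names])
  r2 <- compute_r_squared(curve, model, mean_natural)

  structure(list(subject_id = curve$subject_id, condition = curve$condition,
                 family = model$family, mean = theta_hat,
                 mean_natural = mean_natural, cov = cov,
                 log_evidence = log_evidence, r_squared = as.numeric(r2),
                 converged = any_converged,
                 ridge = ridge),
            class = "imt_subject_posterior")
}

#' @export
print.imt_subject_posterior <- function(x, ...) {
  cat("<imt_subject_posterior>", x$subject_id, "/", x$condition, "-",
      x$family, "\n  log evidence:", format(x$log_evidence, digits = 6),
      "| r2:", format(x$r_squared, digits = 3),
      "| converged:", x$converged, "\n")
  print(x$mean_natural)
  invisible(x)
}
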