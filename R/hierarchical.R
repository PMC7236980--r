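#' Re-estimate the Gaussian group prior from subject posteriors
#'
#' Moment matching of the population distribution in unconstrained space:
#' the new prior mean is the average of posterior means, and the new prior
#' variance is the between-subject (population, divide-by-n) variance of the
#' posterior means plus the average posterior variance, floored at 1e-6.
#'
#' @param posteriors list of `imt_subject_posterior` objects sharing one
#'   parameter set.
#' @param iteration iteration index recorded in the returned prior.
#' @return an `imt_group_prior`.
#' @export
update_group_prior <- function(posteriors, iteration = NA_integer_) {
  if (length(posteriors) < 2L) {
    stop("at least 2 subject posteriors are required", call. = FALSE)
  }
  par_names <- names(posteriors[[1]]$mean)
  means <- do.call(rbind, lapply(posteriors, function(p) p$mean[par_names]))
  vars <- do.call(rbind, lapply(posteriors, function(p) diag(p$cov)[par_names]))
  # failed inversions (non-finite moments) are excluded from the update
  ok <- apply(is.finite(means) & is.finite(vars), 1, all)
  if (sum(ok) < 2L) {
    stop("fewer than 2 finite subject posteriors", call. = FALSE)
  }
  means <- means[ok, , drop = FALSE]
  vars <- vars[ok, , drop = FALSE]
  mu <- colMeans(means)
  between <- colMeans(sweep(means, 2, mu)^2)  # population variance
  v <- pmax(between + colMeans(vars), 1e-6)
  names(v) <- par_names
  group_prior(mu, v, iteration = iteration,
              group_log_evidence = sum(vapply(posteriors, function(p)
                p$log_evidence, numeric(1))))
}

#' Iterated empirical-Bayes fit of one model family to a cohort
#'
#' The mixed-effects fitting loop: every curve (both motivation conditions
#' pooled) is inverted under the current group prior, the prior is
#' re-estimated from the resulting posteriors by [update_group_prior()], and
#' the cycle repeats until the summed subject log evidence improves by less
#' than `tol` nats (or `max_iter` is reached). Pooling both conditions into
#' one prior is conservative with respect to condition differences, since
#' every estimate is shrunk toward the common group mean.
#'
#' @param curves list of [effort_curve()] objects (all subjects, both
#'   conditions).
#' @param model a [model_spec()].
#' @param init initial `imt_group_prior`; defaults to
#'   [default_group_prior()].
#' @param tol convergence tolerance on the change in summed log evidence
#'   (nats).
#' @param max_iter maximum number of empirical-Bayes iterations.
#' @param opts inversion options ([inversion_opts()]); per-curve restart
#'   seeds are derived deterministically from `opts$rng_seed`.
#' @param reward_scale typical reward magnitude of the task variant, used to
#'   scale the starting prior when `init` is `NULL` (1 suits the physical
#'   dollar range; use e.g. 25 for the cognitive pound ladder).
#' @return an object of class `imt_group_fit`: `prior` (final
#'   `imt_group_prior`), `posteriors` (list, one per curve, final iteration),
#'   `trace` (data frame of iteration and summed log evidence),
#'   `n_unconverged` in the final iteration.
#' @export
fit_group <- function(curves, model, init = NULL, tol = 1e-3, max_iter = 32L,
                      opts = inversion_opts(), reward_scale = 1) {
  if (length(curves) == 0L) stop("no curves to fit", call. = FALSE)
  prior <- if (is.null(init)) {
    default_group_prior(model, fit_noise = opts$fit_noise,
                        reward_scale = reward_scale)
  } else init
  trace <- data.frame(iteration = integer(0), group_log_evidence = numeric(0))
  last_ev <- -Inf
  posteriors <- NULL
  for (it in seq_len(max_iter)) {
    posteriors <- lapply(seq_along(curves), function(i) {
      o <- opts
      o$rng_seed <- derive_seed(opts$rng_seed, it * 1000L + i)
      invert_subject(curves[[i]], model, prior, o)
    })
    ev <- vapply(posteriors, function(p) p$log_evidence, numeric(1))
    group_ev <- sum(ev[is.finite(ev)])
    trace <- rbind(trace, data.frame(iteration = it,
                                     group_log_evidence = group_ev))
    if (length(curves) >= 2L) {
      prior <- update_group_prior(posteriors, iteration = it)
    }
    # first-iteration improvement over -Inf is +Inf, so a finite tol never
    # stops before the second pass, while tol = Inf stops after one pass
    if ((group_ev - last_ev) <= tol) break
    last_ev <- group_ev
  }
  structure(list(prior = prior, posteriors = posteriors, trace = trace,
                 model = model,
                 n_unconverged = sum(!vapply(posteriors, function(p)
                   p$converged, logical(1)))),
            class = "imt_group_fit")
}

#' @export
print.imt_group_fit <- function(x, ...) {
  cat("<imt_group_fit>", x$model$family, "-", length(x$posteriors),
      "curves,", nrow(x$trace), "EB iterations\n  final group log evidence:",
      format(utils::tail(x$trace$group_log_evidence, 1), digits = 8), "\n")
  if (x$n_unconverged > 0) cat("  unconverged curves:", x$n_unconverged, "\n")
  invisible(x)
}

#' Fit several model families to the same cohort
#'
#' Runs [fit_group()] once per family (each family gets its own group prior)
#' and collects the per-curve log evidences needed for Bayesian model
#' selection.
#'
#' @param curves list of [effort_curve()] objects.
#' @param families character vector of families to fit.
#' @param tol,max_iter,opts,reward_scale passed to [fit_group()].
#' @return named list of `imt_group_fit` objects, one per family.
#' @export
fit_all_models <- function(curves, families = c("linear", "sigmoid", "weibull"),
                           tol = 1e-3, max_iter = 32L, opts = inversion_opts(),
                           reward_scale = 1) {
  fits <- lapply(families, function(fam) {
    fit_group(curves, model_spec(fam), tol = tol, max_iter = max_iter,
              opts = opts, reward_scale = reward_scale)
  })
  names(fits) <- families
  fits
}

#' Evidence matrix (subjects x models) from a set of group fits
#'
#' Extracts per-subject log evidences from the fits returned by
#' [fit_all_models()]. With `condition = NULL` each subject's evidences are
#' summed across conditions (one row per subject); otherwise only the given
#' condition's curves are used.
#'
#' @param fits named list of `imt_group_fit` objects.
#' @param condition `NULL`, `"internal"` or `"external"`.
#' @return numeric matrix, rows named by subject, columns by model family.
#' @export
evidence_matrix <- function(fits, condition = NULL) {
  stopifnot(length(fits) >= 1L)
  subj_of <- vapply(fits[[1]]$posteriors, function(p) p$subject_id, character(1))
  cond_of <- vapply(fits[[1]]$posteriors, function(p) p$condition, character(1))
  subjects <- sort(unique(subj_of))
  out <- matrix(NA_real_, length(subjects), length(fits),
                dimnames = list(subjects, names(fits)))
  for (fam in names(fits)) {
    ps <- fits[[fam]]$posteriors
    for (p in ps) {
      if (!is.null(condition) && p$condition != condition) next
      cur <- out[p$subject_id, fam]
      out[p$subject_id, fam] <- if (is.na(cur)) p$log_evidence else cur + p$log_evidence
    }
  }
  if (any(is.na(out))) stop("missing evidences for some subject/model", call. = FALSE)
  out
}

#' Tidy table of fitted parameters from a group fit
#'
#' @param fit an `imt_group_fit`.
#' @return data frame with `subject_id`, `condition`, one column per natural-
#'   space parameter, plus `log_evidence`, `r_squared`, `converged`.
#' @export
posterior_table <- function(fit) {
  do.call(rbind, lapply(fit$posteriors, function(p) {
    row <- data.frame(subject_id = p$subject_id, condition = p$condition,
                      stringsAsFactors = FALSE)
    for (nm in names(p$mean_natural)) row[[nm]] <- p$mean_natural[[nm]]
    row$log_evidence <- p$log_evidence
    row$r_squared <- p$r_squared
    row$converged <- p$converged
    row
  }))
}
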