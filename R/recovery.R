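#' Sample parameter sets from a group distribution
#'
#' Independent Gaussian draws per parameter in unconstrained space,
#' back-transformed to natural space (so log-linked parameters are
#' log-normal). The auxiliary observation-noise parameter, if present in the
#' prior, is not sampled.
#'
#' @param group an `imt_group_prior`.
#' @param n number of parameter sets.
#' @param model a [model_spec()] naming the parameters to draw.
#' @param rng_seed integer seed.
#' @return data frame of natural-space parameter sets, one row per draw.
#' @export
sample_from_group <- function(group, n, model, rng_seed = 1L) {
  stopifnot(n >= 1)
  par_names <- model$parameter_names
  draws <- with_seed(rng_seed, {
    vapply(par_names, function(nm) {
      stats::rnorm(n, group$mean[[nm]], sqrt(group$var[[nm]]))
    }, numeric(n))
  })
  draws <- matrix(draws, nrow = n, dimnames = list(NULL, par_names))
  for (nm in par_names) {
    if (model$transform[[nm]] == "log") draws[, nm] <- exp(draws[, nm])
  }
  as.data.frame(draws)
}

#' Simulation-recovery reliability analysis
#'
#' Draws `n_samples` parameter sets from the group distribution, simulates
#' task data for each (at the design's reward levels, with the design's
#' repetitions per level and Gaussian observation noise), aggregates the
#' simulated observations into a discount curve (mean per reward level, as in
#' preprocessing), re-inverts each curve under the group prior, and
#' correlates true with recovered natural-space parameter values (bivariate
#' Pearson).
#'
#' @param model a [model_spec()].
#' @param design an [default_design()] object.
#' @param group an `imt_group_prior`; both the sampling distribution of the
#'   true values and the prior for re-inversion.
#' @param n_samples number of simulated subjects (>= 3).
#' @param noise_sd observation-noise sd (normalized-effort units).
#' @param rng_seed integer master seed.
#' @param opts inversion options ([inversion_opts()]).
#' @return an object of class `imt_recovery`: `summary` (data frame with
#'   `parameter`, `pearson_r`, `n_used`), `values` (tidy data frame of
#'   `sample`, `parameter`, `true`, `recovered`), `n_failed`, `rng_seed`.
#' @export
run_recovery <- function(model, design, group, n_samples = 1000L,
                         noise_sd = 0.05, rng_seed = 1L,
                         opts = inversion_opts()) {
  stopifnot(n_samples >= 3)
  truths <- sample_from_group(group, n_samples, model,
                              rng_seed = derive_seed(rng_seed, 1L))
  rewards <- rep(design$reward_levels, each = design$reps_per_level)
  par_names <- model$parameter_names

  recovered <- matrix(NA_real_, n_samples, length(par_names),
                      dimnames = list(NULL, par_names))
  failed <- logical(n_samples)
  for (i in seq_len(n_samples)) {
    y <- simulate_observations(model, unlist(truths[i, , drop = FALSE]),
                               rewards, noise_sd,
                               rng_seed = derive_seed(rng_seed, 10L + i))
    # aggregate replicates to one point per level, as in preprocessing
    y_level <- vapply(design$reward_levels,
                      function(x) mean(y[rewards == x]), numeric(1))
    curve <- effort_curve("sim", "simulated", design$reward_levels, y_level,
                          n_raw_trials = length(rewards))
    o <- opts
    o$rng_seed <- derive_seed(rng_seed, 20L + i)
    post <- tryCatch(invert_subject(curve, model, group, o),
                     error = function(e) NULL)
    if (is.null(post) || !post$converged) {
      failed[i] <- TRUE
    } else {
      recovered[i, ] <- post$mean_natural[par_names]
    }
  }

  ok <- !failed
  summary <- data.frame(
    parameter = par_names,
    pearson_r = vapply(par_names, function(nm) {
      stats::cor(truths[ok, nm], recovered[ok, nm])
    }, numeric(1)),
    n_used = sum(ok),
    row.names = NULL
  )
  values <- do.call(rbind, lapply(par_names, function(nm) {
    data.frame(sample = seq_len(n_samples), parameter = nm,
               true = truths[[nm]], recovered = recovered[, nm],
               stringsAsFactors = FALSE)
  }))
  structure(list(summary = summary, values = values,
                 n_failed = sum(failed), rng_seed = as.integer(rng_seed)),
            class = "imt_recovery")
}

#' @export
print.imt_recovery <- function(x, ...) {
  cat("<imt_recovery>", max(x$values$sample), "samples,",
      x$n_failed, "failed inversions\n")
  print(x$summary)
  invisible(x)
}
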