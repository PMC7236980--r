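make_post <- function(mean, var) {
  # minimal posterior stub for moment-matching tests
  structure(list(subject_id = "s", condition = "internal", family = "sigmoid",
                 mean = mean, cov = diag(var, length(mean),
                                         length(mean)) |>
                   `dimnames<-`(list(names(mean), names(mean))),
                 log_evidence = 0, r_squared = 1, converged = TRUE, ridge = 0),
            class = "imt_subject_posterior")
}

test_that("group-prior moment matching follows the stated estimator", {
  # identical posteriors Normal(0, 1): prior mean 0, variance 1
  ps <- replicate(5, make_post(c(bias = 0), c(bias = 1)), simplify = FALSE)
  gp <- update_group_prior(ps)
  expect_equal(unname(gp$mean), 0)
  expect_equal(unname(gp$var), 1)
  # two point posteriors at -1, +1: population variance 1, mean 0
  ps2 <- list(make_post(c(bias = -1), c(bias = 1e-12)),
              make_post(c(bias = 1), c(bias = 1e-12)))
  gp2 <- update_group_prior(ps2)
  expect_equal(unname(gp2$mean), 0)
  expect_equal(unname(gp2$var), 1, tolerance = 1e-9)
  # duplicating a subject leaves the moments unchanged
  ps3 <- list(make_post(c(bias = 0.4), c(bias = 0.2)),
              make_post(c(bias = 1.0), c(bias = 0.3)))
  gp3 <- update_group_prior(ps3)
  gp4 <- update_group_prior(c(ps3, ps3))
  expect_equal(gp3$mean, gp4$mean)
  expect_equal(gp3$var, gp4$var)
  expect_error(update_group_prior(ps3[1]), "at least 2")
})

test_that("tol = Inf reduces the loop to independent fits under the initial prior", {
  curves <- small_cohort_curves(n = 4, rng_seed = 3)
  sig <- model_spec("sigmoid")
  init <- default_group_prior(sig)
  fit <- fit_group(curves, sig, init = init, tol = Inf,
                   opts = fast_opts(seed = 5))
  expect_equal(nrow(fit$trace), 1)
  indep <- lapply(seq_along(curves), function(i) {
    o <- fast_opts(seed = 5)
    # same derived restart seed as inside the loop
    o$rng_seed <- (5 + (1000 + i) * 10007) %% 2147483629 + 1
    invert_subject(curves[[i]], sig, init, o)
  })
  expect_equal(fit$posteriors[[1]]$mean, indep[[1]]$mean, tolerance = 1e-8)
  expect_equal(fit$posteriors[[4]]$log_evidence, indep[[4]]$log_evidence,
               tolerance = 1e-8)
})

test_that("the group mean of a synthetic cohort is recovered", {
  n <- 20
  bias_mean <- 1.0; bias_sd <- 0.2
  log_sigma_mean <- log(0.3); log_sigma_sd <- 0.25
  curves <- small_cohort_curves(n = n, bias_mean = bias_mean,
                                bias_sd = bias_sd,
                                log_sigma_mean = log_sigma_mean,
                                log_sigma_sd = log_sigma_sd,
                                noise_sd = 0.03, rng_seed = 7)
  fit <- fit_group(curves, model_spec("sigmoid"), opts = fast_opts(seed = 2))
  # against the realized sample means of the drawn cohort (the quantity the
  # moment-matching estimator targets), and within 3 SE of the population
  set.seed(7)
  biases <- rnorm(n, bias_mean, bias_sd)
  log_sigmas <- rnorm(n, log_sigma_mean, log_sigma_sd)
  expect_lt(abs(fit$prior$mean[["bias"]] - mean(biases)), 0.05)
  expect_lt(abs(fit$prior$mean[["sigma"]] - mean(log_sigmas)), 0.08)
  expect_lt(abs(fit$prior$mean[["bias"]] - bias_mean),
            3 * bias_sd / sqrt(n))
  expect_lt(abs(fit$prior$mean[["sigma"]] - log_sigma_mean),
            3 * log_sigma_sd / sqrt(n))
})

test_that("the group-evidence trace improves until the stopping step", {
  # the loop stops at the first pass that fails to improve the summed
  # evidence, so every step but the last must gain more than the tolerance,
  # and any terminal decrease is bounded
  for (seed in 1:4) {
    curves <- small_cohort_curves(n = 8, rng_seed = seed)
    fit <- fit_group(curves, model_spec("sigmoid"), opts = fast_opts(seed = 1))
    steps <- diff(fit$trace$group_log_evidence)
    if (length(steps) > 1) {
      gains <- head(steps, -1)
      expect_true(all(gains > 1e-3), info = paste("seed", seed))
      # a terminal decrease must be negligible next to the accumulated gain
      expect_gt(tail(steps, 1), -0.05 * max(sum(gains), 1))
    }
  }
})

test_that("empirical-Bayes estimates shrink toward the group mean", {
  curves <- small_cohort_curves(n = 10, rng_seed = 11, noise_sd = 0.05)
  sig <- model_spec("sigmoid")
  init <- default_group_prior(sig)
  # independent fits under a broad fixed prior
  broad <- group_prior(init$mean,
                       c(bias = 25, sigma = 25, log_noise_sd = 1))
  indep <- vapply(curves, function(cu)
    invert_subject(cu, sig, broad, fast_opts(seed = 3))$mean[["bias"]],
    numeric(1))
  fit <- fit_group(curves, sig, opts = fast_opts(seed = 3))
  eb <- vapply(fit$posteriors, function(p) p$mean[["bias"]], numeric(1))
  gmean <- fit$prior$mean[["bias"]]
  # elementwise: EB estimate lies between the independent fit and the group
  # mean (small numerical slack)
  between <- (eb - indep) * (gmean - indep) >= -1e-6 &
    abs(eb - gmean) <= abs(indep - gmean) + 1e-6
  expect_true(mean(between) >= 0.9)
  # and the spread of EB estimates is no larger than the independent spread
  expect_lte(stats::sd(eb), stats::sd(indep) + 1e-9)
})

test_that("condition contrasts of EB estimates are conservative relative to independent fits", {
  # two-condition cohort with a true bias difference
  design <- default_design("physical")
  sig <- model_spec("sigmoid")
  set.seed(31)
  n <- 8
  curves <- list()
  for (i in seq_len(n)) {
    for (cond in c("external", "internal")) {
      b <- rnorm(1, if (cond == "internal") 1.15 else 0.90, 0.25)
      s <- exp(rnorm(1, log(0.3), 0.25))
      y <- simulate_observations(sig, c(bias = b, sigma = s),
                                 design$reward_levels, 0.05,
                                 rng_seed = 31 * 100 + i * 2 +
                                   (cond == "internal"))
      curves[[length(curves) + 1]] <-
        effort_curve(sprintf("S%02d", i), cond, design$reward_levels, y)
    }
  }
  broad <- group_prior(default_group_prior(sig)$mean,
                       c(bias = 25, sigma = 25, log_noise_sd = 1))
  bias_of <- function(posts) {
    vapply(posts, function(p) p$mean_natural[["bias"]], numeric(1))
  }
  conds <- vapply(curves, function(cu) cu$condition, character(1))
  indep <- vapply(curves, function(cu)
    invert_subject(cu, sig, broad, fast_opts(seed = 4))$mean_natural[["bias"]],
    numeric(1))
  fit <- fit_group(curves, sig, opts = fast_opts(seed = 4))
  eb <- bias_of(fit$posteriors)
  d_indep <- mean(indep[conds == "internal"]) - mean(indep[conds == "external"])
  d_eb <- mean(eb[conds == "internal"]) - mean(eb[conds == "external"])
  expect_lte(abs(d_eb), abs(d_indep) + 1e-6)
})

test_that("the cognitive variant fits on its own reward scale", {
  design <- default_design("cognitive")
  spec <- default_cohort_spec("cognitive", rng_seed = 12)
  spec$n_subjects <- 6L
  coh <- generate_cohort(design, spec)
  curves <- build_cohort_curves(coh$trials, design)
  fit <- fit_group(curves, model_spec("sigmoid"), reward_scale = 25,
                   opts = fast_opts(seed = 3))
  pt <- posterior_table(fit)
  truth <- merge(pt, coh$true_params, by = c("subject_id", "condition"),
                 suffixes = c("_hat", "_true"))
  # bias recovered in pounds on the 1-200 ladder
  expect_gt(cor(truth$bias_hat, truth$bias_true), 0.9)
  expect_lt(mean(abs(truth$bias_hat - truth$bias_true)), 10)
})

test_that("evidence_matrix sums conditions and splits them correctly", {
  curves <- c(small_cohort_curves(n = 3, rng_seed = 2),
              lapply(small_cohort_curves(n = 3, rng_seed = 5), function(cu) {
                cu$condition <- "external"; cu
              }))
  fits <- fit_all_models(curves, families = c("linear", "sigmoid"),
                         max_iter = 2L, opts = fast_opts())
  le_all <- evidence_matrix(fits)
  le_int <- evidence_matrix(fits, "internal")
  le_ext <- evidence_matrix(fits, "external")
  expect_equal(dim(le_all), c(3, 2))
  expect_equal(le_all, le_int + le_ext, tolerance = 1e-12)
})
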