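# Shared fixtures: small synthetic curves and fast inversion settings.

fast_opts <- function(seed = 1L, fit_noise = TRUE, noise_sd = 0.05) {
  inversion_opts(n_restarts = 2L, fit_noise = fit_noise, noise_sd = noise_sd,
                 rng_seed = seed)
}

# A noise-free sigmoid curve at the physical reward levels.
sigmoid_curve <- function(bias = 1.0, sigma = 0.3, noise_sd = 0,
                          rng_seed = 1L, subject = "S01",
                          condition = "internal") {
  design <- default_design("physical")
  y <- simulate_observations(model_spec("sigmoid"),
                             c(bias = bias, sigma = sigma),
                             design$reward_levels, noise_sd, rng_seed)
  effort_curve(subject, condition, design$reward_levels, y)
}

# A small cohort of sigmoid curves (one condition) with subject-level
# parameter variation, for hierarchical-fit tests.
small_cohort_curves <- function(n = 8, bias_mean = 1.0, bias_sd = 0.2,
                                log_sigma_mean = log(0.3), log_sigma_sd = 0.25,
                                noise_sd = 0.03, rng_seed = 1L) {
  design <- default_design("physical")
  sig <- model_spec("sigmoid")
  set.seed(rng_seed)
  biases <- rnorm(n, bias_mean, bias_sd)
  sigmas <- exp(rnorm(n, log_sigma_mean, log_sigma_sd))
  lapply(seq_len(n), function(i) {
    y <- simulate_observations(sig, c(bias = biases[i], sigma = sigmas[i]),
                               design$reward_levels, noise_sd,
                               rng_seed = rng_seed * 1000L + i)
    effort_curve(sprintf("S%02d", i), "internal", design$reward_levels, y)
  })
}

# Brute-force log evidence by 2-D trapezoid quadrature for a 2-free-parameter
# sigmoid problem with fixed observation noise. Integrates exp(log_joint)
# over [mean +/- half_width * sd] per dimension.
quadrature_log_evidence <- function(curve, prior, noise_sd,
                                    n_grid = 201, half_width = 4) {
  model <- model_spec("sigmoid")
  g1 <- seq(prior$mean[["bias"]] - half_width * sqrt(prior$var[["bias"]]),
            prior$mean[["bias"]] + half_width * sqrt(prior$var[["bias"]]),
            length.out = n_grid)
  g2 <- seq(prior$mean[["sigma"]] - half_width * sqrt(prior$var[["sigma"]]),
            prior$mean[["sigma"]] + half_width * sqrt(prior$var[["sigma"]]),
            length.out = n_grid)
  lj <- outer(seq_along(g1), seq_along(g2), Vectorize(function(i, j) {
    log_joint(c(bias = g1[i], sigma = g2[j]), curve, model, prior,
              fixed_noise_sd = noise_sd)
  }))
  # trapezoid weights
  w1 <- rep(1, n_grid); w1[c(1, n_grid)] <- 0.5
  w2 <- rep(1, n_grid); w2[c(1, n_grid)] <- 0.5
  m <- max(lj)
  h1 <- diff(g1[1:2]); h2 <- diff(g2[1:2])
  m + log(sum(exp(lj - m) * outer(w1, w2))) + log(h1) + log(h2)
}
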