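test_that("default designs match the task structure", {
  d <- default_design("physical")
  expect_equal(length(d$reward_levels), 8)
  expect_equal(range(d$reward_levels), c(0.25, 2.00))
  expect_equal(d$max_effort, 70)
  expect_equal(d$reps_per_level, 8L)
  # 2 conditions x 8 levels x 8 reps = 128 trials
  expect_equal(2 * length(d$reward_levels) * d$reps_per_level, 128)
  expect_true(all(d$effort_offer_levels >= 3 & d$effort_offer_levels <= 70))
  expect_equal(d$work_probability, 0.30)

  dc <- default_design("cognitive")
  expect_equal(max(dc$reward_levels), 200)  # > 200-pound levels excluded
  expect_equal(dc$max_effort, 200)
  expect_equal(dc$reps_per_level, 1L)
  expect_error(default_design("emotional"))
})

test_that("generated cohorts have the right bookkeeping and are seed-reproducible", {
  design <- default_design("physical")
  spec <- default_cohort_spec("physical", rng_seed = 5)
  coh <- generate_cohort(design, spec)
  expect_equal(nrow(coh$trials), 26 * 128)
  expect_equal(length(unique(coh$trials$subject_id)), 26)
  expect_equal(nrow(coh$true_params), 26 * 2)
  expect_equal(nrow(coh$questionnaire), 26)
  # per subject x condition trial counts match the design
  counts <- table(coh$trials$subject_id, coh$trials$condition)
  expect_true(all(counts == 64))
  # reward level sets match
  expect_equal(sort(unique(coh$trials$reward)), design$reward_levels)
  # external trials carry offers and binary responses; internal carry efforts
  ext <- coh$trials[coh$trials$condition == "external", ]
  int <- coh$trials[coh$trials$condition == "internal", ]
  expect_true(all(ext$offered_effort %in% design$effort_offer_levels))
  expect_true(all(ext$response %in% c(0, 1)))
  expect_true(all(is.na(int$offered_effort)))
  expect_true(all(int$response >= 0 & int$response <= design$max_effort))
  # work flags only on accepted/indicated trials, at ~the design probability
  expect_true(all(!ext$work_flag[ext$response == 0]))
  accepted <- sum(ext$response == 1) + nrow(int)
  frac <- sum(coh$trials$work_flag) / accepted
  expect_lt(abs(frac - design$work_probability),
            4 * sqrt(0.3 * 0.7 / accepted))
  # byte-identical regeneration under the same seed
  coh2 <- generate_cohort(design, spec)
  expect_identical(coh, coh2)
  # different seed gives different draws
  coh3 <- generate_cohort(design, default_cohort_spec("physical", rng_seed = 6))
  expect_false(identical(coh$trials$response, coh3$trials$response))
})

test_that("degenerate generator (zero SDs, zero noise, tiny tau) reproduces the group sigmoid", {
  design <- default_design("physical")
  spec <- default_cohort_spec("physical", rng_seed = 2)
  spec$bias_sd[] <- 0
  spec$log_sigma_sd[] <- 0
  spec$noise_sd <- 0
  spec$tau <- 1e-9
  coh <- generate_cohort(design, spec)
  curves <- build_cohort_curves(coh$trials, design)
  sig <- model_spec("sigmoid")
  for (cu in curves) {
    cond <- cu$condition
    truth <- predict_effort(sig, c(bias = spec$bias_mean[[cond]],
                                   sigma = exp(spec$log_sigma_mean[[cond]])),
                            cu$reward)
    if (cond == "internal") {
      expect_equal(cu$effort, truth, tolerance = 1e-9)
    } else {
      # external curves are quantized to the offer grid: the max accepted
      # offer is the largest offer below the latent threshold
      latent <- design$max_effort * truth
      expected <- vapply(latent, function(l) {
        ok <- design$effort_offer_levels[design$effort_offer_levels < l]
        if (length(ok) == 0) 0 else max(ok) / design$max_effort
      }, numeric(1))
      expect_equal(cu$effort, expected, tolerance = 1e-9)
    }
  }
})

test_that("external acceptance probability is monotone in offer and reward", {
  # direct check of the generator's choice rule on a grid
  design <- default_design("physical")
  spec <- default_cohort_spec("physical")
  sig <- model_spec("sigmoid")
  rewards <- seq(0.25, 2, length.out = 12)
  offers <- seq(3, 70, length.out = 12)
  pars <- c(bias = 1.0, sigma = 0.3)
  latent <- design$max_effort * predict_effort(sig, pars, rewards)
  p <- outer(latent, offers, function(l, e) plogis((l - e) / spec$tau))
  expect_true(all(diff(t(p)) <= 0))  # nonincreasing in offered effort
  expect_true(all(diff(p) >= 0))     # nondecreasing in reward
})

test_that("true bias marginal matches the specified Gaussian (KS)", {
  design <- default_design("physical")
  spec <- default_cohort_spec("physical", rng_seed = 9)
  spec$n_subjects <- 1500L
  # use a 1-rep design to keep the trial table small; the true-parameter
  # draws are what is under test
  design$reps_per_level <- 1L
  coh <- generate_cohort(design, spec)
  b <- coh$true_params$bias[coh$true_params$condition == "internal"]
  ks <- suppressWarnings(
    ks.test(b, "pnorm", spec$bias_mean[["internal"]],
            spec$bias_sd[["internal"]]))
  expect_gt(ks$p.value, 0.01)
  ls <- log(coh$true_params$sigma[coh$true_params$condition == "external"])
  ks2 <- suppressWarnings(
    ks.test(ls, "pnorm", spec$log_sigma_mean[["external"]],
            spec$log_sigma_sd[["external"]]))
  expect_gt(ks2$p.value, 0.01)
})

test_that("the null switch equalizes condition means and the default spec orders them", {
  spec <- default_cohort_spec("physical")
  expect_gt(spec$bias_mean[["internal"]], spec$bias_mean[["external"]])
  expect_gt(spec$log_sigma_mean[["internal"]], spec$log_sigma_mean[["external"]])
  null_spec <- default_cohort_spec("physical", null_effect = TRUE)
  expect_equal(null_spec$bias_mean[["internal"]], null_spec$bias_mean[["external"]])
  expect_equal(null_spec$log_sigma_mean[["internal"]],
               null_spec$log_sigma_mean[["external"]])
})

test_that("cohort CSVs round-trip through write_cohort/read_trials", {
  design <- default_design("physical")
  spec <- default_cohort_spec("physical", rng_seed = 3)
  spec$n_subjects <- 3L
  coh <- generate_cohort(design, spec)
  dir <- withr::local_tempdir()
  write_cohort(coh, design, spec, dir)
  trials <- read_trials(file.path(dir, "trials.csv"))
  expect_equal(nrow(trials), nrow(coh$trials))
  expect_equal(trials$response, coh$trials$response, tolerance = 1e-12)
  # schema validation names the missing column
  bad <- coh$trials[, setdiff(names(coh$trials), "condition")]
  badpath <- file.path(dir, "bad.csv")
  utils::write.csv(bad, badpath, row.names = FALSE)
  expect_error(read_trials(badpath), "condition")
})
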