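#' Default task design for an IMT variant
#'
#' Structural constants of one Internal-External Motivation Task variant.
#' The physical variant offers monetary rewards from $0.25 to $2.00 for a
#' button-pressing task requiring between 3 and 70 presses, over 128 trials
#' (2 conditions x 8 reward levels x 8 repetitions); 30% of accepted trials
#' lead to actually performing the work. The cognitive variant offers
#' 1, 2, 5, ..., 200 pounds for minutes (1-200) of a serial-threes counting
#' task, one internal indication per reward level; reward magnitudes above
#' 200 pounds are excluded from analysis because the internal condition had
#' no upper response bound there. In the external condition of either
#' variant, every reward level is probed with the full offer grid
#' (`effort_offer_levels`); `reps_per_level` counts the internal-condition
#' repetitions per reward level.
#'
#' @param variant `"physical"` or `"cognitive"`.
#' @return an object of class `imt_design` with fields `variant`,
#'   `reward_levels`, `max_effort`, `effort_offer_levels`, `reps_per_level`,
#'   `work_probability`.
#' @export
default_design <- function(variant = c("physical", "cognitive")) {
  variant <- match.arg(variant)
  design <- if (variant == "physical") {
    list(
      variant = "physical",
      reward_levels = seq(0.25, 2.00, by = 0.25),
      max_effort = 70,
      # 8 evenly spaced offers spanning the 3-70 press range, rounded to
      # whole button presses
      effort_offer_levels = round(seq(3, 70, length.out = 8)),
      reps_per_level = 8L,
      work_probability = 0.30
    )
  } else {
    list(
      variant = "cognitive",
      # 1-2-5 ladder capped at the 200-pound analysis cutoff
      reward_levels = c(1, 2, 5, 10, 20, 50, 100, 200),
      max_effort = 200,
      effort_offer_levels = round(seq(1, 200, length.out = 8)),
      reps_per_level = 1L,
      work_probability = 0.30
    )
  }
  class(design) <- "imt_design"
  design
}

#' @export
print.imt_design <- function(x, ...) {
  cat("<imt_design>", x$variant, "\n",
      " reward levels:", paste(x$reward_levels, collapse = ", "), "\n",
      " max effort:", x$max_effort,
      "| reps/level:", x$reps_per_level,
      "| work probability:", x$work_probability, "\n")
  invisible(x)
}

#' Default synthetic-cohort specification
#'
#' Generative assumptions for a synthetic IMT cohort: per-condition Gaussian
#' population distributions of the sigmoid bias (currency units) and
#' log-sigma (log currency units), observation noise on indicated effort,
#' the softness of the accept/reject choice rule in the external condition,
#' and a linear loading of anticipatory-pleasure scores on internal-condition
#' bias so questionnaire correlations have a recoverable ground truth.
#'
#' Physical defaults place the internal condition at higher bias (\$1.15 vs
#' \$0.90) and higher sigma (0.35 vs 0.25) than the external condition — the
#' direction of the reported condition effects (reduced self-generated effort
#' initiation and acceleration). `null_effect = TRUE` equalizes the condition
#' means, giving a no-effect generator for calibration checks.
#'
#' @param variant `"physical"` or `"cognitive"`.
#' @param null_effect if `TRUE`, internal-condition means are set equal to the
#'   external ones (zero condition effect).
#' @param rng_seed integer seed stored in the spec.
#' @return an object of class `imt_cohort_spec`.
#' @export
default_cohort_spec <- function(variant = c("physical", "cognitive"),
                                null_effect = FALSE, rng_seed = 1L) {
  variant <- match.arg(variant)
  spec <- if (variant == "physical") {
    list(
      variant = "physical",
      n_subjects = 26L,
      bias_mean = c(external = 0.90, internal = 1.15),
      bias_sd = c(external = 0.25, internal = 0.25),
      log_sigma_mean = c(external = log(0.25), internal = log(0.35)),
      log_sigma_sd = c(external = 0.30, internal = 0.30),
      noise_sd = 0.05,
      tau = 5,                     # presses; choice softness
      teps_ant_intercept = 60,
      teps_ant_loading = -15,      # points per $ of internal bias
      teps_ant_resid_sd = 4,
      teps_con_mean = 40, teps_con_sd = 6,
      bdi_mean = 6, bdi_sd = 5,
      rng_seed = as.integer(rng_seed)
    )
  } else {
    list(
      variant = "cognitive",
      n_subjects = 28L,
      bias_mean = c(external = 25, internal = 40),
      bias_sd = c(external = 12, internal = 12),
      # no sigma condition effect in the cognitive domain
      log_sigma_mean = c(external = log(12), internal = log(12)),
      log_sigma_sd = c(external = 0.30, internal = 0.30),
      noise_sd = 0.05,
      tau = 15,                    # minutes; choice softness
      teps_ant_intercept = 60,
      teps_ant_loading = -0.4,     # points per pound of internal bias
      teps_ant_resid_sd = 4,
      teps_con_mean = 40, teps_con_sd = 6,
      bdi_mean = 9.8, bdi_sd = 10.2,
      rng_seed = as.integer(rng_seed)
    )
  }
  if (null_effect) {
    spec$bias_mean["internal"] <- spec$bias_mean[["external"]]
    spec$log_sigma_mean["internal"] <- spec$log_sigma_mean[["external"]]
  }
  class(spec) <- "imt_cohort_spec"
  spec
}

#' Generate a synthetic IMT cohort
#'
#' Draws per-subject, per-condition true sigmoid parameters from the
#' specification's Gaussian population distributions (log-normal for sigma),
#' then simulates trial-level behavior:
#'
#' * **internal** condition: the indicated effort at reward `x` is
#'   `clip(max_effort * sigmoid(x) + Normal(0, noise_sd * max_effort), 0,
#'   max_effort)`;
#' * **external** condition: the probability of accepting an offered effort
#'   `e` at reward `x` is `logistic((max_effort * sigmoid(x) - e) / tau)` —
#'   a softmax choice rule around the latent effort threshold.
#'
#' A `work_probability` fraction of accepted/indicated trials is flagged as
#' leading to actual work. Questionnaire scores are generated with a linear
#' loading of TEPS-anticipatory on internal-condition bias plus Gaussian
#' residual; TEPS-consummatory and BDI are independent noise.
#'
#' @param design an [default_design()] object.
#' @param spec an [default_cohort_spec()] object.
#' @return a list with components `trials` (long-format data frame:
#'   `subject_id`, `condition`, `reward`, `offered_effort`, `response`,
#'   `work_flag`), `true_params` (`subject_id`, `condition`, `bias`, `sigma`),
#'   and `questionnaire` (`subject_id`, `teps_anticipatory`,
#'   `teps_consummatory`, `bdi`). All draws are reproducible under
#'   `spec$rng_seed`.
#' @export
generate_cohort <- function(design, spec) {
  stopifnot(inherits(design, "imt_design"), inherits(spec, "imt_cohort_spec"))
  with_seed(spec$rng_seed, {
    n <- spec$n_subjects
    conditions <- c("external", "internal")
    sig <- model_spec("sigmoid")

    true_params <- do.call(rbind, lapply(seq_len(n), function(s) {
      data.frame(
        subject_id = sprintf("S%02d", s),
        condition = conditions,
        bias = stats::rnorm(2, spec$bias_mean[conditions], spec$bias_sd[conditions]),
        sigma = exp(stats::rnorm(2, spec$log_sigma_mean[conditions],
                                 spec$log_sigma_sd[conditions])),
        stringsAsFactors = FALSE
      )
    }))

    trial_rows <- vector("list", n * 2L)
    k <- 0L
    for (s in seq_len(n)) {
      sid <- sprintf("S%02d", s)
      for (cond in conditions) {
        tp <- true_params[true_params$subject_id == sid &
                          true_params$condition == cond, ]
        pars <- c(bias = tp$bias, sigma = tp$sigma)
        if (cond == "internal") {
          rewards <- rep(design$reward_levels, each = design$reps_per_level)
          latent <- design$max_effort * predict_effort(sig, pars, rewards)
          indicated <- clip(
            latent + stats::rnorm(length(rewards), 0,
                                  spec$noise_sd * design$max_effort),
            0, design$max_effort)
          offered <- rep(NA_real_, length(rewards))
          response <- indicated
          accepted <- rep(TRUE, length(rewards))
        } else {
          # every reward level is probed with the full offer grid (accept/
          # reject per offered effort, as in the task's external condition)
          rewards <- rep(design$reward_levels,
                         each = length(design$effort_offer_levels))
          offered <- rep(design$effort_offer_levels,
                         times = length(design$reward_levels))
          latent <- design$max_effort * predict_effort(sig, pars, rewards)
          p_accept <- stats::plogis((latent - offered) / spec$tau)
          accepted <- stats::runif(length(rewards)) < p_accept
          response <- as.numeric(accepted)
        }
        work_flag <- accepted & (stats::runif(length(rewards)) < design$work_probability)
        k <- k + 1L
        trial_rows[[k]] <- data.frame(
          subject_id = sid, condition = cond, reward = rewards,
          offered_effort = offered, response = response,
          work_flag = work_flag, stringsAsFactors = FALSE
        )
      }
    }
    trials <- do.call(rbind, trial_rows)
    rownames(trials) <- NULL
    rownames(true_params) <- NULL

    internal_bias <- true_params$bias[true_params$condition == "internal"]
    questionnaire <- data.frame(
      subject_id = sprintf("S%02d", seq_len(n)),
      teps_anticipatory = spec$teps_ant_intercept +
        spec$teps_ant_loading * internal_bias +
        stats::rnorm(n, 0, spec$teps_ant_resid_sd),
      teps_consummatory = stats::rnorm(n, spec$teps_con_mean, spec$teps_con_sd),
      bdi = pmax(0, round(stats::rnorm(n, spec$bdi_mean, spec$bdi_sd))),
      stringsAsFactors = FALSE
    )

    list(trials = trials, true_params = true_params,
         questionnaire = questionnaire)
  })
}

#' Write a synthetic cohort to CSV files
#'
#' Writes `trials.csv`, `true_params.csv` and `questionnaire.csv` (comma
#' separated, UTF-8, headered, '.' decimal) plus a `manifest.json` recording
#' the design, specification and seed.
#'
#' @param cohort output of [generate_cohort()].
#' @param design,spec the design and cohort specification used.
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, design, spec, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, c("trials.csv", "true_params.csv",
                            "questionnaire.csv", "manifest.json"))
  utils::write.csv(cohort$trials, paths[1], row.names = FALSE)
  utils::write.csv(cohort$true_params, paths[2], row.names = FALSE)
  utils::write.csv(cohort$questionnaire, paths[3], row.names = FALSE)
  manifest <- list(design = unclass(design), cohort_spec = unclass(spec))
  jsonlite::write_json(manifest, paths[4], auto_unbox = TRUE, digits = NA)
  invisible(paths)
}

#' Read a trial table written by [write_cohort()]
#'
#' Validates the CSV dialect (required columns by name) and returns the
#' long-format trial data frame.
#'
#' @param path path to `trials.csv`.
#' @return trial data frame.
#' @export
read_trials <- function(path) {
  trials <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("subject_id", "condition", "reward", "offered_effort",
                "response", "work_flag")
  missing <- setdiff(required, names(trials))
  if (length(missing)) {
    stop("trial table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  trials
}
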