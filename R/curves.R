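#' Effort-by-reward discount curve for one subject and condition
#'
#' The unit of model fitting: one point per retained reward level, with
#' effort normalized to the fraction of the variant's maximum effort.
#'
#' @param subject_id subject identifier.
#' @param condition `"internal"` or `"external"`.
#' @param reward strictly increasing vector of reward levels.
#' @param effort normalized efforts in \[0, 1\], same length as `reward`.
#' @param n_raw_trials number of raw trials the curve was built from.
#' @return an object of class `effort_curve`.
#' @export
effort_curve <- function(subject_id, condition, reward, effort,
                         n_raw_trials = length(reward)) {
  if (length(reward) == 0L) stop("empty curve: no reward levels", call. = FALSE)
  if (length(reward) != length(effort)) {
    stop("reward and effort must have the same length", call. = FALSE)
  }
  if (is.unsorted(reward, strictly = TRUE)) {
    stop("reward levels must be strictly increasing", call. = FALSE)
  }
  if (any(effort < 0 | effort > 1)) {
    stop("efforts must lie in [0, 1]", call. = FALSE)
  }
  structure(list(subject_id = subject_id, condition = condition,
                 reward = as.numeric(reward), effort = as.numeric(effort),
                 n_raw_trials = as.integer(n_raw_trials)),
            class = "effort_curve")
}

#' @export
print.effort_curve <- function(x, ...) {
  cat("<effort_curve>", x$subject_id, "/", x$condition, "-",
      length(x$reward), "points from", x$n_raw_trials, "trials\n")
  invisible(x)
}

#' Build the external-condition discount curve for one subject
#'
#' Per reward level, effort is the maximum offered effort among accepted
#' trials, normalized by the design's maximum effort. Levels at which no
#' offer was accepted map to effort 0 (unwilling to initiate).
#'
#' @param trials trial rows for one subject, all external condition.
#' @param design the [default_design()] used.
#' @return an [effort_curve()].
#' @export
build_external_curve <- function(trials, design) {
  if (nrow(trials) == 0L) stop("empty curve: no external trials", call. = FALSE)
  stopifnot(all(trials$condition == "external"),
            length(unique(trials$subject_id)) == 1L)
  levels <- sort(unique(trials$reward))
  effort <- vapply(levels, function(x) {
    rows <- trials[trials$reward == x & trials$response > 0, ]
    if (nrow(rows) == 0L) 0 else max(rows$offered_effort) / design$max_effort
  }, numeric(1))
  effort_curve(trials$subject_id[1], "external", levels, effort,
               n_raw_trials = nrow(trials))
}

#' Build the internal-condition discount curve for one subject
#'
#' Per reward level, effort is the mean of the indicated efforts at that
#' level, normalized by the design's maximum effort. The mean (rather than
#' the maximum) is used across repeated presentations so that observation
#' noise is averaged out rather than conflated with motivation.
#'
#' @param trials trial rows for one subject, all internal condition.
#' @param design the [default_design()] used.
#' @return an [effort_curve()].
#' @export
build_internal_curve <- function(trials, design) {
  if (nrow(trials) == 0L) stop("empty curve: no internal trials", call. = FALSE)
  stopifnot(all(trials$condition == "internal"),
            length(unique(trials$subject_id)) == 1L)
  levels <- sort(unique(trials$reward))
  effort <- vapply(levels, function(x) {
    mean(trials$response[trials$reward == x]) / design$max_effort
  }, numeric(1))
  effort_curve(trials$subject_id[1], "internal", levels, effort,
               n_raw_trials = nrow(trials))
}

#' Apply the cognitive-variant reward cap
#'
#' Drops all curve points with reward above the cap. In the cognitive task
#' the internal condition had no upper response bound, so reward magnitudes
#' above 200 pounds are excluded to allow direct comparison between
#' conditions.
#'
#' @param curve an [effort_curve()].
#' @param cap maximum retained reward (default 200).
#' @return the filtered [effort_curve()]; an error if no points remain.
#' @export
apply_cognitive_exclusion <- function(curve, cap = 200) {
  keep <- curve$reward <= cap
  effort_curve(curve$subject_id, curve$condition,
               curve$reward[keep], curve$effort[keep],
               n_raw_trials = curve$n_raw_trials)
}

#' Build discount curves for every subject and condition in a trial table
#'
#' Splits the long-format trial table by subject and condition and applies
#' [build_external_curve()] / [build_internal_curve()]; for the cognitive
#' variant the reward cap is applied to every curve.
#'
#' @param trials long-format trial data frame (see [generate_cohort()]).
#' @param design the [default_design()] used.
#' @return a list of [effort_curve()] objects, ordered by subject then
#'   condition (external, internal).
#' @export
build_cohort_curves <- function(trials, design) {
  subjects <- sort(unique(trials$subject_id))
  curves <- list()
  for (sid in subjects) {
    for (cond in c("external", "internal")) {
      sub <- trials[trials$subject_id == sid & trials$condition == cond, ]
      if (nrow(sub) == 0L) next
      curve <- if (cond == "external") {
        build_external_curve(sub, design)
      } else {
        build_internal_curve(sub, design)
      }
      if (design$variant == "cognitive") {
        curve <- apply_cognitive_exclusion(curve)
      }
      curves[[length(curves) + 1L]] <- curve
    }
  }
  curves
}

#' Convert a list of curves to a tidy data frame
#'
#' @param curves list of [effort_curve()] objects.
#' @return data frame with columns `subject_id`, `condition`, `reward`,
#'   `effort`.
#' @export
curves_to_df <- function(curves) {
  do.call(rbind, lapply(curves, function(cu) {
    data.frame(subject_id = cu$subject_id, condition = cu$condition,
               reward = cu$reward, effort = cu$effort,
               stringsAsFactors = FALSE)
  }))
}
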