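#' Paired-samples t-test between conditions
#'
#' Two-sided paired t-test (via [stats::t.test()]) on per-subject parameter
#' estimates, e.g. internal vs external bias. When the differences have zero
#' variance with a nonzero mean the t statistic is infinite and flagged.
#'
#' @param a,b numeric vectors of equal length (paired by subject).
#' @return a list of class `imt_contrast`: `t_statistic`,
#'   `degrees_of_freedom`, `p_value`, `mean_difference`, `n`, `infinite_t`.
#' @export
paired_t <- function(a, b) {
  stopifnot(length(a) == length(b), length(a) >= 2)
  d <- a - b
  if (stats::sd(d) == 0) {
    inf_t <- mean(d) != 0
    res <- list(t_statistic = if (inf_t) Inf * sign(mean(d)) else 0,
                degrees_of_freedom = length(d) - 1L,
                p_value = if (inf_t) 0 else 1,
                mean_difference = mean(d), n = length(d), infinite_t = inf_t)
    class(res) <- "imt_contrast"
    return(res)
  }
  tt <- stats::t.test(a, b, paired = TRUE)
  res <- list(t_statistic = unname(tt$statistic),
              degrees_of_freedom = unname(tt$parameter),
              p_value = tt$p.value,
              mean_difference = unname(tt$estimate),
              n = length(a), infinite_t = FALSE)
  class(res) <- "imt_contrast"
  res
}

#' @export
print.imt_contrast <- function(x, ...) {
  cat(sprintf("t(%d) = %.3f, p = %.4g (mean difference %.4g, n = %d)\n",
              x$degrees_of_freedom, x$t_statistic, x$p_value,
              x$mean_difference, x$n))
  invisible(x)
}

#' Pearson correlation with two-sided p value
#'
#' Product-moment correlation (via [stats::cor.test()]) between a parameter
#' estimate and a questionnaire score.
#'
#' @param x,y numeric vectors of equal length (n >= 3, nonzero variances).
#' @return a list of class `imt_correlation`: `r`, `p_value`, `n`.
#' @export
pearson_corr <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 3)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("correlation undefined: zero variance", call. = FALSE)
  }
  ct <- stats::cor.test(x, y, method = "pearson")
  res <- list(r = unname(ct$estimate), p_value = ct$p.value, n = length(x))
  class(res) <- "imt_correlation"
  res
}

#' @export
print.imt_correlation <- function(x, ...) {
  cat(sprintf("R = %.3f, p = %.4g (n = %d)\n", x$r, x$p_value, x$n))
  invisible(x)
}

#' Difference between two dependent correlations sharing one variable
#'
#' Steiger's Z test for comparing `cor(x1, y)` and `cor(x2, y)` measured on
#' the same subjects: Fisher-transform both correlations and correct the
#' variance of their difference for the correlation `r12` between the two
#' predictors. With `rbar = (r1 + r2)/2`,
#' `s = (r12 * (1 - 2*rbar^2) - rbar^2/2 * (1 - 2*rbar^2 - r12^2)) /
#' (1 - rbar^2)^2` and
#' `Z = (atanh(r1) - atanh(r2)) * sqrt((n - 3) / (2 - 2*s))`, with a
#' two-sided normal p value.
#'
#' @param r1,r2 the two correlations with the shared variable.
#' @param r12 correlation between the two predictors.
#' @param n sample size (>= 4).
#' @return a list: `Z`, `p_value`.
#' @export
dependent_corr_diff <- function(r1, r2, r12, n) {
  stopifnot(n >= 4)
  if (any(abs(c(r1, r2, r12)) >= 1)) {
    stop("correlations must lie strictly inside (-1, 1)", call. = FALSE)
  }
  z1 <- atanh(r1); z2 <- atanh(r2)
  rbar <- (r1 + r2) / 2
  s <- (r12 * (1 - 2 * rbar^2) - 0.5 * rbar^2 * (1 - 2 * rbar^2 - r12^2)) /
    (1 - rbar^2)^2
  Z <- (z1 - z2) * sqrt((n - 3) / (2 - 2 * s))
  list(Z = Z, p_value = 2 * stats::pnorm(-abs(Z)))
}

#' Condition contrasts and questionnaire correlations for a fitted cohort
#'
#' Runs the group-level analysis on a fitted parameter table: paired t-tests
#' of internal vs external condition for each model parameter (on
#' natural-space posterior means), Pearson correlations of each condition's
#' parameters with questionnaire scores, and Steiger's test for the
#' difference between the internal- and external-condition correlations with
#' TEPS-anticipatory. Tests are two-sided and uncorrected by default; setting
#' `bonferroni = TRUE` multiplies contrast p values by the number of
#' parameters tested.
#'
#' @param post_table output of [posterior_table()] for the winning model.
#' @param questionnaire optional questionnaire data frame (see
#'   [generate_cohort()]).
#' @param parameters parameter columns to contrast (defaults to all natural-
#'   space parameter columns except the auxiliary noise term).
#' @param bonferroni apply Bonferroni correction to contrast p values.
#' @return a list: `contrasts` (data frame), `correlations` (data frame or
#'   `NULL`), `correlation_difference` (list or `NULL`).
#' @export
group_statistics <- function(post_table, questionnaire = NULL,
                             parameters = NULL, bonferroni = FALSE) {
  reserved <- c("subject_id", "condition", "log_evidence", "r_squared",
                "converged", "log_noise_sd", "noise_sd")
  if (is.null(parameters)) {
    parameters <- setdiff(names(post_table), reserved)
  }
  internal <- post_table[post_table$condition == "internal", ]
  external <- post_table[post_table$condition == "external", ]
  internal <- internal[order(internal$subject_id), ]
  external <- external[order(external$subject_id), ]
  stopifnot(identical(internal$subject_id, external$subject_id))

  contrasts <- do.call(rbind, lapply(parameters, function(p) {
    ct <- paired_t(internal[[p]], external[[p]])
    data.frame(parameter = p, t_statistic = ct$t_statistic,
               degrees_of_freedom = ct$degrees_of_freedom,
               p_value = min(1, ct$p_value * if (bonferroni) length(parameters) else 1),
               mean_difference = ct$mean_difference, n = ct$n,
               stringsAsFactors = FALSE)
  }))

  correlations <- NULL
  corr_diff <- NULL
  if (!is.null(questionnaire)) {
    q <- questionnaire[order(questionnaire$subject_id), ]
    stopifnot(identical(q$subject_id, internal$subject_id))
    scales <- setdiff(names(q), "subject_id")
    grid <- expand.grid(parameter = parameters, condition = c("internal", "external"),
                        scale = scales, stringsAsFactors = FALSE)
    correlations <- do.call(rbind, lapply(seq_len(nrow(grid)), function(i) {
      tab <- if (grid$condition[i] == "internal") internal else external
      ct <- pearson_corr(tab[[grid$parameter[i]]], q[[grid$scale[i]]])
      data.frame(parameter = grid$parameter[i], condition = grid$condition[i],
                 scale = grid$scale[i], r = ct$r, p_value = ct$p_value,
                 n = ct$n, stringsAsFactors = FALSE)
    }))
    if ("teps_anticipatory" %in% scales && "bias" %in% parameters) {
      r_int <- stats::cor(internal$bias, q$teps_anticipatory)
      r_ext <- stats::cor(external$bias, q$teps_anticipatory)
      r12 <- stats::cor(internal$bias, external$bias)
      corr_diff <- c(list(comparison = "bias~teps_anticipatory: internal vs external"),
                     dependent_corr_diff(r_int, r_ext, r12, nrow(q)))
    }
  }
  list(contrasts = contrasts, correlations = correlations,
       correlation_difference = corr_diff)
}
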