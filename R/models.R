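#' Candidate effort-by-reward psychometric functions
#'
#' Three function families relate effort expended (`y`, normalized to the
#' fraction of the task variant's maximum effort) to reward offered (`x`, in
#' raw currency units):
#'
#' * **linear**: `y = m * x + c`, gradient `m` and intercept `c`;
#' * **sigmoid**: `y = c / (1 + exp(-(x - bias) / sigma))` with the asymptote
#'   `c` fixed at 1, so the free parameters are `bias` (the reward at which
#'   effort reaches half its maximum; larger values mean more reward is
#'   needed to initiate effort) and `sigma` (the inverse-gradient scale, a
#'   reward-insensitivity parameter: larger values mean more additional
#'   reward is needed to accelerate effort expenditure);
#' * **weibull**: `y = A * (1 - 2^(-(x * L)^S))`, asymptote `A`, latency `L`
#'   (minimum reward necessary to begin expending effort) and shape `S`
#'   (abruptness of the rise).
#'
#' A `model_spec` records the family, its free parameter names, the
#' per-parameter link between unconstrained fitting space and natural space
#' (`identity` or `log`; log-linked parameters are therefore positive in
#' natural space), and any parameters held fixed (the sigmoid asymptote).
#'
#' @param family one of `"linear"`, `"sigmoid"`, `"weibull"`.
#' @return an object of class `model_spec` with fields `family`,
#'   `parameter_names`, `transform`, `fixed`.
#' @examples
#' m <- model_spec("sigmoid")
#' m$parameter_names # "bias" "sigma"
#' @export
model_spec <- function(family = c("linear", "sigmoid", "weibull")) {
  family <- match.arg(family)
  spec <- switch(family,
    linear = list(
      family = "linear",
      parameter_names = c("m", "c"),
      transform = c(m = "identity", c = "identity"),
      fixed = list()
    ),
    sigmoid = list(
      family = "sigmoid",
      parameter_names = c("bias", "sigma"),
      transform = c(bias = "identity", sigma = "log"),
      fixed = list(c = 1)
    ),
    weibull = list(
      family = "weibull",
      parameter_names = c("A", "L", "S"),
      transform = c(A = "log", L = "log", S = "log"),
      fixed = list()
    )
  )
  class(spec) <- "model_spec"
  spec
}

#' @export
print.model_spec <- function(x, ...) {
  cat("<model_spec>", x$family, "\n  free parameters:",
      paste(x$parameter_names, collapse = ", "), "\n")
  if (length(x$fixed)) {
    cat("  fixed:", paste(names(x$fixed), unlist(x$fixed), sep = " = ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Evaluate the linear effort function
#'
#' `y = m * x + c`. Not clipped to \[0, 1\]; clipping is the simulator's job.
#'
#' @param x reward (currency units).
#' @param m gradient.
#' @param c intercept.
#' @return predicted normalized effort.
#' @export
eval_linear <- function(x, m, c) {
  m * x + c
}

#' Evaluate the sigmoid effort function
#'
#' `y = c / (1 + exp(-(x - bias) / sigma))`. Strictly increasing in `x` with
#' range `(0, c)`; `bias` is the left-right translation and larger `sigma`
#' gives a shallower slope (reward insensitivity).
#'
#' @param x reward (currency units).
#' @param bias translation parameter (currency units).
#' @param sigma inverse-gradient scale (currency units), must be positive.
#' @param c asymptote (defaults to 1, the normalized-effort ceiling).
#' @return predicted normalized effort.
#' @export
eval_sigmoid <- function(x, bias, sigma, c = 1) {
  if (any(sigma <= 0)) stop("sigma must be > 0", call. = FALSE)
  c * stats::plogis((x - bias) / sigma)
}

#' Evaluate the Weibull effort function
#'
#' `y = A * (1 - 2^(-(x * L)^S))`. Passes through the origin, is monotone
#' increasing, and approaches the asymptote `A` as reward grows.
#'
#' @param x reward (currency units), must be non-negative.
#' @param A asymptote.
#' @param L latency, must be positive.
#' @param S shape, must be positive.
#' @return predicted normalized effort.
#' @export
eval_weibull <- function(x, A, L, S) {
  if (any(x < 0)) stop("x must be >= 0 for the Weibull family", call. = FALSE)
  if (any(L <= 0)) stop("L must be > 0", call. = FALSE)
  if (any(S <= 0)) stop("S must be > 0", call. = FALSE)
  A * (1 - 2^(-(x * L)^S))
}

#' Predict normalized effort under a model specification
#'
#' Dispatches to the family's evaluation function with parameters given in
#' natural space (a named vector or list); fixed parameters from the spec are
#' filled in automatically.
#'
#' @param model a [model_spec()].
#' @param params named numeric vector/list of free parameters, natural space.
#' @param x reward vector.
#' @return vector of predicted normalized efforts (not clipped).
#' @export
predict_effort <- function(model, params, x) {
  p <- as.list(params)
  missing <- setdiff(model$parameter_names, names(p))
  if (length(missing)) {
    stop("missing parameters: ", paste(missing, collapse = ", "), call. = FALSE)
  }
  switch(model$family,
    linear  = eval_linear(x, m = p$m, c = p$c),
    sigmoid = eval_sigmoid(x, bias = p$bias, sigma = p$sigma, c = model$fixed$c),
    weibull = eval_weibull(x, A = p$A, L = p$L, S = p$S)
  )
}

# Map natural-space free parameters to unconstrained fitting space and back.
to_unconstrained <- function(model, params) {
  params <- unlist(params)[model$parameter_names]
  out <- params
  for (nm in model$parameter_names) {
    if (model$transform[[nm]] == "log") out[[nm]] <- log(params[[nm]])
  }
  out
}

to_natural <- function(model, theta) {
  theta <- unlist(theta)[model$parameter_names]
  out <- theta
  for (nm in model$parameter_names) {
    if (model$transform[[nm]] == "log") out[[nm]] <- exp(theta[[nm]])
  }
  out
}

#' Simulate noisy effort observations from a psychometric model
#'
#' Adds independent Gaussian observation noise to the deterministic curve and
#' clips the result to the normalized-effort range \[0, 1\].
#'
#' @param model a [model_spec()].
#' @param params named free parameters, natural space.
#' @param rewards vector of reward levels at which to observe.
#' @param noise_sd observation-noise standard deviation (normalized-effort
#'   units), must be non-negative.
#' @param rng_seed integer seed; the same seed reproduces the same draws.
#' @return vector of noisy normalized efforts, same length as `rewards`.
#' @examples
#' simulate_observations(model_spec("sigmoid"), c(bias = 1, sigma = 0.3),
#'                       rewards = seq(0.25, 2, 0.25), noise_sd = 0.05,
#'                       rng_seed = 1)
#' @export
simulate_observations <- function(model, params, rewards, noise_sd, rng_seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  f <- predict_effort(model, params, rewards)
  eps <- if (noise_sd == 0) {
    numeric(length(rewards))
  } else {
    with_seed(rng_seed, stats::rnorm(length(rewards), 0, noise_sd))
  }
  clip(f + eps, 0, 1)
}
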