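#' Random-effects Bayesian model selection over subject log evidences
#'
#' Treats the identity of the best model as a random effect across subjects:
#' model frequencies `r` follow a Dirichlet distribution whose concentration
#' is estimated by the standard variational scheme. Iterating to convergence:
#' `u_nk` proportional to `exp(LE_nk + psi(alpha_k) - psi(sum(alpha)))` (per
#' subject posterior model assignments), then
#' `alpha_k = alpha0 + sum_n u_nk`.
#'
#' Summaries:
#' * `expected_frequencies = alpha / sum(alpha)`;
#' * `exceedance[k]` — the probability that model k's population frequency
#'   exceeds every competitor's, by Monte-Carlo draws from the Dirichlet
#'   posterior (for K = 2 the closed Beta form
#'   `P(r1 > 1/2) = 1 - pbeta(1/2, alpha1, alpha2)` is used);
#' * `bor` — the Bayesian omnibus risk, the posterior probability that
#'   evidence differences arose by chance:
#'   `1 / (1 + exp(F_rfx - F_null))`, with `F_rfx` the variational lower
#'   bound of the Dirichlet model and
#'   `F_null = sum_n log mean_k exp(LE_nk)` the equal-frequency null;
#' * `protected_exceedance = exceedance * (1 - bor) + bor / K`.
#'
#' @param log_evidences numeric matrix, rows = subjects, columns = models.
#' @param alpha0 Dirichlet prior concentration (flat, 1, by default).
#' @param mc_samples Monte-Carlo draws for the exceedance probability.
#' @param rng_seed seed for the Monte-Carlo draws.
#' @param tol,max_iter convergence controls for the variational updates.
#' @return an object of class `bms_result`: `alpha`,
#'   `expected_frequencies`, `exceedance`, `bor`, `protected_exceedance`,
#'   `assignments` (subjects x models posterior matrix `u`), `F_rfx`,
#'   `F_null`, `mc_samples`, `rng_seed`.
#' @export
rfx_bms <- function(log_evidences, alpha0 = 1, mc_samples = 1e6,
                    rng_seed = 1L, tol = 1e-6, max_iter = 1e4) {
  le <- as.matrix(log_evidences)
  if (!all(is.finite(le))) stop("log evidences must be finite", call. = FALSE)
  n <- nrow(le); K <- ncol(le)
  if (n < 1L || K < 2L) stop("need >= 1 subject and >= 2 models", call. = FALSE)
  model_names <- colnames(le)
  if (is.null(model_names)) model_names <- paste0("m", seq_len(K))

  alpha <- rep(alpha0, K)
  u <- matrix(1 / K, n, K)
  for (it in seq_len(max_iter)) {
    elog_r <- digamma(alpha) - digamma(sum(alpha))
    logu <- sweep(le, 2, elog_r, "+")
    logu <- logu - apply(logu, 1, logsumexp)
    u <- exp(logu)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) {
      alpha <- alpha_new
      break
    }
    alpha <- alpha_new
  }

  ef <- alpha / sum(alpha)
  ep <- exceedance_probability(alpha, mc_samples = mc_samples,
                               rng_seed = rng_seed)

  f_rfx <- rfx_free_energy(le, u, alpha, alpha0)
  f_null <- sum(apply(le, 1, logsumexp) - log(K))
  bor <- 1 / (1 + exp(f_rfx - f_null))
  pxp <- ep * (1 - bor) + bor / K

  names(alpha) <- names(ef) <- names(ep) <- names(pxp) <- model_names
  colnames(u) <- model_names
  structure(list(alpha = alpha, expected_frequencies = ef, exceedance = ep,
                 bor = bor, protected_exceedance = pxp, assignments = u,
                 F_rfx = f_rfx, F_null = f_null,
                 mc_samples = as.integer(mc_samples),
                 rng_seed = as.integer(rng_seed)),
            class = "bms_result")
}

#' @export
print.bms_result <- function(x, ...) {
  cat("<bms_result>", length(x$alpha), "models,",
      "BOR =", format(x$bor, digits = 4), "\n")
  print(round(rbind(alpha = x$alpha,
                    expected_frequency = x$expected_frequencies,
                    exceedance = x$exceedance,
                    protected_exceedance = x$protected_exceedance), 4))
  invisible(x)
}

# Exceedance probability of each component of a Dirichlet(alpha):
# P(r_k > r_j for all j != k). Closed Beta form for K = 2, Monte Carlo
# otherwise.
exceedance_probability <- function(alpha, mc_samples = 1e6, rng_seed = 1L) {
  K <- length(alpha)
  if (K == 2L) {
    ep1 <- 1 - stats::pbeta(0.5, alpha[1], alpha[2])
    return(c(ep1, 1 - ep1))
  }
  with_seed(rng_seed, {
    counts <- integer(K)
    # draw in blocks to bound memory
    remaining <- mc_samples
    while (remaining > 0) {
      m <- min(remaining, 2.5e5)
      g <- matrix(stats::rgamma(m * K, shape = rep(alpha, each = m)), m, K)
      counts <- counts + tabulate(max.col(g, ties.method = "first"), K)
      remaining <- remaining - m
    }
    counts / mc_samples
  })
}

# Variational lower bound (free energy) of the Dirichlet random-effects
# model: E_q[log p(y, z, r)] - E_q[log q(z, r)].
rfx_free_energy <- function(le, u, alpha, alpha0) {
  K <- ncol(le)
  a0 <- rep(alpha0, K)
  elog_r <- digamma(alpha) - digamma(sum(alpha))
  xlogx <- function(p) ifelse(p > 0, p * log(p), 0)
  e_joint <- sum(u * sweep(le, 2, elog_r, "+")) - sum(xlogx(u))
  kl_dir <- lgamma(sum(alpha)) - sum(lgamma(alpha)) -
    lgamma(sum(a0)) + sum(lgamma(a0)) +
    sum((alpha - a0) * elog_r)
  e_joint - kl_dir
}

#' Between-conditions model-stability test
#'
#' Tests whether the same model family generated both motivation conditions'
#' data. For K candidate models, K^2 tuple models are built with per-subject
#' evidence `LE_A[n, i] + LE_B[n, j]` (model i in condition A and model j in
#' condition B); random-effects BMS is run over the K^2 tuples, and tuples
#' are aggregated into two families — "same" (the K diagonal tuples) and
#' "different" (the rest). By the aggregation property of the Dirichlet, the
#' family frequency of "same" follows
#' `Beta(sum alpha_same, sum alpha_diff)`, so the family exceedance
#' probability is computed in closed form; the protected version applies the
#' omnibus-risk correction at the family's chance level (its induced prior
#' mass, `K / K^2 = 1/K`).
#'
#' @param log_evidences_a,log_evidences_b subjects x models evidence
#'   matrices for the two conditions (same subjects, same model set).
#' @param alpha0,mc_samples,rng_seed passed to [rfx_bms()].
#' @return a list: `stability_pxp` (protected exceedance probability that
#'   the same model underlies both conditions), `stability_ep`, `bor`,
#'   `tuple_bms` (the full `bms_result` over the K^2 tuple models),
#'   `same_family` (indices of the diagonal tuples).
#' @export
between_conditions_bms <- function(log_evidences_a, log_evidences_b,
                                   alpha0 = 1, mc_samples = 1e6,
                                   rng_seed = 1L) {
  a <- as.matrix(log_evidences_a); b <- as.matrix(log_evidences_b)
  if (!identical(dim(a), dim(b))) {
    stop("condition evidence matrices must have identical dimensions",
         call. = FALSE)
  }
  n <- nrow(a); K <- ncol(a)
  model_names <- colnames(a)
  if (is.null(model_names)) model_names <- paste0("m", seq_len(K))

  tuples <- expand.grid(i = seq_len(K), j = seq_len(K))
  le <- matrix(NA_real_, n, nrow(tuples))
  colnames(le) <- paste0(model_names[tuples$i], "+", model_names[tuples$j])
  for (t in seq_len(nrow(tuples))) {
    le[, t] <- a[, tuples$i[t]] + b[, tuples$j[t]]
  }
  fit <- rfx_bms(le, alpha0 = alpha0, mc_samples = mc_samples,
                 rng_seed = rng_seed)

  same <- which(tuples$i == tuples$j)
  a_same <- sum(fit$alpha[same])
  a_diff <- sum(fit$alpha[-same])
  ep_same <- 1 - stats::pbeta(0.5, a_same, a_diff)
  chance <- length(same) / nrow(tuples)   # induced family prior mass, 1/K
  pxp_same <- ep_same * (1 - fit$bor) + fit$bor * chance

  list(stability_pxp = pxp_same, stability_ep = ep_same, bor = fit$bor,
       tuple_bms = fit, same_family = same)
}
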