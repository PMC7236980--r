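# Internal helpers shared across modules.

# Run code under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  env <- globalenv()
  had_seed <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had_seed) get(".Random.seed", envir = env, inherits = FALSE) else NULL
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = env)
    } else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Deterministic sub-seed derivation; keeps results within 32-bit integer range.
derive_seed <- function(master_seed, offset) {
  s <- (as.numeric(master_seed) + as.numeric(offset) * 10007) %% 2147483629
  as.integer(s) + 1L
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

stopifnot_finite <- function(x, what) {
  if (!all(is.finite(x))) {
    stop(what, " must be finite, got: ", paste(utils::head(x[!is.finite(x)], 3), collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}
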