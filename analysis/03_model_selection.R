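#!/usr/bin/env Rscript
# Stage 3: random-effects Bayesian model selection.
#
# Which family best explains the cohort is treated as a random effect:
# per-subject log evidences (summed across the two motivation conditions)
# feed the variational Dirichlet scheme, summarized by expected model
# frequencies, exceedance probability, Bayesian omnibus risk and protected
# exceedance probability. A between-conditions run over the 9 tuple models
# (family A in the external condition x family B in the internal) then asks
# whether the same family generated both conditions.

suppressPackageStartupMessages(library(imtfit))

read_le <- function(label) {
  path <- sprintf("results/fits/evidence_%s.csv", label)
  if (!file.exists(path)) {
    stop("missing stage output: ", path, " (run analysis/02_fit_models.R first)")
  }
  df <- read.csv(path)
  le <- as.matrix(df[, -1])
  rownames(le) <- df$subject_id
  le
}

le <- read_le("combined")
bms <- rfx_bms(le, alpha0 = 1, mc_samples = 1e6, rng_seed = 50205L)
print(bms)

st <- between_conditions_bms(read_le("external"), read_le("internal"),
                             alpha0 = 1, mc_samples = 1e6,
                             rng_seed = 50206L)
message(sprintf("between-conditions stability: PXP = %.3f (EP %.3f, BOR %.2e)",
                st$stability_pxp, st$stability_ep, st$bor))

dir.create("results/bms", showWarnings = FALSE, recursive = TRUE)
jsonlite::write_json(list(
  combined = list(alpha = as.list(bms$alpha),
                  expected_frequencies = as.list(bms$expected_frequencies),
                  exceedance = as.list(bms$exceedance),
                  bor = bms$bor,
                  protected_exceedance = as.list(bms$protected_exceedance),
                  mc_samples = bms$mc_samples, rng_seed = bms$rng_seed),
  between_conditions = list(stability_pxp = st$stability_pxp,
                            stability_ep = st$stability_ep, bor = st$bor,
                            tuple_alpha = as.list(st$tuple_bms$alpha))
), "results/bms/model_selection.json", auto_unbox = TRUE, digits = NA)
message("wrote results/bms/model_selection.json")
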