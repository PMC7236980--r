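#!/usr/bin/env Rscript
# Stage 1: generate the synthetic cohorts for both task variants.
#
# The physical-effort cohort (26 subjects, 128 trials each: 8 reward levels
# x 8 repetitions x 2 interleaved conditions) and the cognitive-effort
# cohort (28 subjects, one presentation per reward level) are drawn from the
# default generative assumptions: condition-specific Gaussian populations of
# sigmoid bias and log reward-insensitivity, a logistic accept/reject rule
# in the external condition, Gaussian observation noise on indicated effort,
# and a negative loading of anticipatory-pleasure scores on internal bias.
#
# Pass --null to generate a zero-condition-effect cohort instead.

suppressPackageStartupMessages(library(imtfit))

args <- commandArgs(trailingOnly = TRUE)
null_effect <- "--null" %in% args
master_seed <- 20205L

out_root <- "results"
for (variant in c("physical", "cognitive")) {
  design <- default_design(variant)
  spec <- default_cohort_spec(variant, null_effect = null_effect,
                              rng_seed = master_seed +
                                (variant == "cognitive"))
  cohort <- generate_cohort(design, spec)
  dir <- file.path(out_root,
                   paste0("cohort_", variant, if (null_effect) "_null" else ""))
  write_cohort(cohort, design, spec, dir)
  message(sprintf("%s cohort: %d subjects, %d trials -> %s",
                  variant, spec$n_subjects, nrow(cohort$trials), dir))
}
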