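# imtfit

Effort-discounting model fitting and Bayesian model selection for the
Internal-External Motivation Task (IMT) — an R package plus a scripted
analysis pipeline for dissociating **self-generated (internal)** from
**externally-generated (external)** motivation.

## The problem

Willingness to exert effort for reward is a standard behavioral probe of
motivation, with direct relevance to anhedonia and apathy. Classic
paradigms present explicit effort-for-reward offers (externally-generated
motivation); the IMT adds an interleaved condition in which the subject
freely indicates how much work they would do for each reward
(self-generated motivation, or volition). The physical variant trades
$0.25–$2.00 against 3–70 button presses over 128 trials; the cognitive
variant trades £1–£500 against 1–200 minutes of a serial-threes task
(rewards above £200 are excluded from analysis).

`imtfit` is aimed at researchers who want to fit and compare psychometric
effort-by-reward discount curves on such data. Per subject and condition it
fits three candidate functions:

* linear: `y = m x + c`
* sigmoid: `y = 1 / (1 + exp(-(x - bias) / sigma))`, with `bias` the reward
  needed for effort initiation and `sigma` the *reward insensitivity*
  (inverse gradient): how much extra reward is needed to accelerate effort
* Weibull: `y = A (1 - 2^(-(x L)^S))`

with effort `y` normalized to the variant's maximum and reward `x` in raw
currency units. Fitting is maximum-a-posteriori with a Laplace-approximated
log evidence, wrapped in an iterated empirical-Bayes ("mixed-effects")
loop that re-estimates the Gaussian group prior from the individual
posteriors until the group-level evidence stops improving. Families are
compared by random-effects Bayesian model selection (expected frequencies,
exceedance probability, Bayesian omnibus risk, protected exceedance
probability), including a between-conditions run that asks whether the same
family generated both conditions. Estimator reliability is quantified by
simulation-recovery, and group-level inference covers paired condition
contrasts, questionnaire correlations, and Steiger's test for dependent
correlations. Because no trial-level IMT data are publicly deposited, the
package ships a synthetic-cohort generator that emulates both task
variants with known ground truth; see `vignettes/imt-modelling.Rmd` for
the full model description.

## Worked example

The `analysis/` scripts run the complete pipeline on a default synthetic
cohort and write their tables under `results/`:

```sh
Rscript analysis/01_simulate_cohort.R   # synthetic cohorts, both variants
Rscript analysis/02_fit_models.R        # hierarchical fits, 3 families
Rscript analysis/03_model_selection.R   # RFX-BMS + stability
Rscript analysis/04_recovery.R          # simulation-recovery, N = 1000
Rscript analysis/05_group_stats.R       # contrasts, correlations, report
```

Stage 2 prints the fit summary (26 subjects, 52 curves):

```
linear   15 EB iterations, group log evidence 260.9, mean r2 0.867
sigmoid   8 EB iterations, group log evidence 453.9, mean r2 0.949
weibull  32 EB iterations, group log evidence 354.8, mean r2 0.947
sigmoid external condition: mean r2 = 0.902 +/- 0.06
sigmoid internal condition: mean r2 = 0.996 +/- 0.00
```

Stage 3 identifies the sigmoid as the generating family:

```
                     linear sigmoid weibull
alpha                1.0185 26.9428  1.0387
expected_frequency   0.0351  0.9291  0.0358
exceedance           0.0000  1.0000  0.0000
protected_exceedance 0.0000  1.0000  0.0000
between-conditions stability: PXP = 0.880 (EP 0.880, BOR 9.15e-08)
```

i.e. essentially all Dirichlet mass sits on the sigmoid (protected
exceedance probability 1.000, expected model frequency 0.93). The
between-conditions stability probability is the weakest summary on
synthetic cohorts — the external condition's max-accepted-offer curves are
coarse and carry little family information (see the vignette's discussion).

Stage 4 shows the sigmoid parameters are recoverable from the fitted group
distribution (true vs re-estimated values over 1000 simulated subjects):

```
  parameter pearson_r n_used
1      bias 0.9989418   1000
2     sigma 0.9908126   1000
```

Stage 5 recovers the injected condition effects and questionnaire loading
(internal bias is higher — reduced self-generated effort initiation — and
correlates negatively with anticipatory pleasure):

```
condition contrasts (internal - external):
 parameter t_statistic degrees_of_freedom     p_value mean_difference  n
      bias    3.333621                 25 0.002673259      0.22929902 26
     sigma    2.850841                 25 0.008614596      0.08039621 26
bias ~ anticipatory pleasure:
 parameter condition             scale          r      p_value  n
      bias  internal teps_anticipatory -0.6722906 0.0001686282 26
      bias  external teps_anticipatory -0.2662606 0.1885838800 26
difference of dependent correlations: Z = -1.93, p = 0.0542
```

A consolidated markdown report lands in `results/report.md`.

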