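---
title: "Modelling self-generated and externally-generated motivation with effort-discounting curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling self-generated and externally-generated motivation with effort-discounting curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The task and the modelling problem

The Internal-External Motivation Task (IMT) measures willingness to exert
effort for monetary reward under two interleaved conditions. In the
*external* condition the subject is offered an explicit (effort, reward)
pair — e.g. "41 button presses for \$1.25" — and accepts or rejects it. In
the *internal* condition the subject freely positions a bar to indicate the
maximum effort they would expend for each reward. The external condition
captures externally-generated motivation (the classic accept/reject
effort-discounting setting); the internal condition captures self-generated
motivation, or volition. The physical variant uses 3–70 button presses and
rewards of \$0.25–\$2.00 over 128 trials; the cognitive variant uses 1–200
minutes of a serial-threes counting task for rewards on a 1–2–5 ladder of
pounds, with reward magnitudes above £200 excluded because the internal
condition is unbounded there.

`imtfit` turns raw trial tables into per-subject, per-condition
effort-by-reward discount curves, fits competing psychometric functions to
them under an iterated empirical-Bayes scheme, selects among the functions
by random-effects Bayesian model selection, quantifies estimator
reliability by simulation-recovery, and runs the group-level condition
contrasts and questionnaire correlations. Because no public trial-level
data exist for this task, the package includes a synthetic-cohort generator
that makes every stage testable end to end.

## Candidate psychometric functions

Effort `y` is normalized to the fraction of the variant's maximum (70
presses or 200 minutes); reward `x` stays in raw currency units so that
parameters are interpretable per experiment. Three families are compared:

* linear, `y = m x + c`;
* sigmoid, `y = 1 / (1 + exp(-(x - bias) / sigma))` — `bias` is the reward
  at which effort reaches half maximum (the amount of reward needed to
  initiate effort) and `sigma` is the inverse-gradient scale, read as
  *reward insensitivity*: the larger it is, the more additional reward is
  needed to accelerate effort expenditure;
* Weibull, `y = A (1 - 2^(-(x L)^S))` — latency `L`, abruptness `S`,
  asymptote `A`.

The sigmoid asymptote is fixed at 1 so the family has exactly two free
parameters, matching how the curve characteristics are reported and
contrasted. Positive parameters (`sigma`, `A`, `L`, `S`) are fitted on the
log scale, which makes every unconstrained real value a valid parameter and
makes the group-level Gaussian assumption a log-normal in natural space.

## Subject-level inversion

Each discount curve (one point per reward level) is fitted by
maximum-a-posteriori estimation with a Laplace approximation. The log joint
is a Gaussian likelihood around the model prediction plus independent
Gaussian priors in unconstrained space. The observation-noise log-sd is an
auxiliary free parameter with prior Normal(log 0.1, 1); it is excluded from
condition contrasts and recovery scoring. Optimization uses quasi-Newton
(BFGS) search from 5 jittered starts (relative tolerance 1e-8, at most 500
iterations each, best optimum kept, ties to the first found). The posterior
covariance is the inverse of the finite-difference negative Hessian at the
mode, ridge-regularized (escalating from 1e-8) until a Cholesky
factorization succeeds, and the log evidence is the Laplace free energy

```
log p(y) ~ log_joint(mode) + d/2 log(2 pi) + 1/2 log det(cov).
```

This is a fixed-form Gaussian approximation to the posterior — the same
object targeted by variational-Laplace schemes — specified here completely
so the package has no untestable dependencies. Points where a log-linked
parameter underflows to zero during line search are treated as having
negligible joint density rather than raising an error, and fits whose
Hessian cannot be evaluated fall back to the prior curvature and are
flagged unconverged. Because the evidence is evaluated in unconstrained
space, it includes the log-Jacobian of the log links; all families are
treated identically, so model comparison is unaffected by this convention.

## The iterated empirical-Bayes loop

To reduce outlier parameter estimates, fitting is mixed-effects: after each
round of subject inversions, the Gaussian population distribution is
re-estimated by moment matching — prior mean = average posterior mean,
prior variance = population (divide-by-n) variance of posterior means plus
the average posterior variance, floored at 1e-6 — and used as the prior for
the next round, until the summed subject log evidence improves by less than
1e-3 nats (at most 32 iterations). Data from both motivation conditions are
pooled into a single prior, which shrinks every estimate toward the common
group mean and is therefore *conservative* with respect to condition
differences; the package's tests verify this shrinkage property directly.
Convergence is monitored on summed subject evidence rather than a full
hierarchical free energy. Because each pass re-maximizes the subjects'
objectives under a *changed* prior, the summed evidence is not a joint
ascent criterion: the trace rises strictly until the first non-improving
pass, at which the loop stops, and that terminal step may dip slightly
(the tests bound any such dip to a few percent of the accumulated gain).

## Random-effects model selection

Which family wins is treated as a random effect across subjects. The
variational Dirichlet scheme iterates soft subject-to-model assignments
`u_nk ∝ exp(LE_nk + ψ(α_k) − ψ(Σα))` with `α = α0 + Σ_n u_n` (flat
`α0 = 1`; convergence when α changes by < 1e-6, at most 1e4 iterations).
Summaries:

* expected model frequencies `α/Σα`;
* exceedance probability (EP): the probability that a model's population
  frequency exceeds all others, computed from 1e6 Monte-Carlo Dirichlet
  draws under a fixed, logged seed (closed Beta form when K = 2);
* Bayesian omnibus risk (BOR): the posterior probability that evidence
  differences arose by chance, `1/(1 + exp(F_rfx − F_null))`, where
  `F_rfx` is the variational lower bound of the Dirichlet model and
  `F_null = Σ_n log mean_k exp(LE_nk)` is the equal-frequency null;
* protected exceedance probability (PXP): `EP·(1 − BOR) + BOR/K`.

For the between-conditions stability question, the two conditions' evidence
matrices are combined into K² = 9 tuple models (family i externally, family
j internally, per-subject evidence `LE_ext[n,i] + LE_int[n,j]`), RFX-BMS is
run over the tuples, and the tuples are aggregated into a "same" family
(the diagonal) and a "different" family. By the aggregation property of the
Dirichlet distribution the "same" family's frequency is Beta-distributed,
so its exceedance probability is exact; the protected version applies the
BOR correction at the family's induced prior mass (3/9 = 1/3). The induced
(rather than equalized) family prior is kept so that fully uninformative
evidences yield a stability PXP at the family's prior mass — the natural
chance level for this construction.

## The synthetic-cohort generator

The generator emulates the study conditions so that every downstream stage
has a recoverable ground truth. Defaults for the physical variant: 26
subjects; external bias ~ Normal(\$0.90, 0.25²) and internal bias ~
Normal(\$1.15, 0.25²); external log-sigma ~ Normal(log 0.25, 0.30²) and
internal ~ Normal(log 0.35, 0.30²) — the internal condition sits at higher
bias and higher reward insensitivity, the direction of the reported
condition effects; observation noise 0.05 (normalized effort) on indicated
effort; a logistic accept/reject rule around the latent threshold with
softness τ = 5 presses; 30% of accepted trials flagged as leading to actual
work. Eight reward levels with eight repetitions per condition reproduce
the stated 128-trial total; the external offer grid is 8 evenly spaced
values spanning 3–70 presses (rounded to whole presses), each paired once
with every reward level. Anticipatory-pleasure scores load negatively on
internal-condition bias (−15 points per dollar, residual sd 4) so the
questionnaire correlation analysis has a known target; consummatory scores
and depression scores are independent noise. The cognitive variant uses a
1–2–5 reward ladder capped at £200, 28 subjects, τ = 15 minutes, and no
sigma condition effect.

What the generator does *not* emulate: reaction times, learning or fatigue
across trials, the incentive effects of the hidden work-threshold payout,
or ceiling-prone subjects who accept everything. Passing tests therefore
show that the pipeline recovers what this generative model encodes — not
that real IMT data satisfy these assumptions.

## Curve preprocessing conventions

External curves take, per reward level, the *maximum offered effort among
accepted trials*, normalized; levels with no accepted offer map to 0
("unwilling to initiate"). Internal curves take the *mean* indicated effort
per level — the mean rather than the maximum, because the maximum of a
noisy indication conflates noise with motivation. Cognitive-variant curves
drop points above the £200 cap in both conditions.

A consequence worth knowing: the external statistic is quantized to the
offer grid and can contain exact zeros, giving external curves an
abrupt-rise, through-the-origin character that the three-parameter Weibull
matches nearly as well as the sigmoid once the empirical-Bayes priors have
adapted. In the package's default synthetic cohorts the internal condition
identifies the sigmoid decisively while the external condition alone often
does not — so the combined model selection is dominated by the internal
margins, and the between-conditions stability probability is markedly less
stable across cohort seeds than the other summaries. This is a property of
the max-accepted-offer statistic under a soft choice rule with a coarse
offer grid, not of the selection machinery, whose behavior on clean
evidence patterns is verified independently in the tests.

## Simulation-recovery

Reliability is assessed by drawing N = 1000 parameter sets independently
per dimension from the group distribution (matching the per-parameter
phrasing of the procedure this implements), simulating observations at the
design's reward levels and repetitions with noise sd 0.05, aggregating to
one point per level as in preprocessing, re-inverting under the group
prior, and correlating true with recovered values (posterior means in
natural space; the mean is chosen over the mode for consistency with the
Gaussian approximation). Failed inversions are excluded and counted.
Because averaging eight replicates per level suppresses the observation
noise, recovery under the default design is substantially better than the
floors asserted in the acceptance checks; degradation tests therefore use a
single observation per level, where extreme noise genuinely destroys the
signal.

## Group statistics

Condition contrasts are two-sided paired t-tests on natural-space posterior
means (bias and sigma in currency units), uncorrected for multiple
comparisons by default (a Bonferroni switch exists). Questionnaire
correlations are Pearson product-moment correlations. The difference
between the internal- and external-condition correlations with anticipatory
pleasure — two dependent correlations sharing one variable — is tested with
Steiger's Z (Fisher transforms with the shared-variable covariance
correction). Published values of the analogous difference test on the real
cohort are not recoverable from the standard formula and are not targeted.

## Numerical choices and problem sizes

All randomness is seeded; sub-seeds are derived deterministically from a
master seed, and two runs with the same seed produce identical outputs.
Default problem sizes were chosen so the full pipeline runs on a laptop
core: the three-family hierarchical fit of a 26-subject cohort takes a few
minutes; the N = 1000 recovery takes about two; test-suite property checks
use scaled-down versions (8–20 subjects, 3–5 seeds, 60–80 recovery samples)
of the same procedures. Degenerate inputs are handled explicitly: empty
curves error; flat curves are fittable with an undefined r² flag;
zero-variance difference vectors yield an infinite-t flag; fewer than two
finite posteriors abort a group-prior update.

## Known limitations

* The Laplace evidence is exact only for Gaussian posteriors; the tests
  bound its error against quadrature on 2-parameter instances (0.05 nats)
  but higher-dimensional error is unquantified.
* The empirical-Bayes loop is moment matching, not full hierarchical
  inference; its convergence criterion is the summed subject evidence.
* Parameters are drawn independently in recovery; any true correlation
  between bias and sigma in a population is not propagated.
* The external-condition curve statistic discards rejected-offer
  information below the maximum accepted offer; a full choice-model
  likelihood would be more efficient but is outside the scope of the
  curve-fitting framework implemented here. The information loss is not
  cosmetic: it adds estimation noise to external-condition parameters that
  measurably reduces the power of the paired condition contrast relative
  to what the injected effect size alone would give.
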