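---
title: "Estimating cross-task covariance in metacognitive efficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating cross-task covariance in metacognitive efficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(metacov)
```

## The model

### Type-I and type-II signal detection

Each trial of a 2AFC task presents one of two stimulus classes (S1/S2). The
type-I model places evidence at `x ~ Normal(±d′/2, 1)` and produces the
response by comparison with a criterion `c`; sensitivity is
`d′ = z(hits) − z(false alarms)` with `z` the inverse cumulative normal, and
`c = −0.5 (z(hits) + z(false alarms))`. One response class is designated
"signal" arbitrarily — in 2AFC this only fixes a sign convention.

The type-II model asks how well *confidence* discriminates correct from
incorrect responses. meta-d′ is the type-I sensitivity that an SDT-ideal
confidence observer would need in order to reproduce the observed
response-conditional confidence distributions. Concretely, the meta-level
observer sees a second evidence sample `x2 ~ Normal(±meta-d′/2, 1)`,
restricted to the response-consistent side of the *scaled* criterion
`c′·meta-d′` (where `c′ = c/d′` is the relative criterion, held fixed at its
empirical value), and reports confidence by comparing `x2` with `2(K−1)`
ordered type-2 criteria. The likelihood of a counts table is the multinomial
over response-conditional confidence cells; the type-I response rates depend
only on `(d′, c)` and drop out. Metacognitive efficiency is
`Mratio = meta-d′/d′`: 1 for an SDT-optimal observer, below 1 when
confidence carries less information than the decision.

Fixing the type-I parameters at their point estimates (log-linear corrected)
rather than sampling them jointly follows the established hierarchical
meta-d′ convention; the uncertainty that matters for cross-task covariance
is the type-II uncertainty, which the model carries in full.

### The hierarchical multi-task extension

For subjects `s = 1..N` and tasks `t = 1..T`, the subject's log efficiency
vector is one draw from a multivariate Gaussian,

```
(log M_s1, ..., log M_sT) ~ MVN(mu, Sigma),   Sigma_ij = rho_ij sigma_i sigma_j
```

with priors `mu_t ~ Normal(0, 1)`, `sigma_t ~ InvSqrtGamma(0.001, 0.001)`
(i.e. `1/sigma² ~ Gamma(0.001, 0.001)`) and element-wise
`rho_ij ~ Uniform(−1, 1)`. The element-wise uniform prior does not by itself
guarantee a valid correlation matrix; states whose `Sigma` is not positive
definite are rejected at evaluation (their density is zero), which matches
the rejection-at-evaluation behaviour of graphical samplers under the same
prior. An LKJ-style parameterisation would guarantee validity by
construction but would change the prior; fidelity to the element-wise
uniform prior was preferred, and the prior-predictive check below verifies
the implied marginals.

Group efficiency per task is reported as `exp(mu_t)` (the Mratio scale), and
pairwise group differences as `exp(mu_i) − exp(mu_j)`. A correlation is
flagged significant when its 95% highest-density interval — the narrowest
interval containing 95% of the posterior draws — excludes zero.

## The sampler

No general-purpose MCMC engine (JAGS/Stan) is assumed; the package ships a
Metropolis-within-Gibbs sampler specialised to this model:

- **Subject-level log-Mratio**: random-walk proposals, vectorised across
  subjects (subjects are conditionally independent given group parameters),
  accepted against the type-II multinomial likelihood plus the conditional
  normal prior implied by `MVN(mu, Sigma)`.
- **Subject-level type-2 criteria**: parameterised by log-gaps between
  consecutive criteria (any real vector maps to an admissible ordered set,
  so no constrained optimiser or boundary handling is needed), with
  independent `Normal(log 0.5, 1)` priors on the log-gaps. The criterion
  ladder is anchored at the empirical scaled criterion by construction,
  which is the "weakly informative, centred on the empirical criterion"
  choice in log-gap form.
- **Group means**: exact conjugate Gibbs draws.
- **Group SDs and correlations**: random walks (log scale for `sigma`),
  with five sweeps per iteration — these updates cost only a `T × T`
  Cholesky plus an `N × T` solve, a sliver of the likelihood work, and the
  extra sweeps sharply reduce autocorrelation.
- **Funnel moves**: at 40 trials per task the group posterior has the
  classic hierarchical funnel (small `sigma` pinches every subject effect
  towards `mu`) and elementwise updates cross it slowly. Three joint moves
  address this, each a correctness-preserving Metropolis move:
  a *scaling* move remapping
  `(logM_t, sigma_t) -> (mu_t + c(logM_t − mu_t), c·sigma_t)` with a
  symmetric log-scale step and Jacobian `c^(N+1)`; a *shift* move
  translating `mu_t` and the whole `logM_t` column together (the centered
  MVN term is invariant, so only the `mu` prior and the task likelihood
  enter); and a *non-centered correlation* move that proposes `rho'` while
  holding each subject's standardized coordinates `eta = L^{-1}(logM − mu)`
  fixed and remapping `logM' = mu + L'eta` — the MVN prior ratio cancels
  the map's Jacobian exactly, so `rho` is accepted on the likelihood ratio
  alone, against the data rather than through the shrunk subject
  configuration.

Step sizes adapt toward standard acceptance targets during burn-in only, so
the kept chain is a valid time-homogeneous Markov chain. Defaults are 3
chains × 10,000 kept samples after 1,000 burn-in (the chain lengths used in
examples and tests are smaller and stated where used). Convergence is
monitored with the Gelman–Rubin statistic computed from between- and
within-chain variances; fits warn when any group-level R̂ exceeds 1.1. The
recovery study counts a fit as non-converged at the clearly-failed cut
R̂ > 1.2, because two-chain R̂ at desk-scale chain lengths fluctuates by
±0.05–0.1 around 1.

With `prior_only = TRUE` the posterior is exactly the joint prior, which is
fully known, so it is sampled ancestrally (iid draws; correlation matrices
by rejection of non-PSD element-wise uniform draws) rather than by MCMC.
This gives the exact prior-predictive reference: the marginal of each
`rho` is then Uniform(−1, 1) by construction for `T = 2` and the KS check in
the test suite verifies the sampler output against it.

## The synthetic-data generator

`simulate_group()` emulates the target experimental design: by default 4
tasks × 40 trials × N participants on an 11-level confidence scale
(0–100% in 10% steps), per-subject per-task `d′ ~ Uniform(0.5, 2.5)` —
spanning the range of task-mean sensitivities typical of calibrated
multi-task batteries (roughly 0.9–2.6) — a small criterion jitter
`Normal(0, 0.1)` (unbiased observers with realistic wobble), and per-subject
log-Mratio from the multivariate Gaussian above (default group Mratio 0.8,
spread 0.5, cross-task correlation 0.6 — mid-range values for published
multi-task efficiency estimates). Confidence is generated by the same
truncated-normal second-sample scheme the estimators assume, so meta-d′
fits on these data are *consistent*: parameter-recovery tests are tests of
the estimation machinery, not of model misfit.

Default type-2 criteria are placed at quantiles of the response-conditional
type-2 evidence distribution so every confidence level is used with roughly
equal probability (there are no canonical criterion values to emulate);
`subject_task_params()` accepts arbitrary criteria for non-uniform usage.

What a green simulation test does **not** establish: real observers violate
the generative model (metacognitive noise, criterion drift, response-time
dependence, non-Gaussian evidence), real confidence usage is far from
uniform, and real d′ varies within subjects across a session. Recovery on
synthetic data is a necessary, not sufficient, validation.

## Numerical choices

- **Edge handling.** The MLE path adds `1/(2K)` per cell only when an
  entire response-conditional family is empty (common at 40 trials); the
  Bayesian path applies no correction — zero cells are handled by the
  likelihood itself. Type-I point estimates always use the log-linear
  rate correction so `z()` stays finite.
- **Degenerate inputs.** A single observed confidence level makes meta-d′
  unidentified (the type-II ROC is the diagonal); the fit returns
  meta-d′ = 0 flagged `"degenerate"`. In the hierarchical path, point
  estimates of `d′` are floored at 0.01 so the Mratio parameterisation
  stays defined for (rare) below-chance subjects — the hierarchical model
  keeps all subjects, while the nonhierarchical path excludes any subject
  with `d′ < 0.10` in any task. The asymmetry is deliberate: hierarchical
  shrinkage absorbs near-chance subjects gracefully, whereas their MLE
  Mratio (a ratio with a near-zero denominator) is meaningless.
- **Optimisation.** The MLE maximises over `(meta-d′, log-gaps)` with
  Nelder-Mead from two starts plus a polish pass; admissibility of criteria
  is guaranteed by the parameterisation. The fit is validated against an
  exhaustive grid search (step 0.005) with independently-coded nested
  criteria optimisation.
- **HDI ties.** Equally narrow windows are resolved leftmost
  (deterministic).
- **Paired t limit.** Identical pairs return the natural limit
  `t = 0, p = 1, dz = 0`; any other zero-variance difference vector is a
  degenerate-test error (a constant nonzero shift has no finite t).
- **Confidence binning.** For 40-trial data the 11-level scale is collapsed
  to 4 equal-width bins before meta-d′ fitting (sparse cells otherwise);
  `collapse_to = NULL` disables collapsing. The hierarchical model accepts
  any K.
- **Seeds.** Every stochastic entry point takes a seed and restores the
  caller's RNG state; derived seeds stay below 2³¹.

## Known limitations

- Equal-variance SDT only; no unequal-variance or continuous-rating
  variants, and a single meta-d′ across both responses (no
  response-specific efficiency).
- The correlation prior is element-wise uniform with PSD rejection; for
  `T > 2` the implied marginal priors are not uniform (the PSD constraint
  concentrates them slightly toward zero), a property of the printed prior
  itself, not of the sampler.
- R̂ on short two-chain runs is noisy; the defaults (3 × 10,000) are
  recommended for substantive analyses.
- The regression influence screen (leverage > 2(k+1)/n, |studentized
  residual| > 3, Cook's D > 4/n) flags ~11% of points under a Gaussian
  null at n = 200 — these are screening cutoffs, not calibrated tests, and
  the union rate is dominated by the leverage and Cook's cutoffs.
- Metacognitive bias is operationalised as the plain mean confidence level,
  not as confidence minus performance: on a 2AFC task the anchoring of "0%
  confident" relative to the 50% chance floor is ambiguous, which makes the
  difference score hard to interpret. No bias-score function is provided.
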