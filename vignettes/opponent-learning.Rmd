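---
title: "Modelling opponent-sensitive learning in the repeated Chicken game"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling opponent-sensitive learning in the repeated Chicken game}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The task and the scientific question

In the repeated Chicken game two players simultaneously choose to *swerve*
(the safe, cooperative act) or *go straight* (the competitive act). Going
straight against a swerver pays best; a mutual crash pays worst; swerving is
safe regardless of the partner. When the partner is a pre-programmed
opponent with a fixed competitiveness — here a high-competitive opponent
(HCO) that goes straight on 70% of trials and a low-competitive opponent
(LCO) on 30% — an adaptive player should learn, over repeated play, to
swerve against the aggressive opponent and exploit the submissive one.

`chickrl` provides the machinery to study *which learning computation*
produces that adaptation: it simulates the task, fits a bank of candidate
trial-by-trial learning models by hierarchical Bayesian MCMC, compares them
by out-of-sample predictive accuracy, and validates the whole pipeline by
posterior predictive checks, model recovery and parameter recovery on
synthetic cohorts.

Two session layouts are built in. The blocked design (`make_design("study1")`)
gives 80 trials — each opponent in four contiguous blocks of 10, order
counterbalanced across subjects — with a simplified loss-free payoff matrix
(GS = 3, SS = SG = 1, GG = 0). The interleaved design
(`make_design("study2")`) gives 100 trials, 50 per opponent in uniformly
random order, with a full matrix including losses where a mutual crash
costs 30 points. Only the crash penalty and the ordering
GS > SS > SG > GG are fixed by the task description; the remaining full-matrix
entries default to (30, 10, −10, −30) and are fully configurable, and every
downstream formula is derived from the configured matrix rather than
hard-coded.

## The model bank

All models share a softmax choice rule on an expected-value difference
favouring swerve, $P(\text{swerve}) = \sigma(\beta \, EV + \theta)$, with
inverse temperature $\beta \in [0, 10]$ and (in the third variant of each
family) an additive swerve preference $\theta$. They differ in how $EV$ is
formed and updated:

* **Reward-based family (M1).** Rescorla–Wagner updating of own action
  values, $V \leftarrow V + \alpha (R - V)$, applied to the chosen action
  for the current opponent; $EV = V^{swerve} - V^{go}$. Variants: one
  learning rate (M1-1), opponent-specific rates $\alpha_h/\alpha_l$ (M1-2),
  plus preference (M1-3).
* **Belief-based family (M2).** Fictitious play: the subject tracks each
  opponent's swerve probability $p$ (initialised at 0.5),
  $p \leftarrow p + \alpha (O - p)$ with $O$ the observed opponent action,
  and values actions through the payoff matrix,
  $V^{swerve} = p\,SS + (1-p)\,SG$, $V^{go} = p\,GS + (1-p)\,GG$. Under the
  loss-free matrix this collapses to $EV = 1 - 3p$.
* **Second-order belief family (M3).** The belief update gains an influence
  term $\kappa (Q - q)$, where $Q$ is the subject's own action and $q$ the
  opponent's inferred probability that the subject swerves, obtained by
  inverting the subject's own softmax at the current belief:
  $q$ solves $\beta\,EV(q) = \mathrm{logit}(p)$. With the loss-free matrix
  this is exactly $q = 1/3 + \log((1-p)/p)/(3\beta)$; for any other matrix
  the package uses the generic linear inversion, which reduces to the
  closed form in that special case (checked to machine precision in the
  tests).
* **Baselines.** M0 is the delta rule with the learning rate pinned to 0 —
  with zero initial values it predicts a coin flip on every trial, making
  its $\beta$ unidentifiable; it is retained in this form deliberately as
  the chance anchor of the bank. M4-1/M4-2 are preference-only ablations of
  the reward and belief families: no updating, $EV$ frozen at its initial
  value (0, or the belief value at $p = 0.5$), so choice probability is the
  constant $\sigma(\beta EV_0 + \theta)$; here too $\beta$ and $\theta$
  trade off, which is accepted for fidelity to the ablation logic.

Design choices the equations leave open, decided once and used everywhere:

* The delta rule updates **only the chosen action's** value; the unchosen
  action is frozen. Only the chosen action yields a reward, and this is the
  standard convention; the alternative (updating both from one outcome) is
  not identifiable from these data anyway.
* Reward-family initial values are $V_0 = 0$ for both actions.
* Beliefs are clipped to $[10^{-6}, 1 - 10^{-6}]$ before the logit and
  after every second-order update, keeping the inversion finite.
* In the full-matrix design, rewards are divided by 10 (configurable via
  the design's `reward_scale`) before entering the delta rule, so that
  $\beta \in [0,10]$ spans comparable stochasticity in both designs. Belief
  families always work in raw matrix units, since their $EV$ comes from the
  matrix itself.
* Learning-rate selection in two-rate models keys on the trial's opponent
  ($\alpha_h$ for HCO trials, $\alpha_l$ for LCO).

## Synthetic cohorts

`generate_cohort()` stands in for a participant sample. Per-subject
parameters are drawn on the unconstrained scale from
$\mathcal N(\mu, \sigma)$ and pushed through the same probit bound mapping
the sampler uses, so the simulated population lives exactly in the space
inference assumes. Defaults are set once: raw-scale group means giving
learning rates around 0.31, inverse temperature around 2.1, influence
weight around 0.21 and swerve preference 0.3, with raw spread 0.5 — values
a practitioner would call ordinary for this class of task (moderate
learning, moderately deterministic choice, mild cooperative bias). Blocked
cohorts alternate the first opponent across subjects (even
counterbalancing); interleaved cohorts randomise each subject's schedule.

What the generator emulates: the trial counts, block structure,
counterbalancing, opponent Bernoulli policies and payoff assignment of the
two study designs, and between-subject parameter heterogeneity. What it
does not: response omissions in a timed window (the CSV reader drops and
counts such rows in real exports), reaction times, any drift in opponent
policy, and any model-misspecification gap between children's actual
computations and the bank. Passing recovery tests therefore certify the
*pipeline* — that the estimation machinery identifies models and parameters
when the generating process is in the bank — not that any particular model
is true of real children.

## Inference

`fit_hierarchical()` estimates subject parameters with a non-centered
hierarchy: $\phi_s^{raw} = \mu + \sigma z_s$, $z_s \sim \mathcal N(0,1)$,
mapped into bounds by $\Phi$; priors $\mu \sim \mathcal N(0, 1)$ and
$\sigma \sim \text{half-Cauchy}(0, 3)$ for every parameter (the preference
$\theta$ is modelled hierarchically like the rest and passes through the
identity instead of $\Phi$). The posterior is explored by univariate slice
sampling within a Gibbs sweep, with an ancillarity–sufficiency
interweaving step for the hyperparameters: after the likelihood-informed
non-centered moves, $\mu$ and $\sigma$ are resampled conditional on the
subject-level raw parameters (a likelihood-free conditional — conjugate
normal for $\mu$, a slice step for $\log\sigma$), which decouples the
hierarchical funnel that otherwise throttles mixing. A periodic
non-centered hyperparameter pass keeps small-$\sigma$ regimes mobile.

The full preset matches the study's sampler settings — 4 chains, 3000
warmup, 1000 retained iterations, 4000 draws — and the reduced `"ci"`
preset (2 chains, 500/500) is used for desk-scale and recovery work.
Convergence is judged by split-R̂ over all group- and subject-level
parameters with the usual 1.1 bound (`check_convergence()`); effective
sample sizes are reported alongside because they cost nothing. All
randomness flows through a single integer seed, so fits are bit-for-bit
reproducible.

Numerical notes: choice log-probabilities are computed as
$\log\sigma(\pm x)$ via `log1p`, exact even when $\beta\,EV$ reaches
hundreds of units in the full matrix; the probit inverse used to place
natural-scale values on the raw scale nudges inputs away from the exact
bounds (0.5% quantile clamp) so it stays finite.

## Model comparison

`psis_loo()` computes leave-one-out expected log predictive density at the
trial level from the retained pointwise log-likelihoods, with
Pareto-smoothed importance weights (generalized-Pareto tail fit by the
Zhang–Stephens profile estimator with the standard weak shape prior,
smoothed tail order statistics, truncation at the raw maximum) and the
conventional 0.7 flag on the tail shape. The implementation is checked in
the test suite against a frozen reference computed by an independent PSIS
implementation, and against the closed form for the chance baseline
(elpd = N·T·log 0.5 with zero SE).

`family_comparison()` reproduces the two-stage selection logic: stacking
weights (simplex-constrained maximisation of the pooled log predictive
density, softmax-parameterised from a uniform start so exact ties stay
uniform) aggregate each learning family internally; the stacked predictive
score of each family is compared across families; the winning family's
member with the lowest LOOIC is selected. The chance and preference-only
baselines are reported alongside but never win the contest. Differences
smaller than twice their standard error are labelled non-decisive, and
exactly tied families are reported as a tie rather than silently broken.
The family score — the stacked mixture's pooled leave-one-out density — is
one reasonable operationalisation of "family-level predictive support";
pooled all-model stacking weights are reported too for transparency.

## Validation

*Posterior predictive checks* condition on each subject's recorded
opponent-choice sequence and replay the subject model forward from sampled
posterior draws, correlating observed and simulated cooperation rates at
each within-opponent trial position (means across subjects, then across
replicates). Conditioning on the opponent record isolates the participant
model and keeps trials aligned; a resampling mode is available through the
simulator. Trial-level series use per-position means across subjects; when
either series has zero variance (the chance baseline predicts a flat 0.5
line) the correlation is reported missing with its cause rather than as a
number.

*Model recovery* (`model_recovery()`) simulates cohorts from each
generating model, fits all candidates, and tallies LOOIC winners into a
confusion matrix. *Parameter recovery* (`parameter_recovery()`) draws
ground-truth group parameters uniformly from each parameter's declared
range (the unbounded preference uses [−1, 1], matching its standard-normal
prior mass), simulates, refits, and correlates truths with recovered
posterior means across iterations; the full procedure uses 30 iterations,
and reduced runs are used for routine checking.

## Problem sizes used by the shipped checks

The package's own acceptance suite runs the analytic identities at full
precision (1001-point grids, 100 random short sessions per model against a
brute-force oracle) and the simulation-based guarantees at deliberately
modest scale, chosen as the smallest sizes at which the properties are
stable: parameter recovery with 40 subjects × 80 trials and 10 iterations
(the suite requires correlations above 0.7 for the two learning rates and
the temperature); model recovery over
{M0, M1-3, M2-3} with five 12-subject datasets per generator; and family
selection with five 16-subject replicates per direction, fitting all six
M1/M2 sub-models per replicate. The reduced sampler preset is used
throughout these loops.

## Known limitations

* The chance baseline's temperature and the preference-only baselines'
  temperature/preference trade-off are unidentifiable by construction;
  their posteriors follow the prior and only their likelihoods matter.
* Trial-level PSIS-LOO treats trials as the resampling unit; subjects are
  the exchangeable unit of the hierarchy, so subject-level LOO (grouping
  the pointwise matrix by subject before `psis_loo()`) is the stricter
  alternative when cohorts are large.
* The slice-within-Gibbs sampler is tuned for this model class (few
  bounded parameters per subject, cheap likelihood replays); it is not a
  general-purpose replacement for gradient-based samplers, and very small
  cohorts with the full-matrix design can leave heavy-tailed importance
  ratios (flagged by the Pareto-k diagnostics).
* With the full matrix and large $\beta$, belief-family choice
  probabilities saturate; the likelihood remains exact, but such regimes
  are near-deterministic and parameter recovery there is intrinsically
  harder.
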