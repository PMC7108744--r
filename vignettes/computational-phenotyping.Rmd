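---
title: "Computational phenotyping of reciprocal social adaptation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Computational phenotyping of reciprocal social adaptation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tomrep)
```

## The problem

Reciprocal social adaptation — continuously adjusting one's behaviour to an
opponent who is simultaneously adjusting to you — can be decomposed into
measurable computational constituents.  `tomrep` implements that
decomposition for repeated dyadic hide-and-seek games: 60-trial sessions of
a two-option, zero-sum game in which the seeker wins a trial by matching
the hider's choice.  A player faces one of four artificial opponents (a
biased pseudo-random schedule, or adaptive learners of calibrated
mentalizing sophistication), under one of two framings (the same game
presented as a social competition or as gambling), each condition played
twice — 16 sessions per participant.

From each session's binary choice sequence the package estimates which of
eight adaptation strategies the player used, by approximate Bayesian model
comparison, and condenses the 16 per-session model posteriors into two
*computational phenotypes* per participant:

* **repertoire flexibility** `f` — the posterior probability that the
  participant used *different* strategies in two conditions,
  `f = 1 - sum_m p(m | a1) p(m | a2)`, averaged over matched session
  pairs across framings (`f_framing`) or across repetitions
  (`f_repetitions`);
* **ToM sophistication** `k` — the posterior-expected depth of recursive
  belief, `k = sum_k k p(m = k-ToM | a)`, averaged per framing
  (`k_social`, `k_nonsocial`).

The contrasts `delta_f = f_framing - f_repetitions` (the "flexibility
gap") and `delta_k = k_social - k_nonsocial` quantify how much the social
framing, i.e. the belief that the opponent is a person with competitive
incentives, changes the participant's strategy selection.

## The behavioural repertoire

All agents share one decision rule: action 1 is chosen with probability
`sigmoid((dV + b) / beta)` where `dV` is the expected payoff difference
(`2 p_op - 1` for the seeker, its negative for the hider, `p_op` being the
predicted probability that the opponent plays 1), `beta > 0` the
behavioural temperature and `b` a constant option bias.  The eight models
differ only in how they form `dV`:

| model | free parameters | mechanism |
|---|---|---|
| BN | bias | biased Nash: `dV = 0`, choice driven by bias alone |
| WSLS | beta, bias | win-stay/lose-switch on the signed last reward |
| RL | alpha, beta, bias | Rescorla–Wagner value learning on own rewards |
| 0-ToM | sigma0, beta, bias | Bayesian tracking of the opponent's choice log-odds |
| Inf | eta, w, beta, bias | frequency tracking plus an influence correction |
| 1-/2-/3-ToM | sigma, beta, bias | recursive meta-Bayesian opponent models |

The 0-ToM learner assumes the opponent's choice log-odds `x` drifts with
volatility `sigma0` and updates a Gaussian belief variance-first:
`Sigma' = 1 / (1 / (Sigma + sigma0) + s(mu)(1 - s(mu)))`, then
`mu' = mu + Sigma' (a_op - s(mu))`.  A `k`-ToM learner (k >= 1) treats its
opponent as a `kappa`-ToM agent of unknown level `kappa < k`, whose own
volatility and temperature are the 2-dimensional hidden states
`x = (log sigma, log beta)`.  It maintains, per candidate level, a
Gaussian belief over `x` and a posterior simplex over levels, updated by
(i) reweighting levels by their predictive likelihood of the observed
action, (ii) moving each level's mean along the gradient `W` of that
level's predicted choice log-odds, scaled by the posterior covariance and
the prediction error, and (iii) a precision recursion that adds the
observation information `s'(v) lambda W W'` to the drift-inflated prior
precision.  The influence learner is the heuristic shortcut:
`p' = p + eta (a_op - p) + w p (1 - p) (1 - 2 a_self - beta logit(p))`,
clipped to `[1e-4, 1 - 1e-4]`.

## Numerical design of the mentalizing core

Three design choices in the k-ToM implementation deserve explanation;
they are what makes 3-ToM fitting tractable at cohort scale.

**Incremental simulated opponents.**  A level's predicted choice
probability is a function of the *entire* history; recomputing it by
replay every trial costs `O(t^{k+1})` per game and makes 3-ToM infeasible.
Instead each level keeps a bank of five simulated `kappa`-ToM opponents
run forward in lockstep at fixed offsets (`0`, `±1e-3` per coordinate)
around the current posterior mean of `x`; the gradient `W` is the central
difference across the bank.  `ktom_simulate_level()` retains exact replay
semantics and is the test oracle for the bank at short histories.

**Moment-matched sigmoid expectations.**  Posterior expectations of
sigmoids are approximated by `s(mu / sqrt(1 + 3 V / pi^2))`.  Against a
31-node Gauss–Hermite quadrature the worst error over
`mu in [-5, 5], V <= 8` is 0.021.

**Containment of the assumed-density filter.**  The hidden states of a
simulated opponent are weakly observable whenever play is close to the
mixed-strategy equilibrium: the gradient `W` then vanishes while the
volatility term keeps inflating the covariance, and the unchecked filter
diverges (the mean-update gain grows with the covariance, and the belief
escapes into "my opponent is random", destroying the agent's
decisiveness irreversibly).  The filter is therefore contained: covariance
eigenvalues are floored at `1e-8` (counted as repairs when a PD violation
is corrected) and capped at 4 (the prior scale); belief means are clamped
to `[-2, 2]` in log space, with the believed log-temperature capped at
0.7 — simulated opponents are assumed to stay motivated (`beta <= 2`)
rather than purely random.  These bounds apply identically at every
recursion level, so a 2-ToM's internal 1-ToM simulation remains an exact
image of a real 1-ToM with the same parameters.

**Approximation envelope of the 0-ToM update.**  The variance-first
update is a one-step assumed-density filter, not exact Bayes.  Against a
dense grid filter (domain `[-10, 10]`, step 0.01) the worst deviation of
the posterior-mean choice probability over 60-trial sequences grows with
the assumed drift: about 0.02 at `sigma0 = 0.05`, 0.04–0.054 at 0.1, 0.21
at 1.  The oracle tests therefore run in the slow-drift regime; at high
volatility the update is a deliberately coarse filter, not an
approximation to exact inference.

## Calibrated operating point

The package's default generative parameters
(`default_strategy_params()`) are `beta = 0.15`, `sigma = 0.1` (k >= 1),
`sigma0 = 1`, `alpha = 0.7`, `eta = 0.25`, `w = 0.6`, `bias = 0`.  Two
measurements drove these choices:

* **Exploitation margins scale with choice determinism.**  An oracle
  best-responder that knows a 0-ToM hider's exact parameters and belief
  earns a net correct rate of only ~0.02 at `beta = 1.5` but ~0.12 at
  `beta = 0.5`; pairwise orderings between agents are only measurable at
  low temperature.  At `beta = 0.15` the calibrated hierarchy is decisive
  over 200 games: 1-ToM beats 0-ToM (~+0.4), 2-ToM beats 1-ToM (~+0.03),
  influence learning beats 0-ToM (~+0.07) but loses badly to 1-ToM
  (~-0.3), and the unbiased Nash agent is within ±0.05 of zero against
  everyone.
* **Distinguishability requires decisive and non-degenerate agents.**  At
  high temperature an agent's choices are coin flips carrying no evidence
  about its strategy.  And at high `eta` the influence learner
  degenerates into copy-the-opponent's-last-action, which under this
  payoff is *exactly* win-stay/lose-switch; `eta = 0.25`, `w = 0.6` keeps
  its influence term, its signature, dominant.

Model recovery at this operating point (30 sessions per generating model,
played against the four-opponent battery) identifies BN, WSLS, RL and Inf
strictly in the large majority of sessions.  Three structural
near-equivalences remain, and are treated as documented confusion
clusters rather than failures:

* `{0-ToM, RL, WSLS}` — under the competitive payoff the value of an
  action tracks the opponent's choice frequency, so value learning and
  frequency tracking are near-indistinguishable (measured evidence gaps
  under 1 nat);
* `{RL, WSLS}` — RL with `alpha ~ 1` *is* win-stay/lose-switch;
* `{Inf, 1-ToM, 2-ToM, 3-ToM}` — adjacent mentalizing depths mimic one
  another: a k-ToM whose level posterior settles on `kappa` behaves
  exactly as a `(kappa + 1)`-ToM, and influence learning is the
  non-recursive shortcut of shallow mentalizing.

## Model comparison

Each session is fitted independently by every model.  Free parameters
live in an unconstrained space (`log` for volatilities and temperatures,
`logit` for rates and weights, identity for the bias) with independent
standard-normal priors — weakly informative, symmetric, and the same for
all models.  The log model evidence is approximated by MAP plus Laplace:
multi-start BFGS (first start at the prior mode, the rest drawn from the
prior under a fixed seed; ties keep the earlier start), then
`log p(a|m) ~ log p(a|theta*) + log prior(theta*) + d/2 log(2 pi) -
1/2 log det H` with `H` the negative Hessian at the MAP
(`stats::optimHess`).  A non-positive-definite `H` triggers a flagged
BIC-style fallback.  Because a binary sequence's likelihood cannot exceed
one, evidences are capped at zero (flagged when hit).  On one- and
two-parameter models the Laplace evidence sits within ~0.01 nats of dense
grid marginalization, well inside the 1-nat test band.  Model posteriors
are uniform-prior softmaxes of the evidences, computed with max
subtraction.

Cohort-scale sweeps (6144 evidences: 8 models x 48 participants x 16
sessions) use 2 restarts and 50 BFGS iterations per fit; spot checks
against the 8-restart default change posteriors negligibly because the
posterior modes of these small models are well separated.

## The synthetic cohort

No deposited data accompany the task, so the package ships a generative
cohort model that every downstream stage is tested against.  Each of the
48 participants (24 per group) carries a per-framing repertoire
(probability simplex over the eight strategies) and two switch rates; for
every opponent condition a true strategy is drawn for (non-social, rep 1),
re-drawn between repetitions with `switch_rate_repetition` and between
framings with `switch_rate_framing` (the latter couples the framings —
without it, independent draws would mechanically produce a large
cross-framing flexibility even for a group whose repertoire ignores the
framing).  Sessions are then played for real: the participant agent
(seeker) realizes its drawn strategy against the condition's opponent
(hider), all at the calibrated operating point.

The default **AS-like** profile is dominated by influence learning
(weight 0.65, the rest spread over WSLS/RL/0-ToM/1-ToM) with the *same*
repertoire in both framings and low switch rates (0.2/0.2): flexible
neither across framings nor repetitions, hence `delta_f ~ 0`.  The profile
is deliberately not a point mass: within-group variance in the true
phenotypes is what the symptom regression has to recover, and a
point-mass group would have no variance to explain.  The default
**NT-like** profile plays simple non-mentalizing strategies in the
non-social framing, mentalizing strategies (1-/2-ToM) in the social
framing, and switches freely (0.5 between repetitions, 0.9 between
framings).  These compositions are acknowledged stand-ins chosen for
recovery testing — the real quantitative repertoire of either group is
unknown.

Symptom scores follow a linear readout of the *true* phenotype
contrasts: `social = 10 - 3 delta_k - 5 delta_f + N(0, 1.5)`, rounded and
truncated at zero; the stereotyped-behaviour score is independent noise
(`N(5, 2)`), encoding the assumption that these phenotypes speak to
social, not repetitive, symptoms.

What the generator deliberately does not emulate: reaction times,
motivational or payoff-magnitude effects, timeouts, within-session
strategy switching, and any true between-subject variability in the
generative parameters themselves.  Passing end-to-end tests on this
cohort therefore demonstrates that the pipeline recovers the structure it
assumes — strategy mixtures, framing-coupled switching, linear
symptom coupling — not that real participants satisfy those assumptions.

## Cohort statistics

Group classification uses the eight performance features (net correct
rate per opponent x framing, averaged over repetitions), optionally
augmented with the four phenotypes; features are z-scored inside each
training fold only.  The classifier is an L2-regularized logistic
regression (`glmnet`, ridge, fixed penalty `1/n` — a plain classifier,
not a nested-tuned one, so the estimand stays comparable across feature
sets), evaluated by leave-one-out, with chance level assessed by
re-running the whole LOO loop on 1000 label permutations (add-one
corrected tail probability).  Note that leave-one-out accuracy is *not*
invariant to duplicating subjects — the duplicate's twin stays in the
training fold — so the tests assert the true direction (duplication
cannot decrease accuracy).  The symptom regression is OLS of the social
subscore on the four phenotypes within the AS-like group, with one-sided
univariate follow-ups on `delta_k` and `delta_f`.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use 60-trial sessions, 200
games per tournament pairing, 30 (tests) or 12 (script) recovery sessions
per generating model, 50 subjects for parameter recovery, and the full
24 + 24 cohort with 1000-permutation chance tests for the end-to-end run.
Every stochastic stage draws from an explicit seed, and each run
directory written by the command-line interface contains the
configuration that produced it; identical seeds give bit-identical
cohorts, fits and reports.

## Known limitations

* Adjacent mentalizing depths (and influence learning) are not separable
  from single 60-trial sessions; per-session sophistication estimates are
  only meaningful in aggregate.
* The k-ToM filter's containment bounds (covariance cap, mean clamps) are
  pragmatic stabilizers; outside them the assumed-density recursion is
  not a faithful approximation of exact inference, and the high-volatility
  0-ToM regime should be read as a heuristic filter rather than Bayes.
* The Laplace evidence is exact only to second order; its 1-nat agreement
  was verified for the low-dimensional models, and extrapolated, not
  verified, for the 3- and 4-parameter ones.
* All group-level conclusions are directional recoveries on synthetic
  cohorts, not quantitative reproductions of any empirical dataset.
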