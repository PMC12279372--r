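---
title: "Learning-rate dynamics in probabilistic reversal learning: models and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Learning-rate dynamics in probabilistic reversal learning}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(revlearn)
library(dplyr)
```

`revlearn` simulates and analyses a probabilistic reversal-learning task
with counterfactual feedback, fits a nested family of Pearce–Hall hybrid
reinforcement-learning models to trial-level choices, performs
random-effects Bayesian model selection, quantifies trial-by-trial
learning-rate dynamics, and implements a joint volatility/stochasticity
learner (a Kalman filter inside a particle filter) with a
stochasticity-lesioned variant. This vignette documents the models, their
assumptions, every tunable that matters, and the design decisions taken
where the design was genuinely open.

## The task

On each trial one of three stimuli appears and the agent either gambles
("play") or declines ("pass"). A play wins or loses 10 points according
to the stimulus's current reward contingency; a pass has no monetary
consequence but the forgone (fictive) outcome is still shown. Each
stimulus runs through 7 blocks of 30–35 of its own encounters with a
constant contingency drawn from {20, 30, 50, 70, 80}%; at every block
boundary the contingency changes without warning. With 3 stimuli this
yields 714 trials and 18 reversals. The contingency levels define three
outcome-noise regimes: *low* (20/80%), *high* (30/70%) and *random*
(50%).

`build_schedule()` realizes this design:

* **Block lengths** are drawn uniformly from the configured range under
  the constraint that each stimulus's blocks sum to exactly one third of
  the total (rejection sampling with a constructive fallback).
* **Stimulus order** interleaves the stimuli as consecutive shuffled
  rounds, so no stimulus is absent for more than 4 trials — emulating an
  intermixed pseudo-random series.
* **Contingency sequences** change at every boundary, give every
  stimulus both a good (>0.5) and a bad (<0.5) phase, and are
  counterbalanced across the whole schedule: every level is used a
  comparable number of times and good and bad blocks are matched to
  within two. Without the counterbalancing constraint, schedules
  occasionally come out good-heavy or bad-heavy, which visibly shifts
  attainable point totals and modulates group contrasts; the constraint
  pins the design to the balanced case a task designer would construct.
* **Outcome valences** are pre-drawn per trial, independent of the
  agent's action: factual feedback (after play) and fictive feedback
  (after pass) are two views of the same draw.

A fixed realization built from the documented seed 714 ships as
`inst/extdata/canonical_schedule.csv` (see
`canonical_task_schedule()`). It plays the role of the single fixed
pseudo-random series that all participants of a study would see — an
emulation of such a series, not a reconstruction of any particular one.

## The hybrid model family

Per stimulus $X$, expected value $Q_t(X)$ is updated from the reward
signal $R_t \in \{+1, -1\}$ (displayed as ±10 points):

$$Q_{t+1}(X_t) = Q_t(X_t) + \alpha_t \, \delta_t, \qquad
  \delta_t = R_t - Q_t(X_t).$$

The played option's value is biased, $V_B = B_\mathrm{play} + Q_t(X_t)$,
passing is worth 0, and choice follows a softmax with inverse
temperature $\beta$, so
$P(\mathrm{play}) = \mathrm{logistic}(\beta (B_\mathrm{play} + Q))$.

The learning rate is $\alpha_t = \kappa_t A_t$. The associability $A_t$
is a running average of surprise,

$$A_{t+1}(X_t) = \eta\,|\delta_t| + (1 - \eta)\,A_t(X_t),$$

and $\kappa_t$ is a logistic function of trial features:

* **M1** — no associability ($A \equiv 1$), $\kappa$ an intercept-only
  logistic: constant learning rate. Three parameters.
* **M2** — associability active, intercept-only $\kappa$. Four
  parameters.
* **M3** — adds a confirmatory-feedback predictor to $\kappa$:
  feedback is *confirmatory* when it supports the chosen policy (a
  factual win or a counterfactual loss), *disconfirmatory* otherwise.
  Five parameters.
* **M4** — adds a feedback-modality predictor (factual vs
  counterfactual). Six parameters.

Conventions, each of which the package documents and tests:

* **Initial values**: $Q_0 = 0$, $A_0 = 1$ per stimulus, so the first
  update of a stimulus uses $\alpha = \kappa$ and $\kappa$ is the
  initial learning rate. ($A_0$ is a convention; the interpretation of
  $\kappa$ as initial learning rate motivates 1.)
* **Update order** within a trial: choose → observe → update $Q$ with
  the *current* $A$ → update $A$ with $|\delta_t|$ for the stimulus's
  next encounter. The learning rate therefore depends on the absolute
  prediction error from the past encounter of that stimulus.
* **Counterfactual learning**: $Q$ is updated on pass trials from the
  fictive outcome; modality matters only through $\kappa$ in M4.
* **Predictor coding**: confirmatory and modality are coded ±0.5, so
  the $\kappa$ intercept is the grand-mean logit.
* **No cap on associability.** The recursion above is implemented
  exactly as written. Because $|\delta|$ can reach $1 + |Q|$, a large
  $\kappa$ together with a large $\eta$ lets $\alpha_t = \kappa A_t$
  exceed 1, at which point the value update overshoots, prediction
  errors grow, and the recursion destabilizes. This is a *feature* of
  the model, not a numerical accident: it is precisely the regime in
  which maximally surprise-driven learners fall apart on this task, and
  it produces the inverted-U relation between $\eta$ and payoff (best
  performance at low-to-intermediate $\eta$, collapse at the highest
  $\eta$) that motivates the whole analysis. An earlier design that
  capped $|\delta|$ at 1 (keeping $A \le 1$) was abandoned: with
  $A_0 = 1$, a cap makes raising $\eta$ strictly reduce every learning
  rate below its $\eta = 0$ level, so performance improves
  monotonically with $\eta$ and the inverted-U disappears. Purely as
  floating-point hygiene the state is clamped far outside the operating
  range ($|Q| \le 8$, $A \le 8$); behaviour near and beyond the
  stability boundary is unaffected.
* **Effective learning rates above 1** consequently occur in the
  unstable regime and are reported as computed; summaries of
  learning-rate *trajectories* (variability, peaks) use the raw values.

## MAP fitting and model selection

`fit_map()` maximizes the log posterior of the observed choices:
the choice log likelihood (with a $10^{-12}$ floor inside the log)
plus weak priors — Normal(0, 10²) on the play bias and the $\kappa$
weights, uniform on the boxes $\beta \in [0, 10]$ and
$\eta \in [0, 1]$ — so the MAP estimate is essentially a bounded
maximum-likelihood estimate. Optimization is multi-start (default 10
starts drawn uniformly in the box: $\beta$ [0, 10], play bias [−3, 3],
$\kappa$ weights [−10, 10], $\eta$ [0, 1]) bounded quasi-Newton
(`stats::nlminb`). `nlminb`'s conservative "false convergence" return at
flat or boundary optima is treated as normal termination; only
iteration-limit hits and errors mark a start as failed, and a fit is
flagged unconverged only when every start fails. The trial recursion
itself is compiled (Rcpp), and the identical code path serves
simulation and scoring, so simulating an agent and re-scoring its
choices reproduces the stored latent trajectories bit for bit.

Model comparison uses BIC, $k \ln n - 2 \ln \hat L$, with $-\tfrac12
\mathrm{BIC}$ as the per-subject log model evidence proxy. `bms()`
implements random-effects Bayesian model selection: model frequencies
get a Dirichlet(1) prior; a variational loop alternates subject
responsibilities and the Dirichlet update until `max |Δalpha| < 1e-6`
(at most 10⁴ iterations); exceedance probabilities come from 10⁵ seeded
Dirichlet draws; and the Bayes omnibus risk — the posterior probability
that all models are equally frequent — is computed from the variational
free energy of the frequency model against the equal-frequency null.
Protected exceedance probabilities are
$\mathrm{pxp} = (1 - \mathrm{bor})\,\mathrm{xp} + \mathrm{bor}/K$.

## Learning-rate-dynamics analyses

* **Correct choice**: play a good stimulus or pass a bad one; neutral
  (50%) stimuli have no correct response and are excluded from accuracy
  analyses (they are included in fitting).
* **Reversal-aligned curves** (`reversal_curves()`): mean probability
  correct by position 1–30 after each reversal, split by noise level,
  smoothed last with a ±2-trial running mean that shrinks at the edges.
  Smoothing is display/segmentation-side only — never applied before
  model fitting.
* **Structural breaks** (`detect_breaks()`): segmented least squares
  (per-segment intercept + slope) solved exactly by dynamic programming
  over all admissible placements with minimum segment length 5, the
  number of breaks selected by BIC with $2(m+1) + m$ effective
  parameters for $m$ breaks. For a 30-point curve this admits 0–5
  breaks. The named multiple-breakpoint test this emulates has
  additional tuning (trimming, sup-F sequencing); the BIC-over-exact-DP
  formulation keeps the same admissible-break grammar while staying
  fully reproducible, and a brute-force enumeration oracle verifies the
  DP in the tests. The early/late stage split takes positions 1..b vs
  b+1..30 from the first break (the canonical split used throughout is
  b = 10).
* **Learning-rate variability** (`lr_variability()`): per-subject
  population SD (divide by *n*) of $\alpha_t$ over a stage.
* **SNR** (`snr()`): mean learning-rate *peak* (maximum $\alpha$ over a
  stimulus's next 5 encounters) after true reversals, minus the mean
  peak after late-stage (positions 11+) misleading feedback — how well
  updating is reserved for real change. The peak window and the
  late-stage cutoff are package conventions; the contrast is invariant
  to adding a constant to all learning rates.
* **Misleading feedback**: a win for a bad stimulus or a loss for a
  good one. `double_misleading_accuracy()` finds two consecutive
  misleading outcomes on the same 30/70% stimulus late in a block and
  reports the probability that the next encounter is answered
  correctly.
* **Parameter→performance regression** (`performance_glm()`): OLS of
  total points on z-scored parameter estimates with normal-theory
  confidence intervals.
* **The η sweep** (`eta_sweep()`): simulate agents identical except for
  $\eta$ and record mean total points per grid value.

## The joint volatility/stochasticity learner

A drifting reward rate $x_t$ generates outcomes
$o_t \sim N(x_t, s_t)$; the drift variance is the volatility $v_t$ and
the observation variance the stochasticity $s_t$. Conditional on both,
tracking $x_t$ is a Kalman filter with gain
$\alpha_t = (w_t + v_t)/(w_t + v_t + s_t)$. The inverses $z = 1/v$,
$y = 1/s$ evolve multiplicatively, $z_t = \eta_v^{-1} z_{t-1}
\epsilon_t$ with $\epsilon_t \sim \mathrm{Beta}\!\big(\tfrac{\eta_v}
{2(1-\eta_v)}, \tfrac12\big)$, which has mean $\eta_v$, making the
propagation a martingale (the update rates are $\lambda = 1 - \eta$).
Inference is Rao-Blackwellized: a particle filter tracks $(z, y)$,
and each particle carries its own Kalman mean and variance. Per trial:
propagate; reweight by the Gaussian predictive density
$N(o_t \mid m^l, w^l + v^l + s^l)$ (multiplied into the running
weights, computed in log space); systematically resample when the
effective-sample-size ratio drops strictly below 0.5; apply the Kalman
update per particle. Reported trajectories are weight-averaged.

Defaults and decisions:

* $\lambda_v = \lambda_s = 0.1$, $v_0 = s_0 = 0.1$, 1000 particles
  (smaller counts are used in fast checks), Kalman state initialized at
  $m_0 = 0.5$ (the neutral rate), $w_0 = 0.1$. The update rates are
  mid-range values at which the estimates visibly track the task's
  regimes; they are configuration, not estimates.
* The Beta shape is taken as $\mathrm{Beta}(0.5\,\eta/(1-\eta),\,0.5)$,
  the only parameterization consistent with the stated mean property.
* **Lesioned variant**: stochasticity clamped to 0.001 on every
  particle; only volatility is inferred, so outcome noise is
  misattributed to volatility.
* **Task coupling**: each stimulus gets its own independent filter over
  its encounter sequence. The filter observes Gaussian outcomes
  centred on the scheduled reward probability with variance 0.01
  (low-noise blocks), 0.02 (high-noise) or 0.05 (random). Choices use
  the pre-outcome predicted rate $m$: at believed win rate $m$ the
  gamble's expected payoff on the ±1 reward scale is $2(m - 0.5)$, and
  play probability is $\mathrm{logistic}\big(3 \cdot 2(m-0.5)\big)$
  (decision noise 3 on the payoff scale). The *binary* win/loss
  feedback recorded for behavioural analyses and for re-fitting the
  hybrid model is the schedule's own pre-drawn valence — the feedback a
  learning agent in the task would actually see.
* At the task's outcome-noise settings the filter reliably separates
  the coarse regimes (estimated stochasticity in random blocks well
  above low-noise blocks); the 0.02-vs-0.01 contrast is at the edge of
  its resolution over 238 encounters.

## Synthetic cohorts

`generate_cohort()` draws labelled groups in a paired two-session
design. The associability step size is anchored at the group-level
means of the empirical winning model — low baseline performers 0.33
(placebo) vs 0.24 (drug), high performers 0.26 vs 0.23 — with the drug
acting as a fixed within-subject shift on $\eta$ *only*; all other
parameters are drawn once per subject and shared across sessions.
Between-subject SDs of $\eta$ are three times the printed standard
errors of those group means (0.06 and 0.03) — a generator convention,
since the source reports SEMs, not SDs.

The remaining parameters have no published values and are generator
choices, made once: $\kappa$ intercept 1.8 for low performers
(logistic ≈ 0.85 — fast learners whose stability boundary in $\eta$
sits near 0.28, so the placebo-level $\eta = 0.33$ is in the degraded
regime and the drug-level 0.24 is not) and 1.4 for high performers
(smoother learners, far from the boundary at their $\eta$ levels, hence
a null drug effect); confirmatory weight 1; $\beta$ = 2 (low) vs 3
(high); play bias 0.2 vs 0.1. These place the groups' simulated
learning curves, point totals and drug contrasts in the qualitative
regime the empirical study reports: the drug benefit concentrates in
low performers on high-noise blocks, and group-mean accuracy orders
high > low.

Two estimator notes for cohort-level contrasts:

* For simulated agents the probability of a correct choice is known
  per trial ($p_\mathrm{play}$ or its complement), so cohort accuracy
  contrasts in the validation scripts use this expected accuracy rather
  than re-sampled actions; it estimates the same quantity with much
  less Monte-Carlo noise.
* The drug-by-baseline contrast is modulated by the particular
  pseudo-random schedule realization (which contingencies land where),
  so validation averages it over several schedule realizations; single
  realizations of the design can and do flip the small high-performer
  contrast, and occasionally the low-performer one.

## What the generator does and does not emulate

The synthetic cohorts reproduce the task's structure, feedback rules,
group anchors and the paired-session design with known ground truth.
They do **not** emulate response times, missed/repeated trials,
practice effects across sessions, or any behaviour outside the model
family (working memory, choice perseveration beyond the play bias,
attention lapses). Consequently, passing recovery and direction checks
shows the pipeline is correct and well-identified *under the model*,
not that the model captures every aspect of real behaviour.

Two empirical regularities reported for human data do not emerge from
the generative family itself, and the package's validation reports them
honestly rather than forcing them:

* The reversal-vs-misleading learning-rate **SNR** contrast does not
  increase when $\eta$ is lowered in simulated cohorts: both peak terms
  scale with $\eta$, the reversal term faster. Across many cohort and
  schedule realizations the drug-induced SNR change is
  indistinguishable from zero. The human result was computed on fitted
  latents of real choices, which the model family only approximates.
* Re-fitting the hybrid model to choices simulated from the
  volatility/stochasticity learner recovers a **weakly identified**
  $\eta$: such agents are close to one-encounter-back learners, for
  which the constant-rate solution ($\eta = 0$, $A \equiv 1$) and the
  maximally dynamic solution fit near-equally (a flat likelihood
  ridge). Mean recovered $\eta$ for lesioned vs control agents
  therefore varies in sign across simulation batches. The lesion's
  *behavioural* signature — lower late-stage accuracy on high-noise
  blocks and inflated volatility estimates — is robust.

## Problem sizes

The shipped validation uses 714-trial datasets throughout; 50 subjects
for parameter recovery (10 optimizer starts), 20 subjects × {M1, M3}
for model selection, 200 agents per grid point for the η sweep,
cohorts of 30–40 subjects per group averaged over several schedule
realizations for the drug contrasts, 300-particle filters for the
lesion analyses (24 simulations per arm for the re-fit, 12 per arm for
accuracy), and exact $2^8$ enumeration for the likelihood
normalization oracle. These sizes were chosen so every check is
informative at desk scale while the full suite stays inside a coffee
break.
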