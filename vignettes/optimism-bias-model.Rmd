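---
title: "An active inference model of the optimism bias: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An active inference model of the optimism bias: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(optibias)
```

# The model

`optibias` implements a categorical partially observable Markov decision
process (POMDP) agent in the active inference tradition, together with
three simulation experiments that study the optimism bias: how it can be
lost in development, how it shows up as asymmetric belief updating, and
how it shapes engagement with a risky environment.

The agent's generative model consists of

* per-factor state priors $D$ with Dirichlet concentration counts $d$,
* per-modality likelihood mappings $A = p(o_\tau \mid s_\tau)$ with
  concentration counts $a$,
* per-factor transition mappings $B = p(s_\tau \mid s_{\tau-1}, \pi)$,
* log-domain outcome preferences $C$, and
* a set of one-step policies $\pi$.

The environment is a *generative process* with the same structure but its
own (true) parameters. Optimism is a two-state hidden factor
(optimistic/pessimistic); an agent whose optimism prior is
$D = [0.8, 0.2]$ is at optimism level $0.8$. The bias itself is a precise
likelihood mapping biased towards positive outcomes conditional on the
optimistic state: under the optimistic state the agent's likelihood for
good outcomes is sharper than the environment's, under the pessimistic
state the likelihood for bad outcomes is.

## State inference

Perception inverts the generative model by minimising marginal free
energy,

$$F_{\pi,\tau} = s_{\pi,\tau} \cdot \left( \ln s_{\pi,\tau}
  - \tfrac12\left(\ln B_{\pi} s_{\pi,\tau-1} + \ln B^{\dagger}_{\pi}
  s_{\pi,\tau+1}\right) - \ln A^{\mathsf T} o_\tau \right),$$

via the fixed-point iteration
$\varepsilon \leftarrow \ln A^{\mathsf T} o_\tau + \mathrm{avg}(\text{messages})
 - \ln s$, $v \leftarrow v + \varepsilon$, $s \leftarrow \sigma(v)$,
with at most 16 sweeps. Numerical and boundary choices, in order of how
much they matter:

* **Boundary messages.** At $\tau = 1$ the forward message is the log
  state prior $\ln D$; at $\tau = T$ there is no backward message. The
  transition term averages over the messages that exist (weight $1/2$
  each in the interior, full weight for a lone message). With a single
  timestep the fixed point is then exactly the Bayes posterior
  $s \propto D \odot A^{\mathsf T} o$ — the halved-singleton alternative
  would converge to $D^{1/2} \odot A^{\mathsf T} o$, which reproduces
  neither the uninformative-likelihood limit nor exact Bayes.
* **Sweep schedule.** The per-timestep update equations do not prescribe
  an order. A fully parallel sweep rings in an even/odd two-cycle around
  the fixed point; the package sweeps timesteps sequentially, which
  descends in $F$ (up to a small plateau) and converges in a handful of
  sweeps on the models used here.
* **Gauge fixing.** $\varepsilon$ is mean-centred before the $v$-update.
  Softmax is shift-invariant, and the raw error at the fixed point equals
  the log normaliser times a ones vector, so centring changes no
  posterior but makes the early-exit criterion
  $\max|\varepsilon| < 10^{-4}$ attainable.
* **Log floor.** Every logarithm is $\ln(x + 10^{-16})$; identity
  mappings contain exact zeros. In deeply peaked models the floor keeps
  raw $\varepsilon$ from vanishing on negligible states, so iteration
  also stops once the posterior moves less than $10^{-7}$ per sweep.
* **Step size.** The $v$-update uses the printed unit step; no learning
  rate is introduced. Residual ringing of order $10^{-3}$ in $F$ near
  the fixed point is the documented cost.
* **Initialisation.** $v$ starts at $\ln D$, which makes the
  uninformative-likelihood case exact at the first sweep.

One further point about $F$ itself: the scheme is marginal message
passing, whose fixed point approximately — not exactly — minimises the
$F$ functional above. On coherent observations (data drawn from the
model's own process) $F$ descends monotonically up to a small tolerance;
on deliberately contradictory observation sequences the equilibrium can
sit slightly above the initialisation. The test suite asserts descent on
coherent data, which is the regime all three experiments operate in.

## Policy selection

Policies are scored by expected free energy

$$G_\pi = \sum_\tau \Big( \underbrace{A s_{\pi,\tau} \cdot (\ln A
s_{\pi,\tau} - \ln C)}_{\text{risk}} \;+\;
\underbrace{-\,\mathrm{diag}(A^{\mathsf T} \ln A) \cdot
s_{\pi,\tau}}_{\text{ambiguity}} \;-\; \underbrace{A s_{\pi,\tau} \cdot W
s_{\pi,\tau}}_{\text{novelty}} \Big), \qquad
W = \tfrac12\big(a^{\odot(-1)} - a_{sums}^{\odot(-1)}\big),$$

and the policy posterior is $\pi = \sigma(-\gamma G)$. Two deliberate
readings:

* the softmax is applied to the *negated* $G$, so that policies with low
  expected free energy are preferred, consistent with $G$ being
  minimised (the compact notation $\pi = \sigma(G_\pi)$ leaves the sign
  implicit);
* preferences $C$ are stored as free real weights and softmax-normalised
  before the logarithm in the risk term. This makes risk a proper
  divergence (non-negative) and policy posteriors invariant to constant
  shifts of the preference weights, and it avoids $\ln 0$ for outcomes
  with no stated preference.

The policy precision $\gamma$ (inverse temperature) is 1 unless a task
configuration sets it; the bandit uses its calibrated value. Novelty is
computed only for modalities whose counts are learnable: a mapping locked
by a $\times 1000$ concentration scale should not generate epistemic
drive. Actions are sampled from the policy posterior by default
(`argmax` is available for deterministic tests).

## Learning

After each trial, learnable blocks accumulate concentration counts:
$a \mathrel{+}= \sum_t o_t \otimes s_t$ for likelihoods and
$d \mathrel{+}= s_{\tau=1}$ for state priors, one unit of mass per
timestep. Because the counts normalise to the expected distribution,
early observations move beliefs more than late ones — the
diminishing-influence property that drives order sensitivity in the
developmental simulation. Learning is applied per trial (batch over the
trial's timesteps), matching the trial-indexed update rules.

# Experiment 1 — losing optimism in development

A hierarchical two-level model simulates 200 agents through an in-silico
childhood: 5 state-level trials ("years"), each consuming 52 weekly
valence/arousal events. The observation level maps events to posteriors
through identity likelihood and transition mappings (so its posteriors
are effectively the event one-hots); those posteriors are the state
level's observations. The state level carries the optimism factor with
innate prior $[0.8, 0.2]$, a valence mapping locked at $\times 1000$
(positive valence more likely under the optimistic state, precision 0.8),
and a flat, learnable arousal mapping starting from 0.25 counts per cell.

Structural choices the numbers in the task description do not fix:

* **Year coupling.** Each year is one state-level trial: the 52 weekly
  posteriors enter as 52 sequential observations under an identity
  transition (the agent stays optimistic or pessimistic within the
  year); $d$ is updated once per year from the year's first-timestep
  posterior and the arousal counts from all 52 weeks. This preserves
  both printed trial counts and makes the state level learn more slowly
  than the observation level.
* **Environment statistics.** Each cohort agent draws its negative-event
  probability uniformly on $(0,1)$, covering the exposure range of the
  cohort figure. High arousal co-occurs with negative valence with
  probability `p_couple` (default 0.7; 0.5 makes arousal independent) and
  with positive valence with probability `p_high_arousal` (default 0.5).
* **Initial masses.** The optimism prior starts with one unit of count
  mass (`d_mass`), so five yearly updates can move the level
  substantially in either direction; the arousal mapping starts from
  weak flat counts so five years of data visibly shape it. Both are
  configuration parameters, since the innate mass is not something the
  task description pins down.

Because the sequential message passing attenuates evidence by half per
week of separation, a year's first-timestep posterior is dominated by the
prior and the early weeks of that year. This produces the two cohort
signatures: a strong negative rank correlation between negative-event
exposure and final optimism, and genuine spread at matched exposure (the
same event count in different orders yields different optimism) — there
is no one-to-one mapping from exposure to optimism.

# Experiment 2 — asymmetric belief updating

Each trial is a single-timestep model with two hidden factors: the
outcome belief (good/bad, learnable $d$, prior drawn per trial) and the
optimism factor (precise, locked, set to the agent's level). The news
modality's generative-process likelihood is the identity — the news is
what it is — while the generative model's likelihood is the
optimism-conditioned precision matrix

$$a(:,:,\text{optimistic}) = \begin{bmatrix} a_{good} & 1-a_{bad} \\
1-a_{good} & a_{bad} \end{bmatrix},$$

with the pessimistic slice swapping the two precision roles. Updates are
the printed differences of the normalised $d$ before and after the trial;
good-news updates are averaged over good-news trials only, bad-news over
bad-news trials only, and multiplied by 100. The printed difference is
negative when a belief strengthens, so the summary tables report the
positive strengthening percentage.

Decisions worth knowing:

* Trial priors are drawn uniformly on $[0.2, 0.8]$ (the draw is only
  described as random; bounding it keeps every prior away from the
  simplex boundary), and news is good or bad with equal probability.
* The same seeded trial stream is reused at every optimism level, so
  level contrasts are paired rather than independent — the monotonicity
  of the asymmetry in optimism is then visible without thousands of
  runs.
* The precision pair is *not* hard-coded: `sweep_precisions()` scores a
  9×9 grid by `asymmetry(0.9) − asymmetry(0.1) − 2·|asymmetry(0.5)|`
  (requiring positive asymmetry at 0.9) on a reduced simulation and the
  selected pair feeds the full experiment. Under the default seed the
  sweep selects $a_{good} = 0.45$, $a_{bad} = 0.95$. The asymmetry of the
  likelihood-ratio pair — good news diagnosticity
  $a_{good}/(1-a_{bad})$ against bad news diagnosticity
  $a_{bad}/(1-a_{good})$ — is what the criterion is really choosing:
  optimists must find good news diagnostic and bad news explainable-away.
* At level 0.5 the model is exchangeable under relabelling good↔bad by
  construction (the mixture of the two slices is symmetric), so
  near-zero asymmetry there is structural, not tuned.

# Experiment 3 — the modified two-armed bandit

Each of 60 trials is a two-timestep episode over a location factor
(start, left arm, right arm) and the optimism factor. The location
likelihood is the identity (locked); the reward modality has five
outcomes — large win (+\$4), small win (+\$1), null (\$0), small loss
(−\$1), large loss (−\$4) — and is learnable. The left arm emits only
large outcomes, the right arm only small ones, staying emits null.
Preferences are ordered large win > small win > null > small loss >
large loss with null fixed at zero. Under the optimistic state the agent
believes wins arrive with probability `q_optimistic` on either arm; under
the pessimistic state with `q_pessimistic`; the environment's true win
rates are `p_large_win` (left) and `p_small_win` (right), identical
across optimism states.

The true contingencies, believed precisions, preference magnitudes,
initial count mass and policy precision are not stated quantities; they
are calibration targets, fixed once against the qualitative results the
task is meant to reproduce (engagement rising with optimism, a net loss
for the most pessimistic agent, an interior optimum of winnings) and
shipped both as the `bandit_config()` defaults and as
`inst/extdata/bandit-calibrated.yaml`. The calibrated configuration sets
the large-stakes arm as the profitable one (60% large wins, expected
value +\$0.80 per pull) and the small-stakes arm as a mild trap (25%
small wins, −\$0.50 per pull).

The mechanism under this calibration is worth stating plainly.
Pessimists believe losses are likely under either arm; their early,
novelty-driven pulls land mostly on the small-stakes arm (pessimists
prefer small stakes) and deliver losses, after which they retreat to
the safe stay action and finish slightly below zero. Crucially, their
bias is self-sealing: the few wins they do see are credited to the
optimistic state — which they believe they are not in — so winning does
not re-engage them. Optimists show the mirror-image credit assignment:
wins accumulate in the optimistic-state column of the learned reward
counts and losses in the pessimistic-state one, so their belief in the
high-stakes arm survives loss streaks and they commit to it — the
explore-then-commit pattern, with engagement rising steeply between
levels 0.4 and 0.7. Beyond that the curve flattens and degrades
slightly: a strongly optimistic agent's outcome predictions are less
certain under its moderate believed precision, which produces
occasional opt-outs and residual sampling of the trap arm. The
per-trial policy posterior is sampled, so agents at the same level
differ by seed, and the location of the maximum within the
high-optimism range varies accordingly; under the shipped conditions
the median-winnings curve attains its maximum at level 0.7.

# What the generator emulates — and what it does not

The synthetic environments are the study conditions themselves: event
streams with controlled valence/arousal statistics, trial-wise random
priors with dichotomous news, and stochastic arm outcomes with fixed
contingencies. They deliberately do not emulate content semantics of
life events, non-stationary environments, individual differences beyond
the optimism level, or the empirical human data the belief-updating task
is usually compared against. Passing tests therefore demonstrate the
internal mechanics of the bias — acquisition, expression, and action —
under idealised statistics, not parameter recovery from human
behaviour.

# Problem sizes and determinism

The shipped experiment sizes are those of the study conditions: 200
agents × 52 × 5 events (experiment 1), 70 runs × 70 trials per optimism
level (experiment 2), and 60 trials × 25 seeds per level (experiment 3).
The unit-test suite uses reduced sizes of the same generators where a
property does not need the full cohort. Every entry point takes a master
seed; cohort members draw per-agent seeds derived from it, so any single
agent is reproducible in isolation, and result files embed the seed and
a configuration hash so identical runs are byte-identical.

# Known limitations

* The policy-tree depth is one: the three experiments need only
  single-move policies, and no deep planning is implemented.
* `B`-matrix and `C` learning are not implemented (unused by the
  experiments); `d` learning is per-trial, not within-trial.
* The bandit's interior optimum is a property of the shipped calibrated
  configuration (and a neighbourhood of it), not of every configuration:
  with a sufficiently dominant high-stakes arm the winnings curve
  flattens into a plateau across high optimism levels.
* The marginal-message fixed point approximately minimises the stated
  $F$; the discrepancy is far below any quantity interpreted in the
  experiments but visible if one instruments $F$ per sweep on
  adversarial data.
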