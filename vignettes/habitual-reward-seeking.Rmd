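---
title: "TD learning of habitual reward-seeking with reduced successor representations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TD learning of habitual reward-seeking with reduced successor representations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(habitsr)
```

## The task and the policies

`habitsr` simulates a stylised habitual routine: a linear chain of states
$S_1, \dots, S_n$ with a reward $R$ obtained at the goal $S_n$.  At every
pre-goal state the agent chooses *Go* (advance one state) or *No-Go* (stay).
The behavior policy is exogenous and fixed — this is a deliberate modelling
choice, not an omission: the point is to study what the learned *values*
and *prediction errors* do while behavior is held at a given level of
resistance, so choice probabilities never depend on the learned values.
Two policies are compared:

* **Non-Resistant** — always Go.  The episode is deterministic
  ($n-1$ steps), and the true values are $V(S_k) = R\gamma^{\,n-k}$.
* **Resistant** — No-Go with fixed probability $P_{\text{No-Go}}$ at every
  pre-goal state.  The number of No-Go repeats per visited state is
  geometric with mean $p/(1-p)$, so goal-reaching takes longer and the
  Non-Resistant values overestimate every state.

Each episode is preceded by an *initiation* event: its RPE equals
$\gamma V(S_1)$, interpreted as the learned value of the cue that triggers
the routine.  No learning update is attached to it — there is no
predecessor state whose representation could be credited — it is logged
only.

## The four value learners

All learners are TD learners: at each time step the RPE
$\delta = R(S(t)) + \gamma V(S(t+1)) - V(S(t))$ is computed from pre-update
quantities, then the update is applied, then the next action is sampled.
The bootstrap term is dropped when $S(t)$ is the goal (unless a punishment
state follows) and at the punishment state itself.

* **Punctate** (`td_learner`): each state holds its own value,
  $V(S_k) \mathrel{+}= \alpha\delta$.  This is the non-addicted reference:
  under resistance the values re-converge to the on-policy truth and the
  goal RPE stays at zero (the goal value is pinned at $R$, an exact fixed
  point).
* **Rigid goal-based reduced SR** (`reduced_sr_learner`): each state is a
  single scalar feature $x(S_k) = \gamma^{\,n-k}$, the discounted future
  occupancy of the goal under the Non-Resistant policy, and
  $V \approx w\,x$ with $w \mathrel{+}= \alpha\, x(S(t))\,\delta$.  The
  representation itself is frozen — the operationalisation of an addicted,
  unupdatable habit representation.  Algebraically every Go step has
  $\gamma x(S_{k+1}) = x(S_k)$, so Go RPEs vanish for *any* $w$; No-Go
  steps push $w$ down and the goal event pushes it back up, so $w$ settles
  below $R$ and a sustained positive goal RPE remains in every episode.
  We do not model how this representation formed; runs start from its
  completed state ($w = R$).
* **Adaptive reduced SR** (`alpha_feature > 0`): the features themselves
  also learn by their own TD rule
  $x(S(t)) \mathrel{+}= \alpha_f(\gamma x(S(t+1)) - x(S(t)))$, except the
  goal feature, whose error is identically zero and which stays frozen at
  1.  Both $\delta$ and $\delta_{\text{feature}}$ are computed from the
  same pre-update $(w, x)$ snapshot, which makes the order of the two
  updates immaterial — the source texts for this model class leave the
  order unstated, so we chose the order-free convention.  The coefficient
  $w$ continues to update with $\alpha$ while features adapt; the evolving
  RPE patterns require it (with $w$ frozen at $R$ nothing would relax).
* **Genuine SR** (`genuine_sr_learner`): the full successor representation
  $x_j(S_k) = \gamma^{\,j-k}$ for $j \ge k$, with
  $V \approx \sum_j w_j x_j$ and
  $w_j \mathrel{+}= \alpha\, x_j(S(t))\,\delta$.  Starting from
  $w = (0,\dots,0,R)$ the approximation is exact for the Non-Resistant
  policy.  Under resistance the pre-goal coefficients turn negative — the
  extra dimensions let the learner represent the on-policy devaluation even
  though the features themselves stay Non-Resistant.  The feature matrix is
  not learned (that is the comparison being made: representation quality,
  not representation learning).

### Punishment

The punishment scenario appends a state $S_{n+1}$ after the goal delivering
a negative reward (default $-2$) under the Non-Resistant policy.  For the
punctate learner the negative RPE propagates back and the cue value
eventually approaches $\gamma^n(R + \gamma\,R_{n+1})$, turning negative for
a large enough punishment.  For the reduced SR the feature of $S_{n+1}$ is
0 — the backward transition has never been experienced — so the punishment
RPE multiplies a zero feature and $w$ is *bit-identical* before and after
any number of punished episodes: complete insensitivity to consequences
after the goal.  Punishment is only defined for these two learners under
the Non-Resistant policy; other combinations are rejected rather than
given improvised semantics (in particular the adaptive feature rule at a
terminal-after-goal state never arises in any simulated scenario and is
deliberately unimplemented).

## The dual-system model

`dual_system()` couples a punctate Go/No-Go action-value learner to a
state-value companion whose RPE arrives through the ventral-to-dorsal
spiral striatum–midbrain pathway.  Action values start at the
Non-Resistant truths, $Q(\text{Go}_{S_k}) = R\gamma^{\,n-1-k}$, with No-Go
values one step more discounted.  At each time step the action RPE is
Q-learning-type (max over the current state's two actions) or SARSA-type
(the action actually chosen), with the middle term dropped at the goal and
the last term dropped at the episode's initial step; the value of the
action taken at $t-1$ is then updated by
$\alpha[(1-\kappa)\delta_{\text{action}} + \kappa\,\delta_{\text{state}}]$.

Two conventions matter and are worth stating explicitly:

* The companion keeps learning its own coefficient during the run.  Only
  its initial condition is fixed; the value inflation at the pre-goal state
  exists precisely because the companion's $w$ falls below $R$ and its goal
  RPE turns positive.
* A No-Go at $S_k$ leaves the agent at $S_k$, so the pending credit points
  at (No-Go, $S_k$) and the *next* step's RPE updates that same action.
  This one-step credit offset is why the punctate-state companion behaves
  differently from the punctate system on its own: its positive Go RPEs
  and negative No-Go RPEs land on the *previous* action, not the chosen
  one, and the Go/No-Go difference does not grow with $\kappa$.

With $\kappa = 0$ and Q-learning RPEs the initial action values are an
exact algebraic fixed point (every RPE with a previous action is zero), a
property the implementation preserves bitwise — see below.

## Multi-simulation experiments and aggregation

`run_config()` + `run_simulation()` run `n_sims` independent simulations;
simulation $i$ is seeded `base_seed + i`, so runs are bit-reproducible and
individual simulations can be reproduced in isolation.  The Non-Resistant
presets use a single simulation (the dynamics are deterministic); the
Resistant presets default to 100 simulations.

`aggregate_rpes()` applies the summary conventions: No-Go RPEs recurring at
the same state within an episode are first averaged (and separately
summed) within each simulation; simulations with no No-Go at a given
(state, episode) cell are excluded from that cell's No-Go statistics —
exclusion is per cell, since which simulations lack a No-Go differs from
case to case; initiation, Go and goal events occur exactly once per episode
and use all simulations.  SDs are sample SDs and are reported as `NA` below
two contributors.  The dual-system summaries average the end-of-episode
action values over episodes 41–60 within each simulation before averaging
across simulations.

Episode counts not pinned by the experiment itself default to 60 (30 for
the naive Non-Resistant run, 25 where only the 25th episode is analysed,
200 for the adaptive-feature run); "episode 25" statistics are computed on
that episode's records alone, not a window, except the dual-system window
above.  All defaults are overridable.

## Numerical choices

* **Exact zero Go-RPEs.**  Discount ladders ($x$, the genuine-SR feature
  diagonals, the initial action values) are built by explicit backward
  multiplication ($x_k = \gamma\,x_{k+1}$) rather than `gamma^(n-k)` or
  `cumprod()` — R's `cumprod()` accumulates in extended precision, which
  breaks the bitwise identity $\gamma x_{k+1} = x_k$.  The reduced-SR RPE
  is computed in the factored form $R + w(\gamma x_{t+1} - x_t)$.  Together
  these make Go-step RPEs *exactly* zero in floating point for any $w$
  (comfortably inside the intended $|\delta| < 10^{-12}$ band), and the
  bit-invariance claims (punishment insensitivity of $w$; the
  $\kappa = 0$ Q-learning fixed point) hold exactly rather than
  approximately.
* **Update timing.**  One learner step per environment step; RPE from
  pre-update values; updates applied before the next action is drawn.
* **Degenerate inputs.**  $P_{\text{No-Go}} = 1$ never terminates; a
  configurable per-episode step cap (default $10^6$) raises an error
  instead of hanging.  Chains need $n \ge 2$ and $0 < \gamma < 1$.

## What the simulations do and do not establish

The generator *is* the model: synthetic episodes under the stated policies
and parameters ($n = 10$, $R = 1$, $\gamma = 0.97$,
$P_{\text{No-Go}} \in \{0.5, 0.75, 0.9\}$, $\alpha = 0.5$,
$\alpha_f = 0.05$, punishment $-2$, $\kappa \in \{0, 0.2, 0.4\}$, 100
simulations).  A green test establishes that the implementation reproduces
the model's internal logic — closed forms, fixed points, oracle-matched
stochastic means, orderings across conditions — not that the model
describes any organism.  Real routines have heterogeneous state durations,
non-exponential discounting, stochastic transitions and value-driven
choice, none of which are represented here; the chain is a minimal stage
for comparing state representations.

## Known limitations

* Choice is never value-driven; the dual-system action values influence
  nothing downstream.  The model stops where value inflation is
  demonstrated.
* The formation of the reduced SR is not modelled, only its consequences.
* The genuine-SR feature matrix is fixed to its Non-Resistant form.
* Punishment semantics exist only for the punctate and reduced-SR learners
  under the Non-Resistant policy.
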