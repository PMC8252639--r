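# habitsr

Reinforcement-learning simulation of habitual reward-seeking on a linear
chain of states, for computational-neuroscience and computational-psychiatry
work on why resisting an ingrained reward-obtaining routine can be so hard.

## The model

A routine (e.g. the walk to a favourite pub) is a chain of states
`S_1, ..., S_n` (default `n = 10`) ending in a rewarded goal (`R = 1`).  At
every pre-goal state the agent either **Go** (advance) or **No-Go** (stay).
Two fixed behavior policies are compared: *Non-Resistant* (always Go) and
*Resistant* (No-Go with probability `P_No-Go`, usually 0.75).  Under the
Non-Resistant policy the true values are `V(S_k) = R γ^(n−k)` with discount
`γ = 0.97`.

Value learning is temporal-difference (TD) throughout: every time step
generates a reward prediction error (RPE)

```
δ = R(S(t)) + γ V(S(t+1)) − V(S(t))
```

— the signal carried by dopamine — and `δ` drives the update of whatever
parametrises `V`.  Four state representations are implemented:

| architecture | representation | update |
|---|---|---|
| punctate | each state has its own `V(S_k)` | `V(S_k) += α δ` |
| rigid reduced SR | scalar feature `x(S_k) = γ^(n−k)` (discounted future occupancy of the goal), `V ≈ w·x` | `w += α x(S(t)) δ`; features frozen |
| adaptive reduced SR | as above, but features also learn | additionally `x(S(t)) += α_feature (γ x(S(t+1)) − x(S(t)))` |
| genuine SR | full successor representation `x_j(S_k) = γ^(j−k)` (j ≥ k), `V ≈ Σ w_j x_j` | `w_j += α x_j(S(t)) δ` |

The rigid reduced SR operationalises the *addicted* case: a goal-based,
dimension-reduced successor representation formed under long non-resistant
use that can no longer be updated.  Its signature is a **sustained positive
RPE at the goal** once the agent starts resisting, a weaker decline of the
cue value (the initiation RPE `γV(S_1)`), and complete insensitivity to a
punishment state appended after the goal (its feature is 0, so no update
ever reaches `w`).

A dual-system model additionally couples a punctate Go/No-Go action-value
learner (Q-learning- or SARSA-type RPE) to one of the state-value systems
through the spiral striatum–midbrain circuit: the action taken at `t − 1`
is updated by `α[(1 − κ) δ_action + κ δ_state]` with mixing weight
`κ ∈ {0, 0.2, 0.4}`.  With the rigid-reduced-SR companion the Go/No-Go
value difference inflates with `κ`; with the punctate companion it does
not.

## Worked example

The addicted signature at the 25th Resistant episode (100 simulations):

```r
library(habitsr)
spec <- chain_spec()                      # n = 10, R = 1, gamma = 0.97
cfg <- run_config(spec, policy_spec("resistant", 0.75),
                  learner = "reduced_sr", episodes = 25, n_sims = 100,
                  base_seed = 1)
run <- run_simulation(cfg)
agg <- aggregate_rpes(run)
dplyr::filter(agg, episode == 25,
              rpe_kind %in% c("initiation", "goal", "no_go_mean"))
#> # A tibble: 11 × 6
#>    episode state rpe_kind      mean       sd n_included
#>      <int> <int> <chr>        <dbl>    <dbl>      <int>
#>  1      25     0 initiation  0.589  0.0237          100
#>  2      25     1 no_go_mean -0.0180 0.000800         71
#>  ...
#> 11      25    10 goal        0.407  0.0732          100
```

Reading this: after 25 episodes of resistance the goal still elicits a
large positive mean RPE (0.407 ± 0.073) — the sustained error that cannot
be trained away because the rigid representation misestimates the slowed
progress — while every No-Go produces a small negative RPE (≈ −0.018) and
the cue value has only dropped from `γ^10 ≈ 0.737` to 0.589.  The same
configuration with `learner = "punctate"` gives a goal RPE of exactly 0.
`n_included` < 100 in the No-Go rows because simulations without a No-Go at
that state in that episode are excluded from that cell.

Scenario presets reproduce each figure-style experiment
(`list_scenarios()`; `run_scenario("fig8")`, ...), `autoplot()` and the
`plot_*()` helpers draw them, and a command-line interface is available:

```sh
Rscript inst/cli/habitsr scenario fig3 --seed 1 --out-dir out/
```

## Acceptance script

`scripts/acceptance.R` re-runs the package's main computation from scratch
— the scenario presets for the punctate, rigid reduced-SR, cue-value,
punishment, genuine-SR and dual-system experiments — under a given seed and
writes its result summary as JSON:

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```
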