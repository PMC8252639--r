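Package: habitsr
Title: Temporal-Difference Simulation of Habitual Reward-Seeking with
    Goal-Based Reduced Successor Representations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: Simulates temporal-difference (TD) value learning on a linear
    chain of states leading to a rewarded goal, under a Non-Resistant policy
    (always Go) or a Resistant policy (No-Go with fixed probability), across
    four state-representation architectures: punctate (individual) states, a
    rigid goal-based reduced successor representation (SR), a reduced SR whose
    scalar features themselves adapt slowly by TD learning, and the genuine
    (full) SR.  Also implements a dual-system model in which reward prediction
    errors (RPEs) from a state-value system are mixed, with weight kappa, into
    the updates of a punctate Go/No-Go action-value learner of Q-learning or
    SARSA type, emulating ventral-to-dorsal spiral striatum-midbrain
    influence.  Provides multi-simulation experiment runners, figure-style
    scenario presets, RPE aggregation with within-episode averaging/summation
    and per-cell exclusion conventions, tidiers, ggplot2 plotting helpers, and
    a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
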