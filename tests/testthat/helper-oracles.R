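# Independent oracles, coded from the update algebra directly and kept
# separate from the package's event loop.

# Punctate learner, Non-Resistant policy, zero initial values: the goal value
# is only ever touched at the goal event (bootstrap dropped there), so the
# per-episode goal RPE follows a one-dimensional recursion.
oracle_naive_goal_rpes <- function(episodes, R = 1, alpha = 0.5) {
  v <- 0
  rpes <- numeric(episodes)
  for (m in seq_len(episodes)) {
    rpes[m] <- R - v
    v <- v + alpha * (R - v)
  }
  rpes
}

# Bellman-backup iteration for the punctate chain with a punishment state
# under the Non-Resistant policy; returns the fixed-point state values.
oracle_punishment_values <- function(n = 10, R = 1, gamma = 0.97,
                                     punishment = -2, iters = 200) {
  v <- c(R * gamma^(n - seq_len(n)), 0)
  for (i in seq_len(iters)) {
    nxt <- v
    nxt[n + 1] <- punishment
    nxt[n] <- R + gamma * v[n + 1]
    for (k in seq_len(n - 1)) nxt[k] <- gamma * v[k + 1]
    v <- nxt
  }
  v
}

# Brute-force re-simulation of the rigid reduced SR under the Resistant
# policy, vectorised across simulations.  Go steps leave w unchanged (their
# RPE is zero for any w); each No-Go at S_k multiplies w by
# 1 + alpha * x_k^2 * (gamma - 1), with the per-state No-Go repeat count
# geometric; the goal event does w <- w + alpha * (R - w).  Returns the
# per-simulation goal RPE of the final episode.
oracle_reduced_sr_goal_rpes <- function(n_sims, at_episode, n = 10, R = 1,
                                        gamma = 0.97, alpha = 0.5,
                                        p_no_go = 0.75) {
  x <- gamma^(n - seq_len(n - 1))
  fac <- 1 + alpha * x^2 * (gamma - 1)
  w <- rep(R, n_sims)
  goal_rpe <- numeric(n_sims)
  for (ep in seq_len(at_episode)) {
    for (k in seq_len(n - 1)) {
      reps <- stats::rgeom(n_sims, 1 - p_no_go)
      w <- w * fac[k]^reps
    }
    goal_rpe <- R - w
    w <- w + alpha * (R - w)
  }
  goal_rpe
}
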