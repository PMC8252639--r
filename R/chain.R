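#' Define the linear chain task
#'
#' A reward-seeking episode is modelled as a linear chain of states
#' `S_1, ..., S_n`: the agent starts at `S_1`, can either "Go" (advance to the
#' next state) or "No-Go" (stay put) at every pre-goal state, and obtains a
#' reward of size `reward_size` on arriving at the goal state `S_n`.
#' Optionally a punishment state `S_{n+1}` follows the goal deterministically
#' and delivers `punishment_size` (a non-positive reward), which is how
#' insensitivity to adverse consequences is probed.
#'
#' @param n_states Number of states from start to goal (default 10).
#' @param reward_size Reward delivered at the goal state (default 1).
#' @param gamma Temporal discount factor in (0, 1) (default 0.97).
#' @param punishment_size Reward (<= 0) delivered at the post-goal state
#'   `S_{n+1}`; only meaningful when `has_punishment = TRUE`.
#' @param has_punishment If `TRUE`, a terminal punishment state `S_{n+1}` is
#'   appended after the goal and reached deterministically from it.
#'
#' @return An object of class `chain_spec`: a list with the validated fields.
#' @examples
#' chain_spec()
#' chain_spec(has_punishment = TRUE, punishment_size = -2)
#' @export
chain_spec <- function(n_states = 10, reward_size = 1, gamma = 0.97,
                       punishment_size = 0, has_punishment = FALSE) {
  stopifnot(
    is.numeric(n_states), length(n_states) == 1, n_states >= 2,
    n_states == as.integer(n_states),
    is.numeric(gamma), length(gamma) == 1, gamma > 0, gamma < 1,
    is.numeric(reward_size), length(reward_size) == 1, reward_size > 0,
    is.numeric(punishment_size), length(punishment_size) == 1,
    punishment_size <= 0,
    is.logical(has_punishment), length(has_punishment) == 1
  )
  if (!has_punishment) punishment_size <- 0
  structure(
    list(
      n_states = as.integer(n_states),
      reward_size = reward_size,
      gamma = gamma,
      punishment_size = punishment_size,
      has_punishment = has_punishment
    ),
    class = "chain_spec"
  )
}

#' @export
print.chain_spec <- function(x, ...) {
  cat(sprintf(
    "<chain_spec> n = %d, R = %g, gamma = %g%s\n",
    x$n_states, x$reward_size, x$gamma,
    if (x$has_punishment) {
      sprintf(", punishment %g at S_%d", x$punishment_size, x$n_states + 1L)
    } else ""
  ))
  invisible(x)
}

#' Define a behavior policy on the chain
#'
#' Two exogenously fixed policies are considered: the Non-Resistant policy
#' always chooses "Go", while the Resistant policy chooses "No-Go" (stay at
#' the same state) with a fixed probability `p_no_go` at every pre-goal
#' state.  Choice probabilities never depend on learned values.
#'
#' @param kind `"non_resistant"` or `"resistant"`.
#' @param p_no_go Probability of choosing No-Go at each pre-goal state; must
#'   be 0 for the Non-Resistant policy.  The Resistant policy is typically
#'   run with 0.75 (0.5 and 0.9 are also standard settings).
#'
#' @return An object of class `policy_spec`.
#' @examples
#' policy_spec("resistant", p_no_go = 0.75)
#' @export
policy_spec <- function(kind = c("non_resistant", "resistant"),
                        p_no_go = if (kind == "resistant") 0.75 else 0) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(p_no_go), length(p_no_go) == 1,
            p_no_go >= 0, p_no_go <= 1)
  if (kind == "non_resistant" && p_no_go != 0) {
    stop("the Non-Resistant policy must have p_no_go = 0", call. = FALSE)
  }
  structure(list(kind = kind, p_no_go = p_no_go), class = "policy_spec")
}

#' @export
print.policy_spec <- function(x, ...) {
  cat(sprintf("<policy_spec> %s (P_No-Go = %g)\n", x$kind, x$p_no_go))
  invisible(x)
}

#' Sample one Go/No-Go choice from a policy
#'
#' Consumes exactly one uniform draw from the current RNG stream and returns
#' `"no_go"` with probability `p_no_go`, `"go"` otherwise.
#'
#' @param policy A [policy_spec()].
#' @return `"go"` or `"no_go"`.
#' @export
sample_action <- function(policy) {
  stopifnot(inherits(policy, "policy_spec"))
  if (stats::runif(1) < policy$p_no_go) "no_go" else "go"
}

#' Single-step transition dynamics of the chain
#'
#' "Go" at `S_k` (k < n) advances to `S_{k+1}`; "No-Go" stays at `S_k`.  The
#' goal state delivers `reward_size` on arrival and is terminal unless a
#' punishment state follows, in which case `S_n -> S_{n+1}` happens
#' deterministically (no action) and delivers `punishment_size`.
#'
#' @param spec A [chain_spec()].
#' @param state Current state index (1-based; the goal is `n_states`).
#' @param action `"go"` or `"no_go"`; ignored at the goal state when a
#'   punishment state follows.
#' @return A list with `next_state`, `reward` (delivered on arrival at
#'   `next_state`), and `terminal`.
#' @examples
#' transition(chain_spec(), 9, "go")   # arrive at the goal, reward 1
#' @export
transition <- function(spec, state, action = c("go", "no_go")) {
  stopifnot(inherits(spec, "chain_spec"))
  n <- spec$n_states
  if (state == n) {
    if (!spec$has_punishment) {
      stop("the goal state is terminal; no transition is possible",
           call. = FALSE)
    }
    return(list(next_state = n + 1L, reward = spec$punishment_size,
                terminal = TRUE))
  }
  if (state > n) stop("the punishment state is terminal", call. = FALSE)
  action <- match.arg(action)
  if (action == "no_go") {
    list(next_state = as.integer(state), reward = 0, terminal = FALSE)
  } else {
    nxt <- as.integer(state) + 1L
    list(next_state = nxt,
         reward = if (nxt == n) spec$reward_size else 0,
         terminal = nxt == n && !spec$has_punishment)
  }
}

# Reward attached to occupying a state: R at the goal, the punishment size at
# S_{n+1}, 0 elsewhere.  This is the R(S(t)) entering every RPE.
reward_at <- function(spec, state) {
  if (state == spec$n_states) {
    spec$reward_size
  } else if (state == spec$n_states + 1L) {
    spec$punishment_size
  } else {
    0
  }
}

# gamma^(n-k) for k = 1..n, built by backward cumulative multiplication
# (x[n] = 1, x[k] = gamma * x[k+1]) so that gamma * x[k+1] equals x[k]
# bit-for-bit; Go-step RPEs in the reduced SR are then exactly zero.
# (explicit loop: cumprod() accumulates in extended precision and would
# break the bitwise identity)
discount_to_goal <- function(gamma, n) {
  x <- numeric(n)
  x[n] <- 1
  for (k in rev(seq_len(n - 1L))) x[k] <- gamma * x[k + 1L]
  x
}

# gamma^(0:(n-1)) with the same sequential-product guarantee
discount_powers <- function(gamma, n) {
  g <- numeric(n)
  g[1] <- 1
  for (i in seq_len(n - 1L)) g[i + 1L] <- gamma * g[i]
  g
}

#' True state values under the Non-Resistant policy
#'
#' Under the always-Go policy the chain is traversed deterministically in
#' `n - k` steps from `S_k`, so the true value function is
#' `V(S_k) = R * gamma^(n - k)`.
#'
#' @param spec A [chain_spec()] without punishment.
#' @return Numeric vector of length `n_states`; element `k` is `V(S_k)`.
#' @examples
#' true_values_nonresistant(chain_spec())
#' @export
true_values_nonresistant <- function(spec) {
  stopifnot(inherits(spec, "chain_spec"))
  if (spec$has_punishment) {
    stop("the Non-Resistant closed form assumes no punishment state",
         call. = FALSE)
  }
  spec$reward_size * discount_to_goal(spec$gamma, spec$n_states)
}
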