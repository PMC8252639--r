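#' Initial Go/No-Go action values
#'
#' The punctate action-value system starts from the completion of learning
#' under the Non-Resistant policy: `Q(Go_Sk) = R * gamma^(n-1-k)` (the true
#' value of Go at `S_k`, k = 1..n-1), and No-Go values one time-step
#' discounted from them, `Q(No-Go_Sk) = R * gamma^(n-k)`.
#'
#' @param spec A [chain_spec()].
#' @return A list with numeric vectors `q_go` and `q_no_go` of length
#'   `n_states - 1`.
#' @examples
#' init_action_values(chain_spec())
#' @export
init_action_values <- function(spec) {
  stopifnot(inherits(spec, "chain_spec"))
  n <- spec$n_states
  # backward products keep gamma * q_go[k] == q_no_go[k] == q_go[k - 1]
  # bit-exact, which makes the kappa = 0 Q-learning fixed point exact
  q_go <- spec$reward_size * discount_to_goal(spec$gamma, n - 1L)
  list(q_go = q_go, q_no_go = spec$gamma * q_go)
}

#' Construct the dual-system model
#'
#' Couples a punctate Go/No-Go action-value learner to a companion
#' state-value system whose RPEs flow in through the spiral
#' striatum-midbrain circuit.  At every time step the RPE of the action
#' chosen at `t - 1` is the mixture
#' `(1 - kappa) * delta_action + kappa * delta_companion`, where
#' `delta_action` is of Q-learning type
#' (`R(S(t)) + gamma * max(Q(Go_S(t)), Q(No-Go_S(t))) - Q(A(t-1)_S(t-1))`)
#' or SARSA type (bootstrap on the action actually chosen at `t`), and
#' `delta_companion` is the RPE of the companion system for the same time
#' step.  The companion is the rigid reduced SR (the addicted case) or, as a
#' control, the punctate state-value learner; it keeps updating its own
#' parameters during the run.
#'
#' @param spec A [chain_spec()] without punishment.
#' @param kappa Mixing weight of the companion RPE, in `[0, 1]` (the
#'   simulations use 0, 0.2, 0.4).
#' @param rpe_type `"q_learning"` or `"sarsa"`.
#' @param companion `"reduced_sr"` (default) or `"punctate"`; both start from
#'   the completion of learning under the Non-Resistant policy.
#' @param alpha Learning rate of the combined action-value update
#'   (default 0.5).
#' @return An object of class `dual_system`.
#' @export
dual_system <- function(spec, kappa = 0,
                        rpe_type = c("q_learning", "sarsa"),
                        companion = c("reduced_sr", "punctate"),
                        alpha = 0.5) {
  stopifnot(inherits(spec, "chain_spec"),
            is.numeric(kappa), length(kappa) == 1, kappa >= 0, kappa <= 1,
            alpha > 0, alpha <= 1)
  if (spec$has_punishment) {
    stop("the dual-system model does not support a punishment state",
         call. = FALSE)
  }
  rpe_type <- match.arg(rpe_type)
  companion <- match.arg(companion)
  q <- init_action_values(spec)
  comp <- switch(companion,
    reduced_sr = reduced_sr_learner(spec),
    punctate = td_learner(spec, init = "nonresistant")
  )
  structure(
    list(spec = spec, q_go = q$q_go, q_no_go = q$q_no_go, kappa = kappa,
         rpe_type = rpe_type, alpha = alpha, companion = comp,
         companion_kind = companion),
    class = "dual_system"
  )
}

#' @export
print.dual_system <- function(x, ...) {
  cat(sprintf(
    "<dual_system> %s-type action RPE, kappa = %g, companion = %s\n",
    x$rpe_type, x$kappa, x$companion_kind
  ))
  invisible(x)
}

# internal: Q(action_Sk) lookup / assignment helpers
q_value <- function(ds, state, action) {
  if (action == "go") ds$q_go[state] else ds$q_no_go[state]
}

#' Action-value RPE of the dual system
#'
#' Returns the Q-learning- or SARSA-type RPE for the arrival at `s_t`.  The
#' bootstrap (middle) term is dropped when `s_t` is the goal state, and the
#' previous-action term is dropped at the initial time step of an episode
#' (`credit = NULL`).
#'
#' @param ds A [dual_system()].
#' @param s_t State at time `t`.
#' @param reward Reward obtained at `s_t`.
#' @param chosen_action Action actually chosen at `s_t` (`"go"`/`"no_go"`);
#'   required for the SARSA type at non-goal states.
#' @param credit `NULL` at the initial time step, otherwise
#'   `list(state =, action =)` identifying the action taken at `t - 1`.
#' @return A single number.
#' @export
action_rpe <- function(ds, s_t, reward = 0, chosen_action = NULL,
                       credit = NULL) {
  stopifnot(inherits(ds, "dual_system"))
  n <- ds$spec$n_states
  boot <- if (s_t == n) {
    0  # middle term dropped at the goal
  } else if (ds$rpe_type == "q_learning") {
    ds$spec$gamma * max(ds$q_go[s_t], ds$q_no_go[s_t])
  } else {
    if (is.null(chosen_action)) {
      stop("the SARSA-type RPE needs the action chosen at the current state",
           call. = FALSE)
    }
    ds$spec$gamma * q_value(ds, s_t, chosen_action)
  }
  prev <- if (is.null(credit)) 0 else q_value(ds, credit$state, credit$action)
  reward + boot - prev
}

#' Apply the combined (mixed-RPE) action-value update
#'
#' Updates the value of the action taken at `t - 1` by
#' `alpha * ((1 - kappa) * action_rpe + kappa * companion_rpe)`.  A no-op
#' when `credit` is `NULL` (initial time step: there is no previous action
#' to credit, so neither RPE drives any action-value learning).
#'
#' @inheritParams action_rpe
#' @param action_rpe RPE of the action-value system (from [action_rpe()]).
#' @param companion_rpe RPE of the companion state-value system for the same
#'   time step.
#' @return The updated `dual_system`.
#' @export
combined_update <- function(ds, action_rpe, companion_rpe, credit) {
  stopifnot(inherits(ds, "dual_system"))
  if (is.null(credit)) return(ds)
  delta <- ds$alpha *
    ((1 - ds$kappa) * action_rpe + ds$kappa * companion_rpe)
  if (credit$action == "go") {
    ds$q_go[credit$state] <- ds$q_go[credit$state] + delta
  } else {
    ds$q_no_go[credit$state] <- ds$q_no_go[credit$state] + delta
  }
  ds
}

#' Tidy the dual system's action values
#'
#' @param x A [dual_system()].
#' @param ... Unused.
#' @return A tibble with one row per (state, action): columns `state`,
#'   `action`, `q`.
#' @method tidy dual_system
#' @export
tidy.dual_system <- function(x, ...) {
  n1 <- length(x$q_go)
  tibble::tibble(
    state = rep(seq_len(n1), 2L),
    action = rep(c("go", "no_go"), each = n1),
    q = c(x$q_go, x$q_no_go)
  )
}

#' @method glance dual_system
#' @export
glance.dual_system <- function(x, ...) {
  tibble::tibble(rpe_type = x$rpe_type, kappa = x$kappa,
                 companion = x$companion_kind,
                 companion_cue_value = cue_value(x$companion))
}
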