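#' Value-learner constructors
#'
#' Four state-value learning architectures are available, all updated by
#' temporal-difference (TD) reward prediction errors (RPEs) with learning
#' rate `alpha`:
#'
#' * `td_learner()` — punctate (individual) state representation: each state
#'   carries its own value `V(S_k)`, updated directly by its RPE.  Models the
#'   non-addicted case.
#' * `reduced_sr_learner()` — goal-based reduced SR: each state is a single
#'   scalar feature `x(S_k) = gamma^(n-k)` (the discounted future occupancy
#'   of the goal under the Non-Resistant policy) and values are approximated
#'   linearly as `w * x(S_k)`.  With `alpha_feature = 0` the representation
#'   is *rigid* (the addicted case): only `w` learns.  With
#'   `alpha_feature > 0` the scalar features themselves adapt slowly by their
#'   own TD rule (the goal feature stays frozen at 1).
#' * `genuine_sr_learner()` — genuine (full) SR: state `S_k` is the vector of
#'   discounted future occupancies of all states, and a weight vector `w_j`
#'   learns; with the initial weights `(0, ..., 0, R)` the approximation
#'   starts exact for the Non-Resistant policy.
#'
#' For all learners the initial condition `init = "nonresistant"` corresponds
#' to the completion of learning under the Non-Resistant policy (values
#' `R * gamma^(n-k)`, `w = R`, or `w = (0, ..., 0, R)`); `init = "zero"`
#' (punctate only) starts naive with all values 0.
#'
#' @param spec A [chain_spec()].
#' @param init Initial condition (see Details).
#' @param alpha,alpha_w Learning rate for values / for the reduced-SR
#'   coefficient `w` (default 0.5).
#' @param w Initial reduced-SR coefficient (default `reward_size`).
#' @param alpha_feature Learning rate of the reduced-SR scalar features
#'   (default 0 = rigid; the slowly adapting variant uses 0.05).
#'
#' @return A learner object (classes `"punctate_td"`, `"reduced_sr_learner"`
#'   or `"genuine_sr_learner"`, all inheriting from `"habitsr_learner"`).
#' @name learners
#' @examples
#' lr <- reduced_sr_learner(chain_spec())
#' cue_value(lr)   # w * gamma^n
NULL

#' @rdname learners
#' @export
td_learner <- function(spec, init = c("nonresistant", "zero"), alpha = 0.5) {
  stopifnot(inherits(spec, "chain_spec"), alpha > 0, alpha <= 1)
  init <- match.arg(init)
  v <- if (init == "zero") {
    rep(0, spec$n_states)
  } else {
    spec$reward_size * discount_to_goal(spec$gamma, spec$n_states)
  }
  if (spec$has_punishment) v <- c(v, 0)  # S_{n+1} starts unlearned
  structure(list(spec = spec, v = v, alpha = alpha),
            class = c("punctate_td", "habitsr_learner"))
}

#' @rdname learners
#' @export
reduced_sr_learner <- function(spec, w = spec$reward_size, alpha_w = 0.5,
                               alpha_feature = 0) {
  stopifnot(inherits(spec, "chain_spec"),
            is.numeric(w), length(w) == 1, is.finite(w),
            alpha_w > 0, alpha_w <= 1,
            alpha_feature >= 0, alpha_feature <= 1)
  if (alpha_feature > 0 && spec$has_punishment) {
    stop("adaptive reduced-SR features are not defined with a punishment ",
         "state", call. = FALSE)
  }
  structure(
    list(spec = spec, x = reduced_features(spec), w = w, alpha_w = alpha_w,
         alpha_feature = alpha_feature, rigid = alpha_feature == 0),
    class = c("reduced_sr_learner", "habitsr_learner")
  )
}

#' @rdname learners
#' @export
genuine_sr_learner <- function(spec, alpha = 0.5) {
  stopifnot(inherits(spec, "chain_spec"), alpha > 0, alpha <= 1)
  if (spec$has_punishment) {
    stop("the genuine-SR learner does not support a punishment state",
         call. = FALSE)
  }
  n <- spec$n_states
  structure(
    list(spec = spec, m = genuine_features(spec),
         w = c(rep(0, n - 1L), spec$reward_size), alpha = alpha),
    class = c("genuine_sr_learner", "habitsr_learner")
  )
}

#' @export
print.habitsr_learner <- function(x, ...) {
  cat(sprintf("<%s> n = %d, gamma = %g, cue value = %.4f\n",
              class(x)[1], x$spec$n_states, x$spec$gamma, cue_value(x)))
  invisible(x)
}

#' One TD step of a value learner
#'
#' Computes the reward prediction error for the step from `s_t` to `s_next`
#' and applies the learner's update, in that order (RPE from pre-update
#' quantities).  The general form is
#' `delta = R(S(t)) + gamma * V(S(t+1)) - V(S(t))`; passing `s_next = NA`
#' drops the bootstrap term `gamma * V(S(t+1))`, which happens at the goal
#' state (unless a punishment state follows) and at the punishment state.
#'
#' Architecture-specific updates:
#' * punctate: `V(s_t) <- V(s_t) + alpha * delta`;
#' * reduced SR: `w <- w + alpha_w * x(s_t) * delta`, and, when features
#'   adapt, additionally `x(s_t) <- x(s_t) + alpha_feature * delta_feature`
#'   with `delta_feature = gamma * x(s_next) - x(s_t)` — both deltas taken
#'   from the same pre-update snapshot, and the goal feature never updated;
#' * genuine SR: `w_j <- w_j + alpha * x_j(s_t) * delta` for all j.
#'
#' @param learner A learner from [td_learner()], [reduced_sr_learner()] or
#'   [genuine_sr_learner()].
#' @param s_t Current state index.
#' @param s_next Next state index, or `NA` to drop the bootstrap term.
#' @param reward Reward obtained at `s_t` (`R(S(t))`).
#' @return A list with `rpe`, the updated `learner`, and (adaptive reduced SR
#'   only) `feature_rpe`.
#' @export
td_step <- function(learner, s_t, s_next = NA, reward = 0) {
  UseMethod("td_step")
}

#' @export
td_step.punctate_td <- function(learner, s_t, s_next = NA, reward = 0) {
  v <- learner$v
  boot <- if (!is.na(s_next)) learner$spec$gamma * v[s_next] else 0
  rpe <- reward + boot - v[s_t]
  learner$v[s_t] <- v[s_t] + learner$alpha * rpe
  list(rpe = rpe, learner = learner)
}

#' @export
td_step.reduced_sr_learner <- function(learner, s_t, s_next = NA, reward = 0) {
  x <- learner$x
  # factored form R + w * (gamma * x_next - x_cur): with the features built
  # by backward cumulative products, Go steps give exactly 0 for any w
  boot_x <- if (!is.na(s_next)) learner$spec$gamma * x[s_next] else 0
  rpe <- reward + learner$w * (boot_x - x[s_t])
  learner$w <- learner$w + learner$alpha_w * x[s_t] * rpe
  out <- list(rpe = rpe, learner = learner)
  if (!learner$rigid && s_t != learner$spec$n_states) {
    feature_rpe <- boot_x - x[s_t]  # same pre-update snapshot of x
    out$learner$x[s_t] <- x[s_t] + learner$alpha_feature * feature_rpe
    out$feature_rpe <- feature_rpe
  }
  out
}

#' @export
td_step.genuine_sr_learner <- function(learner, s_t, s_next = NA, reward = 0) {
  w <- learner$w
  v_cur <- sum(w * learner$m[s_t, ])
  boot <- if (!is.na(s_next)) {
    learner$spec$gamma * sum(w * learner$m[s_next, ])
  } else 0
  rpe <- reward + boot - v_cur
  learner$w <- w + learner$alpha * learner$m[s_t, ] * rpe
  list(rpe = rpe, learner = learner)
}

#' One TD step of the reduced-SR feature itself
#'
#' The slowly adapting reduced SR updates its scalar features by their own
#' TD rule, `delta_feature = gamma * x(S(t+1)) - x(S(t))` and
#' `x(S(t)) <- x(S(t)) + alpha_feature * delta_feature`.  The goal-state
#' feature is theoretically error-free and is never updated (frozen at 1).
#' This standalone entry point updates *only* the feature; during
#' simulations [td_step()] performs the coefficient and feature updates
#' together from a shared pre-update snapshot.
#'
#' @param learner An adaptive [reduced_sr_learner()] (`alpha_feature > 0`).
#' @param s_t Current (non-goal) state index.
#' @param s_next Next state index.
#' @return A list with `feature_rpe` and the updated `learner`.
#' @export
feature_td_step <- function(learner, s_t, s_next) {
  stopifnot(inherits(learner, "reduced_sr_learner"))
  if (learner$rigid) {
    stop("feature updates are undefined for a rigid reduced SR",
         call. = FALSE)
  }
  if (s_t == learner$spec$n_states) {
    stop("the goal-state feature is frozen and never updated", call. = FALSE)
  }
  feature_rpe <- learner$spec$gamma * learner$x[s_next] - learner$x[s_t]
  learner$x[s_t] <- learner$x[s_t] + learner$alpha_feature * feature_rpe
  list(feature_rpe = feature_rpe, learner = learner)
}

#' Predicted value of the cue that initiates behavior
#'
#' The RPE generated upon initiation of behavior, `gamma * V(S_1) - 0`, is
#' interpreted as the learned predicted value of the cue that triggers the
#' reward-seeking sequence.  It equals `gamma * V(S_1)` for the punctate
#' learner, `w * gamma^n` for the reduced SR, and
#' `gamma * sum_j w_j x_j(S_1)` for the genuine SR.  No learning update is
#' associated with this event (there is no predecessor state to credit).
#'
#' @param learner A learner object.
#' @return A single number.
#' @export
cue_value <- function(learner) UseMethod("cue_value")

#' @export
cue_value.punctate_td <- function(learner) {
  learner$spec$gamma * learner$v[1]
}

#' @export
cue_value.reduced_sr_learner <- function(learner) {
  learner$w * (learner$spec$gamma * learner$x[1])
}

#' @export
cue_value.genuine_sr_learner <- function(learner) {
  learner$spec$gamma * sum(learner$w * learner$m[1, ])
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a value learner into a per-state tibble
#'
#' @param x A learner object.
#' @param ... Unused.
#' @return A tibble with one row per state: `state`, the current estimated
#'   `value`, and architecture-specific columns (`feature` and `w` for the
#'   reduced SR; `w` for the genuine SR, whose `value` is
#'   `sum_j w_j x_j(S_k)`).
#' @method tidy punctate_td
#' @export
tidy.punctate_td <- function(x, ...) {
  tibble::tibble(state = seq_along(x$v), value = x$v)
}

#' @rdname tidy.punctate_td
#' @method tidy reduced_sr_learner
#' @export
tidy.reduced_sr_learner <- function(x, ...) {
  tibble::tibble(state = seq_along(x$x), feature = x$x, w = x$w,
                 value = x$w * x$x)
}

#' @rdname tidy.punctate_td
#' @method tidy genuine_sr_learner
#' @export
tidy.genuine_sr_learner <- function(x, ...) {
  tibble::tibble(state = seq_along(x$w), w = x$w,
                 value = as.numeric(x$m %*% x$w))
}

#' One-row summary of a value learner
#'
#' @param x A learner object.
#' @param ... Unused.
#' @return A tibble with `architecture`, `n_states`, `gamma` and the current
#'   `cue_value`.
#' @method glance habitsr_learner
#' @export
glance.habitsr_learner <- function(x, ...) {
  tibble::tibble(architecture = class(x)[1], n_states = x$spec$n_states,
                 gamma = x$spec$gamma, cue_value = cue_value(x))
}
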