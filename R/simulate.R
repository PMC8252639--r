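# Step logs are accumulated in plain local vectors with an explicit write
# index and capacity doubling: subassignment on a function-local vector is
# in-place, whereas any shared/closure-held accumulator would be copied on
# every write.
grow <- function(v) c(v, v)

#' Configure a multi-episode, multi-simulation experiment
#'
#' Bundles the chain, the behavior policy, the learner architecture and the
#' run dimensions into a validated configuration for [run_simulation()].
#' Each of the `n_sims` simulations gets its own RNG stream seeded
#' `base_seed + sim_id`, so individual simulations are reproducible and
#' independent, and identical configurations give bit-identical outputs.
#'
#' @param chain A [chain_spec()].
#' @param policy A [policy_spec()].
#' @param learner Architecture tag: `"punctate"`, `"reduced_sr"` or
#'   `"genuine_sr"`.  Ignored when `dual` is given (the dual system fixes its
#'   own architectures).
#' @param episodes Number of episodes per simulation.
#' @param n_sims Number of simulations (standard setting 100).
#' @param base_seed Integer base seed.
#' @param init Initial condition for the punctate learner
#'   (`"nonresistant"` or `"zero"`); other learners always start from the
#'   completion of learning under the Non-Resistant policy.
#' @param alpha Learning rate of the value (or combined action-value) update.
#' @param alpha_feature Feature learning rate of the reduced SR (0 = rigid).
#' @param dual `NULL`, or a list with elements `kappa`, `rpe_type`
#'   (`"q_learning"`/`"sarsa"`) and `companion` (`"reduced_sr"`/`"punctate"`)
#'   to run the dual-system model.
#' @param max_steps Safety cap on time steps within one episode (the
#'   Resistant policy terminates almost surely for `p_no_go < 1`, so the cap
#'   only guards degenerate configurations).
#' @return An object of class `run_config`.
#' @export
run_config <- function(chain, policy,
                       learner = c("punctate", "reduced_sr", "genuine_sr"),
                       episodes, n_sims = 100L, base_seed = 1L,
                       init = "nonresistant", alpha = 0.5,
                       alpha_feature = 0, dual = NULL, max_steps = 1e6) {
  stopifnot(inherits(chain, "chain_spec"), inherits(policy, "policy_spec"),
            episodes >= 1, n_sims >= 1, max_steps >= 1,
            is.numeric(base_seed), length(base_seed) == 1)
  learner <- match.arg(learner)
  if (!is.null(dual)) {
    stopifnot(is.list(dual), all(c("kappa", "rpe_type") %in% names(dual)))
    dual$companion <- dual$companion %||% "reduced_sr"
    if (chain$has_punishment) {
      stop("the dual-system model does not support a punishment state",
           call. = FALSE)
    }
  }
  if (chain$has_punishment) {
    if (policy$kind != "non_resistant") {
      stop("punishment scenarios are only defined under the Non-Resistant ",
           "policy", call. = FALSE)
    }
    if (learner == "genuine_sr") {
      stop("punishment scenarios are only defined for the punctate and ",
           "reduced-SR learners", call. = FALSE)
    }
    if (alpha_feature > 0) {
      stop("adaptive reduced-SR features are not defined with a punishment ",
           "state", call. = FALSE)
    }
  }
  structure(
    list(chain = chain, policy = policy, learner = learner,
         episodes = as.integer(episodes), n_sims = as.integer(n_sims),
         base_seed = as.integer(base_seed), init = init, alpha = alpha,
         alpha_feature = alpha_feature, dual = dual,
         max_steps = max_steps),
    class = "run_config"
  )
}

#' @export
print.run_config <- function(x, ...) {
  cat(sprintf(
    "<run_config> %s, %s, %d episode(s) x %d simulation(s), seed %d\n",
    if (is.null(x$dual)) x$learner else {
      sprintf("dual(%s, kappa = %g, %s companion)", x$dual$rpe_type,
              x$dual$kappa, x$dual$companion)
    },
    x$policy$kind, x$episodes, x$n_sims, x$base_seed
  ))
  invisible(x)
}

make_learner <- function(cfg) {
  switch(cfg$learner,
    punctate = td_learner(cfg$chain, init = cfg$init, alpha = cfg$alpha),
    reduced_sr = reduced_sr_learner(cfg$chain, alpha_w = cfg$alpha,
                                    alpha_feature = cfg$alpha_feature),
    genuine_sr = genuine_sr_learner(cfg$chain, alpha = cfg$alpha)
  )
}

# End-of-episode snapshot of learner parameters, as parallel vectors
# (quantity, state, value) collected once per simulation.
snapshot_learner <- function(learner) {
  if (inherits(learner, "punctate_td")) {
    nv <- length(learner$v)
    list(quantity = rep("v", nv), state = seq_len(nv), value = learner$v)
  } else if (inherits(learner, "reduced_sr_learner")) {
    if (learner$rigid) {
      list(quantity = c("w", "cue_value"),
           state = c(NA_integer_, NA_integer_),
           value = c(learner$w, cue_value(learner)))
    } else {
      nx <- length(learner$x)
      list(quantity = c("w", "cue_value", rep("x", nx)),
           state = c(NA_integer_, NA_integer_, seq_len(nx)),
           value = c(learner$w, cue_value(learner), learner$x))
    }
  } else {
    nw <- length(learner$w)
    list(quantity = rep("w", nw), state = seq_len(nw), value = learner$w)
  }
}

snapshot_dual <- function(ds) {
  n1 <- length(ds$q_go)
  reduced <- inherits(ds$companion, "reduced_sr_learner")
  extra_q <- if (reduced) c("w_companion", "companion_cue_value") else
    "companion_cue_value"
  extra_v <- if (reduced) c(ds$companion$w, cue_value(ds$companion)) else
    cue_value(ds$companion)
  list(
    quantity = c(rep("q_go", n1), rep("q_no_go", n1), extra_q),
    state = c(seq_len(n1), seq_len(n1), rep(NA_integer_, length(extra_q))),
    value = c(ds$q_go, ds$q_no_go, extra_v)
  )
}

collect_snapshots <- function(sim_id, snaps) {
  lens <- vapply(snaps, function(sn) length(sn$value), integer(1))
  tibble::tibble(
    sim_id = rep(sim_id, sum(lens)),
    episode = rep(seq_along(snaps), lens),
    quantity = unlist(lapply(snaps, `[[`, "quantity"), use.names = FALSE),
    state = unlist(lapply(snaps, `[[`, "state"), use.names = FALSE),
    value = unlist(lapply(snaps, `[[`, "value"), use.names = FALSE)
  )
}

run_one_sim_single <- function(cfg, sim_id) {
  set.seed(cfg$base_seed + sim_id)
  spec <- cfg$chain
  n <- spec$n_states
  p_no_go <- cfg$policy$p_no_go
  learner <- make_learner(cfg)
  cap <- 2048L
  c_ep <- integer(cap); c_t <- integer(cap); c_state <- integer(cap)
  c_action <- character(cap); c_rpe <- numeric(cap); c_frpe <- numeric(cap)
  i <- 0L
  snaps <- vector("list", cfg$episodes)
  for (ep in seq_len(cfg$episodes)) {
    # behavior initiation: the RPE is the learned cue value; no update
    i <- i + 1L
    c_ep[i] <- ep; c_t[i] <- 0L; c_state[i] <- 0L
    c_action[i] <- "initiation"; c_rpe[i] <- cue_value(learner)
    c_frpe[i] <- NA_real_
    state <- 1L
    t <- 1L
    while (state < n) {
      go <- stats::runif(1) >= p_no_go
      s_next <- if (go) state + 1L else state
      res <- td_step(learner, state, s_next, 0)
      learner <- res$learner
      if (i >= cap - 2L) {
        cap <- cap * 2L
        c_ep <- grow(c_ep); c_t <- grow(c_t); c_state <- grow(c_state)
        c_action <- grow(c_action); c_rpe <- grow(c_rpe)
        c_frpe <- grow(c_frpe)
      }
      i <- i + 1L
      c_ep[i] <- ep; c_t[i] <- t; c_state[i] <- state
      c_action[i] <- if (go) "go" else "no_go"
      c_rpe[i] <- res$rpe
      c_frpe[i] <- res$feature_rpe %||% NA_real_
      state <- s_next
      t <- t + 1L
      if (t > cfg$max_steps) {
        stop("episode step cap (max_steps) exceeded", call. = FALSE)
      }
    }
    # goal arrival: reward delivered; bootstrap dropped unless S_{n+1} follows
    s_next <- if (spec$has_punishment) n + 1L else NA_integer_
    res <- td_step(learner, n, s_next, spec$reward_size)
    learner <- res$learner
    i <- i + 1L
    c_ep[i] <- ep; c_t[i] <- t; c_state[i] <- n
    c_action[i] <- "goal_arrival"; c_rpe[i] <- res$rpe; c_frpe[i] <- NA_real_
    if (spec$has_punishment) {
      t <- t + 1L
      res <- td_step(learner, n + 1L, NA_integer_, spec$punishment_size)
      learner <- res$learner
      i <- i + 1L
      c_ep[i] <- ep; c_t[i] <- t; c_state[i] <- n + 1L
      c_action[i] <- "punishment_arrival"; c_rpe[i] <- res$rpe
      c_frpe[i] <- NA_real_
    }
    snaps[[ep]] <- snapshot_learner(learner)
  }
  keep <- seq_len(i)
  list(
    steps = tibble::tibble(
      sim_id = rep(sim_id, i), episode = c_ep[keep], t = c_t[keep],
      state = c_state[keep], action = c_action[keep], rpe = c_rpe[keep],
      rpe_action = rep(NA_real_, i), feature_rpe = c_frpe[keep]
    ),
    snapshots = collect_snapshots(sim_id, snaps)
  )
}

run_one_sim_dual <- function(cfg, sim_id) {
  set.seed(cfg$base_seed + sim_id)
  spec <- cfg$chain
  n <- spec$n_states
  p_no_go <- cfg$policy$p_no_go
  ds <- dual_system(spec, kappa = cfg$dual$kappa,
                    rpe_type = cfg$dual$rpe_type,
                    companion = cfg$dual$companion, alpha = cfg$alpha)
  cap <- 2048L
  c_ep <- integer(cap); c_t <- integer(cap); c_state <- integer(cap)
  c_action <- character(cap); c_rpe <- numeric(cap); c_arpe <- numeric(cap)
  i <- 0L
  snaps <- vector("list", cfg$episodes)
  for (ep in seq_len(cfg$episodes)) {
    i <- i + 1L
    c_ep[i] <- ep; c_t[i] <- 0L; c_state[i] <- 0L
    c_action[i] <- "initiation"; c_rpe[i] <- cue_value(ds$companion)
    c_arpe[i] <- NA_real_
    credit <- NULL  # no previous action at the initial time step
    state <- 1L
    t <- 1L
    while (state < n) {
      go <- stats::runif(1) >= p_no_go
      action <- if (go) "go" else "no_go"
      s_next <- if (go) state + 1L else state
      comp <- td_step(ds$companion, state, s_next, 0)
      a_rpe <- action_rpe(ds, state, 0, action, credit)
      ds <- combined_update(ds, a_rpe, comp$rpe, credit)
      ds$companion <- comp$learner
      if (i >= cap - 1L) {
        cap <- cap * 2L
        c_ep <- grow(c_ep); c_t <- grow(c_t); c_state <- grow(c_state)
        c_action <- grow(c_action); c_rpe <- grow(c_rpe)
        c_arpe <- grow(c_arpe)
      }
      i <- i + 1L
      c_ep[i] <- ep; c_t[i] <- t; c_state[i] <- state
      c_action[i] <- action; c_rpe[i] <- comp$rpe; c_arpe[i] <- a_rpe
      credit <- list(state = state, action = action)
      state <- s_next
      t <- t + 1L
      if (t > cfg$max_steps) {
        stop("episode step cap (max_steps) exceeded", call. = FALSE)
      }
    }
    # goal arrival: both RPEs carry the reward and credit the final Go
    comp <- td_step(ds$companion, n, NA_integer_, spec$reward_size)
    a_rpe <- action_rpe(ds, n, spec$reward_size, NULL, credit)
    ds <- combined_update(ds, a_rpe, comp$rpe, credit)
    ds$companion <- comp$learner
    i <- i + 1L
    c_ep[i] <- ep; c_t[i] <- t; c_state[i] <- n
    c_action[i] <- "goal_arrival"; c_rpe[i] <- comp$rpe; c_arpe[i] <- a_rpe
    snaps[[ep]] <- snapshot_dual(ds)
  }
  keep <- seq_len(i)
  list(
    steps = tibble::tibble(
      sim_id = rep(sim_id, i), episode = c_ep[keep], t = c_t[keep],
      state = c_state[keep], action = c_action[keep], rpe = c_rpe[keep],
      rpe_action = c_arpe[keep], feature_rpe = rep(NA_real_, i)
    ),
    snapshots = collect_snapshots(sim_id, snaps)
  )
}

#' Run a configured experiment
#'
#' Runs `n_sims` independent simulations of `episodes` episodes each and
#' returns the complete per-time-step event log together with per-episode
#' snapshots of the learner's parameters.
#'
#' Every episode starts with an `initiation` event (logged with pseudo-state
#' 0 and `t = 0`; its RPE is the current cue value and it performs no
#' update), then one row per time step with the action taken (`go`,
#' `no_go`), one `goal_arrival` row, and — in punishment runs — one
#' `punishment_arrival` row.
#'
#' @param cfg A [run_config()].
#' @return An object of class `habitsr_run`: a list with
#'   \describe{
#'     \item{steps}{tibble with columns `sim_id`, `episode`, `t`, `state`,
#'       `action`, `rpe` (state-value system), `rpe_action` (dual-system
#'       runs only) and `feature_rpe` (adaptive reduced SR only).}
#'     \item{snapshots}{long tibble (`sim_id`, `episode`, `quantity`,
#'       `state`, `value`) of end-of-episode learner parameters: `v` per
#'       state (punctate), `w`/`cue_value` and adaptive `x` (reduced SR),
#'       `w` per feature (genuine SR), `q_go`/`q_no_go` per state plus
#'       companion quantities (dual system).}
#'     \item{config}{the configuration used.}
#'   }
#' @examples
#' cfg <- run_config(chain_spec(), policy_spec("resistant", 0.75),
#'                   learner = "reduced_sr", episodes = 3, n_sims = 2)
#' run <- run_simulation(cfg)
#' head(run$steps)
#' @export
run_simulation <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  runner <- if (is.null(cfg$dual)) run_one_sim_single else run_one_sim_dual
  sims <- lapply(seq_len(cfg$n_sims), function(sim_id) runner(cfg, sim_id))
  steps <- dplyr::bind_rows(lapply(sims, `[[`, "steps"))
  if (is.null(cfg$dual)) steps$rpe_action <- NULL
  adaptive <- is.null(cfg$dual) && cfg$learner == "reduced_sr" &&
    cfg$alpha_feature > 0
  if (!adaptive) steps$feature_rpe <- NULL
  snapshots <- dplyr::bind_rows(lapply(sims, `[[`, "snapshots"))
  structure(list(steps = steps, snapshots = snapshots, config = cfg),
            class = "habitsr_run")
}

#' @export
print.habitsr_run <- function(x, ...) {
  print(x$config)
  cat(sprintf("  %d step records, %d snapshot records\n",
              nrow(x$steps), nrow(x$snapshots)))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
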