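#' List the available scenario presets
#'
#' @return A tibble with one row per preset: `name`, default `episodes` and
#'   `n_sims`, and a short description.
#' @export
list_scenarios <- function() {
  tibble::tribble(
    ~name, ~episodes, ~n_sims, ~description,
    "fig2a", 30L, 1L,
    "punctate learner, naive start, Non-Resistant policy (deterministic)",
    "fig2bcd", 60L, 100L,
    "punctate learner under the Resistant policy (P_No-Go = 0.75)",
    "fig3", 60L, 100L,
    "rigid reduced SR under the Resistant policy, with w trajectory",
    "fig4a", 25L, 100L,
    "cue values at episode 25 for P_No-Go in {0.5, 0.75, 0.9}, both learners",
    "fig4b", 25L, 1L,
    "punishment (-2) after the goal, Non-Resistant policy, both learners",
    "fig5", 200L, 100L,
    "slowly adapting reduced-SR features (alpha_feature = 0.05)",
    "fig6", 25L, 100L,
    "genuine SR under the Resistant policy, with w_j trajectories",
    "fig8", 60L, 100L,
    "dual system with reduced-SR companion, kappa in {0, 0.2, 0.4}",
    "fig9", 60L, 100L,
    "dual system with punctate-state companion (control)"
  )
}

cue_summary <- function(run, at_episode) {
  run$steps |>
    dplyr::filter(.data$action == "initiation",
                  .data$episode == at_episode) |>
    dplyr::summarise(episode = at_episode, mean_cue = mean(.data$rpe),
                     sd_cue = ifelse(dplyr::n() >= 2, stats::sd(.data$rpe),
                                     NA_real_),
                     n = dplyr::n())
}

#' Windowed action-value summary of a dual-system run
#'
#' For each simulation, averages `Q(Go_Sk)` and `Q(No-Go_Sk)` over the
#' end-of-episode snapshots in `window`, takes their difference, and then
#' summarises across simulations (mean and sample SD).
#'
#' @param run A dual-system `habitsr_run`.
#' @param window Episodes to average over (standard: 41 to 60).
#' @return A tibble with one row per pre-goal state: `state`, mean/SD of the
#'   windowed Go and No-Go values and of their difference, and `n_sims`.
#' @export
dual_window_summary <- function(run, window = 41:60) {
  stopifnot(inherits(run, "habitsr_run"), !is.null(run$config$dual))
  if (max(window) > run$config$episodes) {
    stop("the averaging window extends past the simulated episodes",
         call. = FALSE)
  }
  run$snapshots |>
    dplyr::filter(.data$quantity %in% c("q_go", "q_no_go"),
                  .data$episode %in% window) |>
    dplyr::group_by(.data$sim_id, .data$quantity, .data$state) |>
    dplyr::summarise(value = mean(.data$value), .groups = "drop") |>
    tidyr::pivot_wider(names_from = "quantity", values_from = "value") |>
    dplyr::mutate(diff = .data$q_go - .data$q_no_go) |>
    dplyr::group_by(.data$state) |>
    dplyr::summarise(
      mean_q_go = mean(.data$q_go), sd_q_go = stats::sd(.data$q_go),
      mean_q_no_go = mean(.data$q_no_go),
      sd_q_no_go = stats::sd(.data$q_no_go),
      mean_diff = mean(.data$diff), sd_diff = stats::sd(.data$diff),
      n_sims = dplyr::n(), .groups = "drop"
    )
}

#' Run a named scenario preset
#'
#' Each preset reproduces the configuration behind one figure-style result:
#' `fig2a` (naive punctate learning under the Non-Resistant policy, a single
#' deterministic simulation), `fig2bcd` (punctate under the Resistant
#' policy), `fig3` (rigid reduced SR under the Resistant policy, with the
#' across-episode trajectory of the coefficient `w`), `fig4a` (cue values at
#' episode 25 for `P_No-Go` 0.5/0.75/0.9, punctate vs reduced SR), `fig4b`
#' (size-2 punishment after the goal under the Non-Resistant policy),
#' `fig5` (slowly adapting reduced-SR features over 200 episodes, with
#' feature snapshots after 50/100/200 episodes), `fig6` (genuine SR, with
#' the `w_j` trajectories), and `fig8`/`fig9` (dual system with the
#' reduced-SR / punctate-state companion, `kappa` in 0/0.2/0.4, action
#' values averaged over episodes 41 to 60).
#'
#' Results are deterministic given `base_seed`: simulation `i` of every run
#' uses seed `base_seed + i`.
#'
#' @param name Preset name (see [list_scenarios()]).
#' @param base_seed Integer base seed.
#' @param episodes,n_sims Optional overrides of the preset defaults.
#' @param rpe_types For `fig8`/`fig9`: which action-RPE types to run
#'   (default both `"q_learning"` and `"sarsa"`).
#' @return An object of class `habitsr_scenario`: a list with `name`, the
#'   named list `runs` of `habitsr_run` objects, a scenario-level `summary`
#'   tibble, and scenario-specific `extras` tibbles (e.g. `w_trajectory`,
#'   `features`, `weights`, `cue_values`).
#' @examples
#' \donttest{
#' sc <- run_scenario("fig3", base_seed = 1, episodes = 25, n_sims = 10)
#' sc$summary
#' }
#' @export
run_scenario <- function(name, base_seed = 1, episodes = NULL, n_sims = NULL,
                         rpe_types = c("q_learning", "sarsa")) {
  presets <- list_scenarios()
  if (!name %in% presets$name) {
    stop("unknown scenario preset: ", name, call. = FALSE)
  }
  defaults <- presets[presets$name == name, ]
  episodes <- as.integer(episodes %||% defaults$episodes)
  n_sims <- as.integer(n_sims %||% defaults$n_sims)
  rpe_types <- match.arg(rpe_types, several.ok = TRUE)
  spec <- chain_spec()
  resistant <- function(p = 0.75) policy_spec("resistant", p)

  runs <- list()
  extras <- list()
  summary <- NULL

  if (name == "fig2a") {
    cfg <- run_config(spec, policy_spec("non_resistant"),
                      learner = "punctate", episodes = episodes,
                      n_sims = n_sims, base_seed = base_seed, init = "zero")
    runs$punctate_naive <- run_simulation(cfg)
    summary <- aggregate_rpes(runs$punctate_naive)
  } else if (name == "fig2bcd") {
    cfg <- run_config(spec, resistant(), learner = "punctate",
                      episodes = episodes, n_sims = n_sims,
                      base_seed = base_seed)
    runs$punctate <- run_simulation(cfg)
    summary <- aggregate_rpes(runs$punctate)
  } else if (name == "fig3") {
    cfg <- run_config(spec, resistant(), learner = "reduced_sr",
                      episodes = episodes, n_sims = n_sims,
                      base_seed = base_seed)
    runs$reduced_sr <- run_simulation(cfg)
    summary <- aggregate_rpes(runs$reduced_sr)
    w_traj <- runs$reduced_sr$snapshots |>
      dplyr::filter(.data$quantity == "w") |>
      dplyr::group_by(.data$episode) |>
      dplyr::summarise(mean_w = mean(.data$value),
                       sd_w = ifelse(dplyr::n() >= 2, stats::sd(.data$value),
                                     NA_real_),
                       .groups = "drop")
    # the assumed initial condition (w = 1, SD = 0) plotted at episode 0
    extras$w_trajectory <- dplyr::bind_rows(
      tibble::tibble(episode = 0L, mean_w = spec$reward_size, sd_w = 0),
      w_traj
    )
  } else if (name == "fig4a") {
    grid <- tidyr::expand_grid(learner = c("punctate", "reduced_sr"),
                               p_no_go = c(0.5, 0.75, 0.9))
    rows <- purrr::pmap(grid, function(learner, p_no_go) {
      cfg <- run_config(spec, resistant(p_no_go), learner = learner,
                        episodes = episodes, n_sims = n_sims,
                        base_seed = base_seed)
      run <- run_simulation(cfg)
      runs[[sprintf("%s_p%g", learner, p_no_go)]] <<- run
      dplyr::mutate(cue_summary(run, episodes), learner = learner,
                    p_no_go = p_no_go, .before = 1)
    })
    # episode-0 reference: the cue value at the completion of learning under
    # the Non-Resistant policy, gamma^n * R, identical for both learners
    ref <- tibble::tibble(
      learner = c("punctate", "reduced_sr"), p_no_go = 0, episode = 0L,
      mean_cue = cue_value(td_learner(spec)), sd_cue = 0, n = 1L
    )
    summary <- dplyr::bind_rows(ref, purrr::list_rbind(rows))
  } else if (name == "fig4b") {
    pspec <- chain_spec(has_punishment = TRUE, punishment_size = -2)
    for (learner in c("punctate", "reduced_sr")) {
      cfg <- run_config(pspec, policy_spec("non_resistant"),
                        learner = learner, episodes = episodes,
                        n_sims = n_sims, base_seed = base_seed)
      runs[[learner]] <- run_simulation(cfg)
    }
    summary <- purrr::imap(runs, function(run, learner) {
      dplyr::mutate(cue_summary(run, episodes), learner = learner,
                    .before = 1)
    }) |> purrr::list_rbind()
    extras$cue_values <- purrr::imap(runs, function(run, learner) {
      run$steps |>
        dplyr::filter(.data$action == "initiation") |>
        dplyr::group_by(.data$episode) |>
        dplyr::summarise(mean_cue = mean(.data$rpe), .groups = "drop") |>
        dplyr::mutate(learner = learner, .before = 1)
    }) |> purrr::list_rbind()
  } else if (name == "fig5") {
    cfg <- run_config(spec, resistant(), learner = "reduced_sr",
                      episodes = episodes, n_sims = n_sims,
                      base_seed = base_seed, alpha_feature = 0.05)
    runs$adaptive <- run_simulation(cfg)
    summary <- aggregate_rpes(runs$adaptive)
    snaps <- intersect(c(50L, 100L, 200L), seq_len(episodes))
    feat <- runs$adaptive$snapshots |>
      dplyr::filter(.data$quantity == "x", .data$episode %in% snaps) |>
      dplyr::group_by(.data$episode, .data$state) |>
      dplyr::summarise(mean_x = mean(.data$value), .groups = "drop")
    extras$features <- dplyr::bind_rows(
      tibble::tibble(episode = 0L, state = seq_len(spec$n_states),
                     mean_x = reduced_features(spec)),
      feat
    )
  } else if (name == "fig6") {
    cfg <- run_config(spec, resistant(), learner = "genuine_sr",
                      episodes = episodes, n_sims = n_sims,
                      base_seed = base_seed)
    runs$genuine_sr <- run_simulation(cfg)
    summary <- aggregate_rpes(runs$genuine_sr)
    extras$weights <- runs$genuine_sr$snapshots |>
      dplyr::filter(.data$quantity == "w") |>
      dplyr::group_by(.data$episode, .data$state) |>
      dplyr::summarise(mean_w = mean(.data$value),
                       sd_w = ifelse(dplyr::n() >= 2, stats::sd(.data$value),
                                     NA_real_),
                       .groups = "drop")
  } else if (name %in% c("fig8", "fig9")) {
    companion <- if (name == "fig8") "reduced_sr" else "punctate"
    grid <- tidyr::expand_grid(rpe_type = rpe_types,
                               kappa = c(0, 0.2, 0.4))
    window <- if (episodes >= 60) 41:60 else seq_len(episodes)
    rows <- purrr::pmap(grid, function(rpe_type, kappa) {
      cfg <- run_config(spec, resistant(), episodes = episodes,
                        n_sims = n_sims, base_seed = base_seed,
                        dual = list(kappa = kappa, rpe_type = rpe_type,
                                    companion = companion))
      run <- run_simulation(cfg)
      runs[[sprintf("%s_kappa%g", rpe_type, kappa)]] <<- run
      dual_window_summary(run, window) |>
        dplyr::mutate(rpe_type = rpe_type, kappa = kappa, .before = 1)
    })
    summary <- purrr::list_rbind(rows)
  }

  structure(list(name = name, runs = runs, summary = summary,
                 extras = extras,
                 base_seed = as.integer(base_seed), episodes = episodes,
                 n_sims = n_sims),
            class = "habitsr_scenario")
}

#' @export
print.habitsr_scenario <- function(x, ...) {
  cat(sprintf("<habitsr_scenario> %s: %d run(s), seed %d\n",
              x$name, length(x$runs), x$base_seed))
  print(x$summary, n = 10)
  invisible(x)
}

#' Combined step log of a scenario
#'
#' Binds the step logs of all runs of a scenario into one tibble with a
#' `condition` column naming the run.
#'
#' @param sc A `habitsr_scenario`.
#' @return A tibble.
#' @export
scenario_steps <- function(sc) {
  stopifnot(inherits(sc, "habitsr_scenario"))
  purrr::imap(sc$runs, function(run, nm) {
    dplyr::mutate(run$steps, condition = nm, .before = 1)
  }) |> purrr::list_rbind()
}
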