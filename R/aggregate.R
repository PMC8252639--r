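#' Aggregate RPEs across simulations
#'
#' Summarises a step log into across-simulation means and standard
#' deviations per (episode, state, RPE kind), with the following
#' conventions:
#'
#' * No-Go RPEs can recur at the same state within an episode; within each
#'   simulation they are first averaged (kind `no_go_mean`) and separately
#'   summed (kind `no_go_sum`) within the episode, so each simulation
#'   contributes a single value per cell.
#' * A simulation that took no No-Go at a given (state, episode) cell is
#'   excluded from that cell's No-Go statistics (it simply does not
#'   contribute; `n_included` counts the contributing simulations, and cells
#'   with no contributors are absent from the table).
#' * `initiation`, `go`, `goal` and `punishment` events occur exactly once
#'   per episode (per state, for `go`), so all simulations contribute.
#' * The SD is the sample standard deviation and is `NA` when fewer than two
#'   simulations contribute.
#'
#' @param x A `habitsr_run` (from [run_simulation()]) or its `steps` tibble.
#' @param rpe_col Which RPE column to aggregate (`"rpe"`, the state-value
#'   system; `"rpe_action"` is available for dual-system runs).
#' @return A tibble with columns `episode`, `state`, `rpe_kind` (one of
#'   `initiation`, `go`, `no_go_mean`, `no_go_sum`, `goal`, `punishment`),
#'   `mean`, `sd`, `n_included`.
#' @examples
#' cfg <- run_config(chain_spec(), policy_spec("resistant", 0.75),
#'                   learner = "punctate", episodes = 2, n_sims = 5)
#' aggregate_rpes(run_simulation(cfg))
#' @export
aggregate_rpes <- function(x, rpe_col = "rpe") {
  steps <- if (inherits(x, "habitsr_run")) x$steps else x
  stopifnot(is.data.frame(steps), rpe_col %in% names(steps))
  steps <- dplyr::rename(steps, .rpe = dplyr::all_of(rpe_col))

  kind_map <- c(initiation = "initiation", go = "go", goal_arrival = "goal",
                punishment_arrival = "punishment")
  once <- steps |>
    dplyr::filter(.data$action != "no_go") |>
    dplyr::mutate(rpe_kind = kind_map[.data$action]) |>
    dplyr::group_by(.data$episode, .data$state, .data$rpe_kind) |>
    dplyr::summarise(
      mean = mean(.data$.rpe),
      sd = ifelse(dplyr::n() >= 2, stats::sd(.data$.rpe), NA_real_),
      n_included = dplyr::n(),
      .groups = "drop"
    )

  no_go <- steps |>
    dplyr::filter(.data$action == "no_go") |>
    dplyr::group_by(.data$sim_id, .data$episode, .data$state) |>
    dplyr::summarise(no_go_mean = mean(.data$.rpe),
                     no_go_sum = sum(.data$.rpe), .groups = "drop") |>
    tidyr::pivot_longer(c("no_go_mean", "no_go_sum"),
                        names_to = "rpe_kind", values_to = "value") |>
    dplyr::group_by(.data$episode, .data$state, .data$rpe_kind) |>
    dplyr::summarise(
      mean = mean(.data$value),
      sd = ifelse(dplyr::n() >= 2, stats::sd(.data$value), NA_real_),
      n_included = dplyr::n(),
      .groups = "drop"
    )

  dplyr::bind_rows(once, no_go) |>
    dplyr::arrange(.data$episode, .data$state, .data$rpe_kind)
}
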