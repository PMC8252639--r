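#' Plot the per-state RPE profile of one episode
#'
#' Mirrors the per-episode RPE panels: one point per state and RPE kind
#' (initiation at the pseudo-state 0 position, Go, within-episode mean and
#' summation of No-Go, goal), with across-simulation mean and SD error bars.
#'
#' @param agg An aggregate table from [aggregate_rpes()].
#' @param episode Which episode to show.
#' @param kinds RPE kinds to include.
#' @return A ggplot object.
#' @export
plot_rpe_profile <- function(agg, episode,
                             kinds = c("initiation", "go", "no_go_mean",
                                       "no_go_sum", "goal")) {
  dat <- agg |>
    dplyr::filter(.data$episode == !!episode, .data$rpe_kind %in% kinds)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$state, y = .data$mean,
                                    colour = .data$rpe_kind)) +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      width = 0.2, na.rm = TRUE
    ) +
    ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
    ggplot2::scale_x_continuous(breaks = sort(unique(dat$state))) +
    ggplot2::labs(x = "state (0 = initiation cue)", y = "RPE",
                  colour = "event",
                  title = sprintf("RPEs in episode %d", episode))
}

#' Plot RPE kinds across episodes
#'
#' Shows how the mean RPE of each kind evolves over episodes (mean across
#' simulations, ribbon = mean +/- SD), at one state for the per-state kinds.
#'
#' @param agg An aggregate table from [aggregate_rpes()].
#' @param state State to show for `go`/`no_go` kinds (default 1, the start
#'   state); `initiation` and `goal` are unambiguous.
#' @param kinds RPE kinds to include.
#' @return A ggplot object.
#' @export
plot_rpe_trajectory <- function(agg, state = 1,
                                kinds = c("initiation", "go", "no_go_mean",
                                          "no_go_sum", "goal")) {
  dat <- agg |>
    dplyr::filter(.data$rpe_kind %in% kinds,
                  .data$rpe_kind %in% c("initiation", "goal", "punishment") |
                    .data$state == !!state)
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$episode, y = .data$mean,
                                    colour = .data$rpe_kind,
                                    fill = .data$rpe_kind)) +
    ggplot2::geom_ribbon(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      alpha = 0.2, colour = NA, na.rm = TRUE
    ) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "episode", y = "RPE", colour = "event", fill = "event")
}

#' Plot reduced-SR feature curves
#'
#' Shows the scalar feature `x(S_k)` (discounted future occupancy of the
#' goal) against the state index, one curve per snapshot episode — the
#' adaptive-feature picture in which the curve becomes steeper with
#' continued resistance.
#'
#' @param features A tibble with columns `episode`, `state`, `mean_x`
#'   (e.g. `extras$features` of the `fig5` scenario).
#' @return A ggplot object.
#' @export
plot_feature_curves <- function(features) {
  ggplot2::ggplot(features,
                  ggplot2::aes(x = .data$state, y = .data$mean_x,
                               colour = factor(.data$episode),
                               group = .data$episode)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_continuous(breaks = sort(unique(features$state))) +
    ggplot2::labs(x = "state", y = "x(S_k)", colour = "after episode")
}

#' Plot dual-system action values per state
#'
#' Shows the windowed mean Go and No-Go values (or their difference) per
#' state, faceted by `kappa` and RPE type.
#'
#' @param summary A tibble from [dual_window_summary()] or the `summary` of
#'   a `fig8`/`fig9` scenario (needs `rpe_type` and `kappa` columns for
#'   faceting; they are added with value `NA` when absent).
#' @param what `"values"` (Go and No-Go with SD bars) or `"diff"`
#'   (`Q(Go) - Q(No-Go)`).
#' @return A ggplot object.
#' @export
plot_action_values <- function(summary, what = c("values", "diff")) {
  what <- match.arg(what)
  if (!"kappa" %in% names(summary)) summary$kappa <- NA_real_
  if (!"rpe_type" %in% names(summary)) summary$rpe_type <- NA_character_
  if (what == "values") {
    long <- summary |>
      tidyr::pivot_longer(
        cols = c("mean_q_go", "mean_q_no_go"),
        names_to = "action", values_to = "q"
      ) |>
      dplyr::mutate(
        action = ifelse(.data$action == "mean_q_go", "go", "no_go"),
        sd = ifelse(.data$action == "go", .data$sd_q_go, .data$sd_q_no_go)
      )
    p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$state, y = .data$q,
                                            colour = .data$action)) +
      ggplot2::geom_line() +
      ggplot2::geom_errorbar(
        ggplot2::aes(ymin = .data$q - .data$sd, ymax = .data$q + .data$sd),
        width = 0.2, na.rm = TRUE
      ) +
      ggplot2::labs(x = "state", y = "action value")
  } else {
    p <- ggplot2::ggplot(summary,
                         ggplot2::aes(x = .data$state,
                                      y = .data$mean_diff)) +
      ggplot2::geom_col() +
      ggplot2::geom_errorbar(
        ggplot2::aes(ymin = .data$mean_diff - .data$sd_diff,
                     ymax = .data$mean_diff + .data$sd_diff),
        width = 0.2, na.rm = TRUE
      ) +
      ggplot2::labs(x = "state", y = "Q(Go) - Q(No-Go)")
  }
  p + ggplot2::facet_grid(
    rows = ggplot2::vars(.data$rpe_type),
    cols = ggplot2::vars(.data$kappa),
    labeller = ggplot2::label_both
  )
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Autoplot methods
#'
#' `autoplot()` on a `habitsr_run` shows the RPE trajectories of its
#' aggregate table; on a `habitsr_scenario` it picks a representative plot
#' for the preset (action-value differences for the dual-system presets,
#' feature curves for the adaptive-SR preset, RPE trajectories otherwise).
#'
#' @param object A `habitsr_run` or `habitsr_scenario`.
#' @param ... Passed to the underlying `plot_*` helper.
#' @return A ggplot object.
#' @method autoplot habitsr_run
#' @export
autoplot.habitsr_run <- function(object, ...) {
  plot_rpe_trajectory(aggregate_rpes(object), ...)
}

#' @rdname autoplot.habitsr_run
#' @method autoplot habitsr_scenario
#' @export
autoplot.habitsr_scenario <- function(object, ...) {
  if (object$name %in% c("fig8", "fig9")) {
    plot_action_values(object$summary, ...)
  } else if (object$name == "fig5") {
    plot_feature_curves(object$extras$features, ...)
  } else if (object$name == "fig4a") {
    ggplot2::ggplot(object$summary,
                    ggplot2::aes(x = factor(.data$p_no_go),
                                 y = .data$mean_cue,
                                 colour = .data$learner)) +
      ggplot2::geom_point(position = ggplot2::position_dodge(0.3)) +
      ggplot2::labs(x = "P_No-Go (0 = Non-Resistant reference)",
                    y = "cue value")
  } else if (object$name == "fig4b") {
    ggplot2::ggplot(object$summary,
                    ggplot2::aes(x = .data$learner, y = .data$mean_cue)) +
      ggplot2::geom_point() +
      ggplot2::geom_hline(yintercept = 0, linetype = "dotted") +
      ggplot2::labs(x = NULL, y = "cue value after punishment")
  } else {
    plot_rpe_trajectory(object$summary, ...)
  }
}
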