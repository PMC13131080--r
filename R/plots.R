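# Figure-style plots: recovery fit panels and MPV trajectories.

#' Plot a bi-exponential recovery fit
#'
#' Shows the smoothed recovery data with the full bi-exponential fit, the
#' fast component (plus baseline) and the baseline line — the standard
#' off-kinetics panel.
#'
#' @param object A `biexp_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.biexp_fit <- function(object, ...) {
  win <- object$data
  tt <- win$grid_time_s - object$recovery_start_s
  curves <- tibble::tibble(
    t = rep(tt, times = 2),
    vo2 = c(predict(object, tt, "full"), predict(object, tt, "fast")),
    curve = rep(c("full fit", "fast component"), each = length(tt))
  )
  ggplot2::ggplot(tibble::tibble(t = tt, vo2 = win$vo2_l_s),
                  ggplot2::aes(x = .data$t, y = .data$vo2)) +
    ggplot2::geom_point(alpha = 0.3, size = 0.6) +
    ggplot2::geom_line(data = curves,
                       ggplot2::aes(colour = .data$curve, linetype = .data$curve)) +
    ggplot2::geom_hline(yintercept = object$c, linewidth = 0.3) +
    ggplot2::scale_colour_manual(values = c("full fit" = "red",
                                            "fast component" = "blue")) +
    ggplot2::scale_linetype_manual(values = c("full fit" = "solid",
                                              "fast component" = "dashed")) +
    ggplot2::labs(x = "Time since recovery start (s)",
                  y = expression(dot(V) * O[2] ~ "(L/s)"),
                  colour = NULL, linetype = NULL) +
    ggplot2::theme_minimal()
}

#' Plot MPV trajectories across repetitions
#'
#' Absolute mean propulsive velocity and percent-of-fastest per set, across
#' the overall repetition index of a session. With several participants
#' (`participant` column present) individual lines are drawn with a
#' mean +/- SD band.
#'
#' @param table A [repetition_table()], optionally with a `participant`
#'   column, and optionally a `protocol` column for facetting.
#' @param normalized Plot percent of the set-fastest repetition instead of
#'   absolute MPV.
#' @return A ggplot.
#' @export
plot_mpv <- function(table, normalized = FALSE) {
  reps_per_set <- max(table$rep_index)
  dat <- normalize_mpv(table) |>
    dplyr::mutate(
      overall_rep = (.data$set_index - 1) * reps_per_set + .data$rep_index,
      y = if (normalized) .data$pct_of_fastest else .data$mpv_m_s
    )
  ylab <- if (normalized) "MPV (% of fastest rep in set)" else "MPV (m/s)"
  has_participants <- "participant" %in% names(dat) &&
    dplyr::n_distinct(dat$participant) > 1

  p <- ggplot2::ggplot(dat, ggplot2::aes(x = .data$overall_rep, y = .data$y))
  if (has_participants) {
    band <- dat |>
      dplyr::group_by(dplyr::across(dplyr::any_of(c("protocol", "overall_rep")))) |>
      dplyr::summarise(mean = mean(.data$y), sd = sd(.data$y), .groups = "drop")
    p <- p +
      ggplot2::geom_line(ggplot2::aes(group = .data$participant,
                                      colour = .data$participant),
                         alpha = 0.5, linewidth = 0.3) +
      ggplot2::geom_ribbon(data = band,
                           ggplot2::aes(x = .data$overall_rep,
                                        ymin = .data$mean - .data$sd,
                                        ymax = .data$mean + .data$sd),
                           inherit.aes = FALSE, alpha = 0.2) +
      ggplot2::geom_line(data = band,
                         ggplot2::aes(x = .data$overall_rep, y = .data$mean),
                         inherit.aes = FALSE, linewidth = 0.8)
  } else {
    p <- p + ggplot2::geom_line() + ggplot2::geom_point()
  }
  if ("protocol" %in% names(dat)) {
    p <- p + ggplot2::facet_wrap(~protocol)
  }
  p +
    ggplot2::labs(x = "Repetition", y = ylab, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot relative energy contributions per protocol
#'
#' Individual participant points connected across protocols with
#' mean +/- SD ranges, one panel per energy system.
#'
#' @param sessions Per-session tibble from [analyze_cohort()].
#' @return A ggplot.
#' @export
plot_energy_shares <- function(sessions) {
  long <- sessions |>
    tidyr::pivot_longer(dplyr::starts_with("rel_"),
                        names_to = "system", values_to = "rel_pct") |>
    dplyr::mutate(system = sub("^rel_(.*)_pct$", "\\1", .data$system))
  band <- long |>
    dplyr::group_by(.data$system, .data$protocol) |>
    dplyr::summarise(mean = mean(.data$rel_pct), sd = sd(.data$rel_pct),
                     .groups = "drop")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$protocol, y = .data$rel_pct)) +
    ggplot2::geom_line(ggplot2::aes(group = .data$participant),
                       alpha = 0.4, linewidth = 0.3) +
    ggplot2::geom_point(alpha = 0.5, size = 1) +
    ggplot2::geom_pointrange(data = band,
                             ggplot2::aes(y = .data$mean,
                                          ymin = .data$mean - .data$sd,
                                          ymax = .data$mean + .data$sd),
                             linewidth = 0.7, size = 0.3) +
    ggplot2::facet_wrap(~system) +
    ggplot2::labs(x = NULL, y = "Relative contribution (%)") +
    ggplot2::theme_minimal()
}
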