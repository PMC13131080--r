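# Mean-propulsive-velocity metrics: per-set and session velocity loss, and
# percent-of-fastest normalisation.

#' Velocity loss of one set
#'
#' The percentage decrease in mean propulsive velocity from the fastest to
#' the last repetition of a set: `100 * (max(MPV) - MPV_last) / max(MPV)`.
#' The fastest repetition may occur at any position within the set; when the
#' last repetition is the fastest the loss is 0.
#'
#' @param reps Ordered MPV values (m/s) of one set; at least 2 repetitions.
#' @return Velocity loss in percent.
#' @export
#' @examples
#' set_velocity_loss(c(1.00, 0.95, 0.92, 0.90, 0.85, 0.80)) # 20
set_velocity_loss <- function(reps) {
  if (length(reps) < 2) {
    rlang::abort("A set needs at least 2 repetitions to define velocity loss.")
  }
  if (any(reps <= 0)) rlang::abort("MPV values must be positive.")
  100 * (max(reps) - reps[length(reps)]) / max(reps)
}

#' Session velocity loss
#'
#' Computes the per-set velocity loss for every set of a repetition table and
#' averages across sets. Values are carried at full precision; round only at
#' report time.
#'
#' @param table A [repetition_table()] (complete grid).
#' @return An object of class `velocity_loss`: `tidy()` gives the per-set
#'   table (`set_index`, `vl_pct`, `fastest_rep_index`), `glance()` the
#'   session mean.
#' @export
session_velocity_loss <- function(table) {
  stopifnot(inherits(table, "repetition_table") || is.data.frame(table))
  per_set <- table |>
    dplyr::group_by(.data$set_index) |>
    dplyr::arrange(.data$rep_index, .by_group = TRUE) |>
    dplyr::summarise(
      vl_pct = set_velocity_loss(.data$mpv_m_s),
      fastest_rep_index = .data$rep_index[which.max(.data$mpv_m_s)],
      .groups = "drop"
    )
  structure(
    list(per_set = per_set, session_vl_pct = mean(per_set$vl_pct)),
    class = "velocity_loss"
  )
}

#' @export
print.velocity_loss <- function(x, ...) {
  cat(sprintf("<velocity_loss> session VL = %.1f%% over %d sets\n",
              x$session_vl_pct, nrow(x$per_set)))
  print(x$per_set)
  invisible(x)
}

#' @export
tidy.velocity_loss <- function(x, ...) x$per_set

#' @export
glance.velocity_loss <- function(x, ...) {
  tibble::tibble(session_vl_pct = x$session_vl_pct, n_sets = nrow(x$per_set))
}

#' Normalise MPV to percent of the fastest repetition per set
#'
#' Each repetition is expressed as `100 * MPV / max(MPV in its set)`. The set
#' maximum maps to exactly 100; profiles need not start at 100 because the
#' fastest repetition can occur anywhere in the set.
#'
#' @param table A [repetition_table()].
#' @return The table with an added `pct_of_fastest` column.
#' @export
normalize_mpv <- function(table) {
  out <- table |>
    dplyr::group_by(.data$set_index) |>
    dplyr::mutate(pct_of_fastest = 100 * .data$mpv_m_s / max(.data$mpv_m_s)) |>
    dplyr::ungroup()
  class(out) <- class(table)
  out
}
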