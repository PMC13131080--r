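# End-to-end orchestration: per-session analysis, cohort comparison, and
# report writing.

#' Analyse one session end to end
#'
#' Chains the stages in order: unit conversion and smoothing
#' ([preprocess()]), bi-exponential recovery fit ([fit_recovery()]), energy
#' partition ([partition_session()]) and velocity loss
#' ([session_velocity_loss()]).
#'
#' @param session Either a `synthetic_session` or a named list with elements
#'   `breath`, `reps`, `lactate`, `marks`, `timeline`, `participant`.
#' @param protocol Protocol label stamped on the report (taken from the
#'   timeline's spec when available).
#' @param constants [energy_constants()].
#' @param rest_attribution,negative_policy Policy switches passed to
#'   [partition_session()].
#' @param fit_window_s Recovery fit window, s.
#' @return An object of class `session_report`; `tidy()` returns the one-row
#'   per-session summary used by [compare_cohort()].
#' @export
analyze_session <- function(session, protocol = NULL,
                            constants = energy_constants(),
                            rest_attribution = c("measured", "modelled"),
                            negative_policy = c("floor", "allow"),
                            fit_window_s = 900) {
  rest_attribution <- match.arg(rest_attribution)
  negative_policy <- match.arg(negative_policy)
  needed <- c("breath", "reps", "lactate", "marks", "timeline", "participant")
  missing <- setdiff(needed, names(session))
  if (length(missing) > 0) {
    rlang::abort(paste0("Session input lacks stream(s): ",
                        paste(missing, collapse = ", ")))
  }
  spec <- attr(session$timeline, "spec")
  if (is.null(protocol)) {
    protocol <- if (!is.null(spec)) spec$label else NA_character_
  }

  smoothed <- preprocess(session$breath,
                         body_mass_kg = session$participant$body_mass_kg)
  fit <- fit_recovery(smoothed, session$marks, fit_window_s = fit_window_s)
  energy <- partition_session(
    smoothed, session$timeline, fit, session$lactate, session$participant,
    constants = constants, rest_attribution = rest_attribution,
    negative_policy = negative_policy
  )
  vl <- session_velocity_loss(session$reps)
  delta_lactate <- max(session$lactate$post_mmol_l) -
    session$lactate$baseline_mmol_l

  structure(
    list(
      participant = session$participant$id,
      protocol = protocol,
      smoothed = smoothed,
      fit = fit,
      energy = energy,
      velocity = vl,
      delta_lactate_mmol_l = delta_lactate,
      baseline_ml_kg_min = vo2_l_s_to_ml_kg_min(
        fit$c, session$participant$body_mass_kg
      ),
      constants = constants,
      policies = list(rest_attribution = rest_attribution,
                      negative_policy = negative_policy)
    ),
    class = "session_report"
  )
}

#' @export
print.session_report <- function(x, ...) {
  cat(sprintf("<session_report> %s / %s\n", x$participant, x$protocol))
  print(x$fit)
  cat(sprintf(
    "  energy: aerobic %.1f kJ (%.1f%%), alactic %.1f kJ (%.1f%%), lactic %.1f kJ (%.1f%%)\n",
    x$energy$aerobic_kj, x$energy$rel_aerobic_pct,
    x$energy$alactic_kj, x$energy$rel_alactic_pct,
    x$energy$lactic_kj, x$energy$rel_lactic_pct
  ))
  cat(sprintf("  session VL %.1f%%, lactate rise %.2f mmol/L, baseline %.2f mL/kg/min\n",
              x$velocity$session_vl_pct, x$delta_lactate_mmol_l,
              x$baseline_ml_kg_min))
  invisible(x)
}

#' @export
tidy.session_report <- function(x, ...) {
  dplyr::bind_cols(
    tibble::tibble(participant = x$participant, protocol = x$protocol),
    tibble::as_tibble(x$energy),
    tibble::tibble(
      session_vl_pct = x$velocity$session_vl_pct,
      delta_lactate_mmol_l = x$delta_lactate_mmol_l,
      baseline_ml_kg_min = x$baseline_ml_kg_min,
      fit_a = x$fit$a, fit_tau_a = x$fit$tau_a,
      fit_b = x$fit$b, fit_tau_b = x$fit$tau_b, fit_c = x$fit$c,
      fit_converged = x$fit$converged
    )
  )
}

#' Analyse every session of a cohort
#'
#' @param cohort A tibble from [generate_cohort()] (or with the same shape:
#'   `participant`, `protocol`, `session` list-column).
#' @param ... Passed to [analyze_session()].
#' @return A tibble with one row per session (the `tidy()` summaries).
#' @export
analyze_cohort <- function(cohort, ...) {
  purrr::map(cohort$session, analyze_session, ...) |>
    purrr::map(tidy) |>
    dplyr::bind_rows()
}

#' Compare the two protocols across a cohort
#'
#' The inferential layer of the crossover design: a Student's paired t-test
#' with Hedges' g on session velocity loss, a Wilcoxon signed-rank test
#' (exact for small n) with Hedges' g on the lactate rise, Shapiro-Wilk
#' checks on both difference sets, and the mixed model on relative energy
#' contributions ([fit_energy_lmm()]). Differences are taken CS minus TS.
#'
#' @param sessions Per-session summary tibble from [analyze_cohort()]
#'   (columns `participant`, `protocol`, `rel_*_pct`, `session_vl_pct`,
#'   `delta_lactate_mmol_l`).
#' @return An object of class `cohort_report` with elements `summary`
#'   (mean +/- SD per protocol), `vl_test`, `vl_shapiro`, `lactate_test`,
#'   `lactate_g`, `lactate_shapiro` and `lmm`.
#' @export
compare_cohort <- function(sessions) {
  sessions <- dplyr::mutate(
    sessions, protocol = factor(.data$protocol, levels = c("CS", "TS"))
  )
  unpaired <- sessions |>
    dplyr::count(.data$participant) |>
    dplyr::filter(.data$n != 2)
  if (nrow(unpaired) > 0) {
    rlang::abort(paste0("Unpaired participants: ",
                        paste(unpaired$participant, collapse = ", ")))
  }

  summary_tbl <- sessions |>
    dplyr::group_by(.data$protocol) |>
    dplyr::summarise(dplyr::across(
      c("session_vl_pct", "delta_lactate_mmol_l", "rel_aerobic_pct",
        "rel_alactic_pct", "rel_lactic_pct"),
      list(mean = mean, sd = sd)
    ), .groups = "drop")

  vl_diffs <- paired_differences(sessions, session_vl_pct,
                                 protocol, participant)
  lact_diffs <- paired_differences(sessions, delta_lactate_mmol_l,
                                   protocol, participant)

  long <- sessions |>
    dplyr::select("participant", "protocol", "rel_aerobic_pct",
                  "rel_alactic_pct", "rel_lactic_pct") |>
    tidyr::pivot_longer(dplyr::starts_with("rel_"),
                        names_to = "system", values_to = "rel_pct") |>
    dplyr::mutate(system = sub("^rel_(.*)_pct$", "\\1", .data$system))

  structure(
    list(
      summary = summary_tbl,
      vl_test = paired_t(vl_diffs),
      vl_shapiro = shapiro_wilk(vl_diffs),
      lactate_test = wilcoxon_signed_rank(lact_diffs),
      lactate_g = hedges_g_paired(lact_diffs),
      lactate_shapiro = shapiro_wilk(lact_diffs),
      lmm = fit_energy_lmm(long),
      sessions = sessions
    ),
    class = "cohort_report"
  )
}

#' @export
print.cohort_report <- function(x, ...) {
  cat("<cohort_report>\n")
  cat("Per-protocol summary (mean / sd):\n")
  print(as.data.frame(x$summary), digits = 3)
  cat(sprintf("VL paired t: t(%d) = %.2f, p = %.4f, g = %.2f\n",
              x$vl_test$df, x$vl_test$t, x$vl_test$p, x$vl_test$hedges_g))
  cat(sprintf("Lactate rise Wilcoxon: V = %g, p = %.4f (g = %.2f)\n",
              x$lactate_test$statistic, x$lactate_test$p, x$lactate_g))
  g <- glance(x$lmm)
  cat(sprintf("Energy LMM interaction: F(%g, %.1f) = %.2f, p = %.2g\n",
              g$interaction_num_df, g$interaction_den_df, g$interaction_f,
              g$interaction_p))
  invisible(x)
}

#' Write a run report to disk
#'
#' Writes a JSON report (fits, energies, velocity loss, statistics, resolved
#' constants and policies) plus a tidy per-session CSV. Output is
#' deterministic given identical inputs.
#'
#' @param sessions Per-session tibble from [analyze_cohort()].
#' @param dir Output directory (created if needed).
#' @param comparison Optional `cohort_report` from [compare_cohort()].
#' @return Invisibly, the paths written.
#' @export
write_report <- function(sessions, dir, comparison = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  csv_path <- file.path(dir, "sessions.csv")
  readr::write_csv(sessions, csv_path)

  report <- list(sessions = sessions)
  if (!is.null(comparison)) {
    report$comparison <- list(
      summary = comparison$summary,
      vl_test = comparison$vl_test,
      vl_shapiro = comparison$vl_shapiro,
      lactate_test = comparison$lactate_test,
      lactate_g = comparison$lactate_g,
      lactate_shapiro = comparison$lactate_shapiro,
      lmm_anova = comparison$lmm$anova,
      lmm_contrasts = comparison$lmm$contrasts
    )
  }
  json_path <- file.path(dir, "report.json")
  jsonlite::write_json(report, json_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(c(csv = csv_path, json = json_path))
}
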