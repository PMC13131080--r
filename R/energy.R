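# The three-component (PCr-La-O2) energy partition: aerobic energy from
# baseline-adjusted VO2 during work, anaerobic alactic energy from the fast
# recovery component integrated over every rest window, anaerobic lactic
# energy from the net blood lactate rise.

#' Energy conversion constants
#'
#' The caloric equivalent of oxygen (20.92 kJ per litre O2) and the lactate
#' oxygen equivalent (3 mL O2 per kg body mass per mmol/L net lactate rise).
#'
#' @param caloric_equiv_kj_per_l_o2 kJ per litre O2 (default 20.92).
#' @param lactate_o2_equiv_ml_per_kg_per_mmol mL O2 per kg body mass per
#'   mmol/L (default 3).
#' @return A named list of class `energy_constants`.
#' @export
energy_constants <- function(caloric_equiv_kj_per_l_o2 = 20.92,
                             lactate_o2_equiv_ml_per_kg_per_mmol = 3) {
  if (caloric_equiv_kj_per_l_o2 <= 0 || lactate_o2_equiv_ml_per_kg_per_mmol <= 0) {
    rlang::abort("Energy constants must be strictly positive.")
  }
  structure(
    list(
      caloric_equiv_kj_per_l_o2 = caloric_equiv_kj_per_l_o2,
      lactate_o2_equiv_ml_per_kg_per_mmol = lactate_o2_equiv_ml_per_kg_per_mmol
    ),
    class = "energy_constants"
  )
}

#' Closed-form integral of an exponential component
#'
#' Integrates `amplitude * exp(-t / tau)` from 0 to `duration_s`:
#' `amplitude * tau * (1 - exp(-duration_s / tau))`. This is the oxygen
#' volume attributed to one decay component over one rest window.
#'
#' @param amplitude Component amplitude, L/s.
#' @param tau Time constant, s (> 0).
#' @param duration_s Window duration, s (>= 0).
#' @return Litres of O2 (vectorised over the inputs).
#' @export
#' @examples
#' component_integral(0.030, 35, 30) # ~0.604 L
component_integral <- function(amplitude, tau, duration_s) {
  if (any(tau <= 0)) rlang::abort("`tau` must be positive.")
  if (any(duration_s < 0)) rlang::abort("`duration_s` must be non-negative.")
  amplitude * tau * (1 - exp(-duration_s / tau))
}

# Trapezoidal integral of a 1-s gridded series over [from, to], resolving
# fractional edges by linear interpolation.
integrate_series <- function(time, value, from, to) {
  if (to <= from) return(0)
  if (from < min(time) - 1e-9 || to > max(time) + 1e-9) {
    rlang::abort(sprintf(
      "Integration window [%.1f, %.1f] s lies outside the measured span [%.1f, %.1f] s.",
      from, to, min(time), max(time)
    ))
  }
  f <- stats::approxfun(time, value, rule = 2)
  knots <- time[time > from & time < to]
  xs <- c(from, knots, to)
  ys <- f(xs)
  sum(diff(xs) * (head(ys, -1) + tail(ys, -1)) / 2)
}

#' Aerobic energy over the exercise phase
#'
#' Integrates baseline-adjusted oxygen uptake, `max(VO2 - c, 0)`, over the
#' exercise phase and removes the rest windows, so that the aerobic energy
#' reflects only the work periods. Two attribution policies are available:
#'
#' * `"measured"` (default): the measured rest-window integrals are
#'   subtracted from the total exercise-phase integral — numerically equal
#'   to integrating over the work segments only.
#' * `"modelled"`: the modelled recovery components are subtracted instead
#'   (fast component over intra-set rests; fast and slow over inter-set
#'   rests), which requires `fit`.
#'
#' @param series A [smoothed_series()].
#' @param timeline A `session_timeline` from [build_timeline()].
#' @param c_baseline Baseline oxygen uptake in L/s (the `c` of an unflagged
#'   [fit_recovery()] fit).
#' @param constants [energy_constants()].
#' @param rest_attribution `"measured"` or `"modelled"`.
#' @param fit A `biexp_fit`, required for `rest_attribution = "modelled"`.
#' @return Energy in kJ.
#' @export
aerobic_energy <- function(series, timeline, c_baseline,
                           constants = energy_constants(),
                           rest_attribution = c("measured", "modelled"),
                           fit = NULL) {
  rest_attribution <- match.arg(rest_attribution)
  stopifnot(inherits(series, "smoothed_series"))
  timeline_validate(timeline)
  adj <- pmax(series$vo2_l_s - c_baseline, 0)
  t <- series$grid_time_s

  work <- timeline_segments(timeline, "work")
  rests <- timeline_segments(timeline, c("intra_rest", "inter_rest"))

  litres <- if (rest_attribution == "measured") {
    # total over [exercise start, exercise end] minus measured rest windows
    # == sum over work segments
    sum(purrr::map2_dbl(work$start_s, work$end_s,
                        ~ integrate_series(t, adj, .x, .y)))
  } else {
    if (is.null(fit) || !isTRUE(fit$converged)) {
      rlang::abort("`rest_attribution = \"modelled\"` needs an unflagged `fit`.")
    }
    total <- integrate_series(t, adj, min(work$start_s), max(rests$end_s, work$end_s))
    modelled_rest <- sum(purrr::pmap_dbl(
      list(rests$kind, rests$start_s, rests$end_s),
      function(kind, s0, s1) {
        d <- s1 - s0
        fast <- component_integral(fit$a, fit$tau_a, d)
        slow <- component_integral(fit$b, fit$tau_b, d)
        if (kind == "intra_rest") fast else fast + slow
      }
    ))
    max(total - modelled_rest, 0)
  }
  litres * constants$caloric_equiv_kj_per_l_o2
}

#' Anaerobic alactic energy from the fast recovery component
#'
#' Integrates the fitted fast component `a * exp(-t / tau_a)` in closed form
#' over every rest window of the session: the final seated recovery (once),
#' each inter-set rest, and — for cluster-set protocols — each intra-set
#' pause. The final-recovery estimates of `(a, tau_a)` are re-used for every
#' window, each window's local clock starting at zero; short rests do not
#' allow reliable curve fitting, so equal fast-component repayment after
#' every cluster or set is a modelling assumption of the method.
#'
#' @param fit An unflagged `biexp_fit`.
#' @param timeline A `session_timeline`.
#' @param constants [energy_constants()].
#' @param force Set `TRUE` to use a flagged (non-converged) fit anyway.
#' @return Energy in kJ.
#' @export
alactic_energy <- function(fit, timeline, constants = energy_constants(),
                           force = FALSE) {
  stopifnot(inherits(fit, "biexp_fit"))
  if (!isTRUE(fit$converged) && !force) {
    rlang::abort("Refusing a flagged (non-converged) fit; set `force = TRUE` to override.")
  }
  timeline_validate(timeline)
  wins <- timeline_segments(timeline, c("intra_rest", "inter_rest", "final_recovery"))
  litres <- sum(component_integral(fit$a, fit$tau_a, wins$end_s - wins$start_s))
  litres * constants$caloric_equiv_kj_per_l_o2
}

#' Anaerobic lactic energy from the net blood lactate rise
#'
#' The baseline-to-peak lactate rise is converted to an oxygen equivalent
#' (3 mL O2 per kg body mass per mmol/L) and then to energy via the caloric
#' equivalent. A negative rise (peak below baseline) is floored at zero with
#' a warning under the default policy; `negative_policy = "allow"` keeps the
#' negative value.
#'
#' @param panel A [lactate_panel()].
#' @param participant A [participant_info()] (body mass is used).
#' @param constants [energy_constants()].
#' @param negative_policy `"floor"` (default) or `"allow"`.
#' @return Energy in kJ.
#' @export
#' @examples
#' p <- lactate_panel(1.0, c("60" = 2.1, "180" = 3.0, "300" = 2.6))
#' lactic_energy(p, participant_info("P1", 75))
lactic_energy <- function(panel, participant,
                          constants = energy_constants(),
                          negative_policy = c("floor", "allow")) {
  negative_policy <- match.arg(negative_policy)
  stopifnot(inherits(panel, "lactate_panel"))
  delta <- max(panel$post_mmol_l) - panel$baseline_mmol_l
  if (delta < 0 && negative_policy == "floor") {
    rlang::warn(sprintf(
      "Negative lactate rise (%.2f mmol/L) floored at 0.", delta
    ))
    delta <- 0
  }
  ml_o2 <- delta * constants$lactate_o2_equiv_ml_per_kg_per_mmol *
    participant$body_mass_kg
  (ml_o2 / 1000) * constants$caloric_equiv_kj_per_l_o2
}

#' Partition one session into its three energy components
#'
#' Combines [aerobic_energy()], [alactic_energy()] and [lactic_energy()]
#' into absolute energies (kJ) and relative contributions (%).
#'
#' @inheritParams aerobic_energy
#' @inheritParams lactic_energy
#' @param fit An unflagged `biexp_fit`; its `c` is the baseline for the
#'   aerobic integral.
#' @return A one-row tibble of class `energy_components` with columns
#'   `aerobic_kj`, `alactic_kj`, `lactic_kj`, `total_kj`, `rel_aerobic_pct`,
#'   `rel_alactic_pct`, `rel_lactic_pct`.
#' @export
partition_session <- function(series, timeline, fit, panel, participant,
                              constants = energy_constants(),
                              rest_attribution = c("measured", "modelled"),
                              negative_policy = c("floor", "allow")) {
  rest_attribution <- match.arg(rest_attribution)
  negative_policy <- match.arg(negative_policy)
  aer <- aerobic_energy(series, timeline, fit$c, constants,
                        rest_attribution = rest_attribution, fit = fit)
  ala <- alactic_energy(fit, timeline, constants)
  lac <- lactic_energy(panel, participant, constants, negative_policy)
  energy_components(aer, ala, lac)
}

#' Assemble an energy-components row
#'
#' @param aerobic_kj,alactic_kj,lactic_kj Absolute energies, kJ.
#' @return A one-row tibble of class `energy_components`.
#' @export
energy_components <- function(aerobic_kj, alactic_kj, lactic_kj) {
  total <- aerobic_kj + alactic_kj + lactic_kj
  if (!is.finite(total) || total <= 0) {
    rlang::abort("Total energy must be positive (degenerate session).")
  }
  out <- tibble::tibble(
    aerobic_kj = aerobic_kj,
    alactic_kj = alactic_kj,
    lactic_kj = lactic_kj,
    total_kj = total,
    rel_aerobic_pct = 100 * aerobic_kj / total,
    rel_alactic_pct = 100 * alactic_kj / total,
    rel_lactic_pct = 100 * lactic_kj / total
  )
  class(out) <- c("energy_components", class(out))
  out
}
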