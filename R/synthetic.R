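# Synthetic cluster-set / traditional-set sessions with a known ground
# truth, so the whole pipeline is testable without any measured data.
#
# The generative VO2 path is piecewise closed-form on the session timeline:
# a mono-exponential rise toward the work demand during work segments and a
# bi-exponential decay during every rest, re-anchored at each rest onset
# from the current elevation with the fast:slow amplitudes in the configured
# a:b ratio (so the modelled VO2 is continuous at work/rest transitions).

#' Configuration of the synthetic session generator
#'
#' Defaults emulate the study conditions: a ~5.4 mL/kg/min baseline,
#' breath-by-breath sampling about every 3 s with +/-30% jitter, Gaussian
#' noise at 5% of peak modelled oxygen uptake, a fast recovery component
#' around tau 35 s and a slow component around tau 240 s, per-repetition
#' velocity fatigue with partial recovery during rests, and lactate
#' accumulation once fatigue exceeds a threshold.
#'
#' @param body_mass_kg Body mass (kg).
#' @param baseline_vo2_l_s Baseline oxygen uptake `c`, L/s.
#' @param on_tau_s Time constant of the mono-exponential rise during work, s.
#' @param work_demand_l_s Steady-state oxygen demand above baseline during
#'   work, L/s.
#' @param a,tau_a,b,tau_b Recovery truth: fast/slow amplitudes (their ratio
#'   fixes the fast:slow split at every rest onset) and time constants, s.
#' @param breath_interval_s Mean breath spacing, s.
#' @param breath_jitter_frac Uniform jitter fraction on the breath spacing.
#' @param noise_sd_l_s Additive Gaussian noise on sampled VO2 (L/s); `NULL`
#'   means 5% of peak modelled uptake (`baseline + work_demand`).
#' @param base_mpv_m_s Unfatigued mean propulsive velocity, m/s.
#' @param per_rep_fatigue_increment Fatigue added per repetition
#'   (dimensionless fraction of `base_mpv_m_s`).
#' @param rest_recovery_tau_s Exponential decay time of fatigue during
#'   rests, s.
#' @param mpv_noise_sd_m_s Gaussian noise on each repetition's MPV, m/s.
#' @param lactate_baseline_mmol_l Baseline blood lactate, mmol/L.
#' @param lactate_per_rep_mmol_l Lactate added per repetition performed above
#'   the fatigue threshold, mmol/L.
#' @param lactate_fatigue_threshold Fatigue level above which repetitions
#'   accumulate lactate.
#' @param lactate_clearance_mmol_per_s Linear lactate clearance per rest
#'   second, mmol/L/s (floored at baseline).
#' @param lactate_noise_sd_mmol_l Gaussian noise on sampled lactate, mmol/L.
#' @param rep_duration_s Seconds per repetition.
#' @param baseline_duration_s Pre-exercise baseline segment, s.
#' @param seed Integer seed fixing the full sample path.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(body_mass_kg = 72,
                             baseline_vo2_l_s = 0.0065,
                             on_tau_s = 20,
                             work_demand_l_s = 0.045,
                             a = 0.028, tau_a = 35,
                             b = 0.012, tau_b = 240,
                             breath_interval_s = 3,
                             breath_jitter_frac = 0.3,
                             noise_sd_l_s = NULL,
                             base_mpv_m_s = 0.68,
                             per_rep_fatigue_increment = 0.04,
                             rest_recovery_tau_s = 60,
                             mpv_noise_sd_m_s = 0.01,
                             lactate_baseline_mmol_l = 1.2,
                             lactate_per_rep_mmol_l = 0.25,
                             lactate_fatigue_threshold = 0.08,
                             lactate_clearance_mmol_per_s = 0.002,
                             lactate_noise_sd_mmol_l = 0.1,
                             rep_duration_s = 3.5,
                             baseline_duration_s = 120,
                             seed = 1L) {
  cfg <- as.list(environment())
  if (is.null(cfg$noise_sd_l_s)) {
    cfg$noise_sd_l_s <- 0.05 * (baseline_vo2_l_s + work_demand_l_s)
  }
  positives <- c("body_mass_kg", "baseline_vo2_l_s", "on_tau_s",
                 "work_demand_l_s", "a", "tau_a", "b", "tau_b",
                 "breath_interval_s", "base_mpv_m_s", "rest_recovery_tau_s",
                 "rep_duration_s", "baseline_duration_s")
  for (nm in positives) {
    if (!is.finite(cfg[[nm]]) || cfg[[nm]] <= 0) {
      rlang::abort(sprintf("`%s` must be positive.", nm))
    }
  }
  if (cfg$tau_a >= cfg$tau_b) {
    rlang::abort("`tau_a` must be smaller than `tau_b`.")
  }
  structure(cfg, class = "synthetic_config")
}

# Per-segment elevation state: elevation above baseline at each segment
# start, propagated in closed form across the timeline.
segment_states <- function(config, timeline) {
  ra <- config$a / (config$a + config$b)
  rb <- 1 - ra
  e0 <- numeric(nrow(timeline))
  e <- 0
  for (i in seq_len(nrow(timeline))) {
    e0[i] <- e
    d <- timeline$end_s[i] - timeline$start_s[i]
    e <- switch(timeline$kind[i],
      baseline = e,
      work = config$work_demand_l_s -
        (config$work_demand_l_s - e) * exp(-d / config$on_tau_s),
      # any rest kind: bi-exponential decay of the current elevation
      e * (ra * exp(-d / config$tau_a) + rb * exp(-d / config$tau_b))
    )
  }
  dplyr::mutate(tibble::as_tibble(timeline), e0 = e0)
}

# Noiseless generative VO2 (L/s) at arbitrary session times.
vo2_truth_at <- function(t, config, states) {
  ra <- config$a / (config$a + config$b)
  rb <- 1 - ra
  idx <- findInterval(t, states$start_s, rightmost.closed = TRUE)
  idx[idx < 1] <- 1
  idx[idx > nrow(states)] <- nrow(states)
  dt <- t - states$start_s[idx]
  e0 <- states$e0[idx]
  kind <- states$kind[idx]
  elev <- ifelse(
    kind == "baseline", e0,
    ifelse(
      kind == "work",
      config$work_demand_l_s - (config$work_demand_l_s - e0) * exp(-dt / config$on_tau_s),
      e0 * (ra * exp(-dt / config$tau_a) + rb * exp(-dt / config$tau_b))
    )
  )
  config$baseline_vo2_l_s + elev
}

# Fatigue / lactate bookkeeping shared by the MPV table and lactate panel.
# Returns rep rows with the fatigue state before each rep, plus lactate at
# segment boundaries.
simulate_mechanics <- function(config, spec, timeline) {
  reps <- list()
  f <- 0
  lact <- config$lactate_baseline_mmol_l
  lact_trace <- numeric(nrow(timeline)) # lactate at each segment END
  rep_counter <- integer(spec$n_sets)
  for (i in seq_len(nrow(timeline))) {
    seg <- timeline[i, ]
    d <- seg$end_s - seg$start_s
    if (seg$kind == "work") {
      s <- seg$set_index
      n_rep <- round(d / config$rep_duration_s)
      for (r in seq_len(n_rep)) {
        rep_counter[s] <- rep_counter[s] + 1L
        if (f >= config$lactate_fatigue_threshold) {
          lact <- lact + config$lactate_per_rep_mmol_l
        }
        reps[[length(reps) + 1L]] <- tibble::tibble(
          set_index = s,
          rep_index = rep_counter[s],
          fatigue_before = f,
          time_s = seg$start_s + (r - 0.5) * config$rep_duration_s
        )
        f <- f + config$per_rep_fatigue_increment
      }
    } else if (seg$kind != "baseline") {
      f <- f * exp(-d / config$rest_recovery_tau_s)
      lact <- max(config$lactate_baseline_mmol_l,
                  lact - config$lactate_clearance_mmol_per_s * d)
    }
    lact_trace[i] <- lact
  }
  list(reps = dplyr::bind_rows(reps), lactate_trace = lact_trace)
}

#' Generate one synthetic session
#'
#' Produces the four measurement streams of one session (breath-by-breath
#' oxygen uptake, per-repetition velocities, lactate panel, phase marks)
#' together with the timeline and the ground-truth energy ledger. Identical
#' seeds give identical sessions.
#'
#' @param config A [synthetic_config()].
#' @param spec A [protocol_spec()].
#' @param participant_id Identifier stamped on the streams.
#' @return A list of class `synthetic_session` with elements `breath`
#'   (a [breath_series()], in mL/min), `reps` ([repetition_table()]),
#'   `lactate` ([lactate_panel()]), `marks` ([phase_marks()]), `timeline`,
#'   `participant` ([participant_info()]), `truth` (see [truth_energy()])
#'   and `config`.
#' @export
generate_session <- function(config, spec, participant_id = "S1") {
  stopifnot(inherits(config, "synthetic_config"), inherits(spec, "protocol_spec"))
  if (config$work_demand_l_s + config$baseline_vo2_l_s <= 0) {
    rlang::abort("Configuration implies non-positive oxygen uptake.")
  }
  if (!is.null(config$seed)) set.seed(config$seed)

  timeline <- build_timeline(spec,
                             baseline_duration_s = config$baseline_duration_s,
                             rep_duration_s = config$rep_duration_s)
  states <- segment_states(config, timeline)
  total <- max(timeline$end_s)

  # breath times: jittered intervals from t = 0 to the session end
  times <- numeric(0)
  t <- 0
  while (t <= total) {
    times <- c(times, t)
    t <- t + config$breath_interval_s *
      (1 + stats::runif(1, -config$breath_jitter_frac, config$breath_jitter_frac))
  }
  vo2_l_s <- vo2_truth_at(times, config, states) +
    stats::rnorm(length(times), 0, config$noise_sd_l_s)
  vo2_l_s <- pmax(vo2_l_s, 0)
  breath <- breath_series(times, vo2_l_s * 60000, unit = "ml_min",
                          participant_id = participant_id)

  mech <- simulate_mechanics(config, spec, timeline)
  reps <- mech$reps |>
    dplyr::mutate(
      mpv_m_s = pmax(
        config$base_mpv_m_s * (1 - .data$fatigue_before) +
          stats::rnorm(dplyr::n(), 0, config$mpv_noise_sd_m_s),
        0.05
      )
    ) |>
    dplyr::select("set_index", "rep_index", "mpv_m_s")
  reps <- repetition_table(reps)

  # lactate panel: end-of-exercise lactate declines/peaks post-exercise with
  # a fixed appearance profile (peak at +180 s)
  exercise_end_i <- max(which(timeline$kind == "work"))
  l_end <- mech$lactate_trace[exercise_end_i]
  base_l <- config$lactate_baseline_mmol_l
  rise <- l_end - base_l
  post_profile <- c("60" = 0.92, "180" = 1.00, "300" = 0.95)
  post <- pmax(base_l + rise * post_profile +
                 stats::rnorm(3, 0, config$lactate_noise_sd_mmol_l), 0)
  names(post) <- names(post_profile)
  # pre-final-set sample: 60 s before the last set starts (QC only)
  last_set_start <- min(timeline$start_s[timeline$kind == "work" &
    timeline$set_index == spec$n_sets])
  pre_i <- max(which(timeline$end_s <= last_set_start - 60))
  pre_sample <- max(base_l, mech$lactate_trace[pre_i])
  panel <- lactate_panel(
    baseline_mmol_l = max(0, base_l + stats::rnorm(1, 0, config$lactate_noise_sd_mmol_l)),
    post_mmol_l = post,
    pre_final_set_mmol_l = pre_sample
  )

  marks <- phase_marks(
    exercise_start_s = config$baseline_duration_s,
    recovery_start_s = timeline$start_s[timeline$kind == "final_recovery"]
  )

  structure(
    list(
      breath = breath,
      reps = reps,
      lactate = panel,
      marks = marks,
      timeline = timeline,
      participant = participant_info(participant_id, config$body_mass_kg),
      truth = truth_energy(config, spec),
      config = config
    ),
    class = "synthetic_session"
  )
}

#' @export
print.synthetic_session <- function(x, ...) {
  cat(sprintf("<synthetic_session> %s, %d breaths, %d reps, %.0f s total\n",
              attr(x$breath, "participant_id"), nrow(x$breath), nrow(x$reps),
              timeline_duration(x$timeline)))
  invisible(x)
}

#' Ground-truth energy ledger of a synthetic session
#'
#' Computes the energy partition from the noiseless generative path in
#' closed form, using the same attribution rules as [partition_session()]:
#' aerobic energy is the elevation integral over the work segments; alactic
#' energy integrates the fast component with the final-recovery amplitude
#' re-used over every rest window; lactic energy converts the end-exercise
#' lactate rise. The returned object also carries the session's true
#' recovery kinetics (`a`, `tau_a`, `b`, `tau_b`, `c` of the final
#' recovery) as the `kinetics` attribute.
#'
#' @param config A [synthetic_config()].
#' @param spec A [protocol_spec()].
#' @return An [energy_components()] row with a `kinetics` attribute.
#' @export
truth_energy <- function(config, spec) {
  timeline <- build_timeline(spec,
                             baseline_duration_s = config$baseline_duration_s,
                             rep_duration_s = config$rep_duration_s)
  states <- segment_states(config, timeline)
  ra <- config$a / (config$a + config$b)
  const <- energy_constants()

  work <- states[states$kind == "work", ]
  d <- work$end_s - work$start_s
  aerobic_l <- sum(
    config$work_demand_l_s * d -
      (config$work_demand_l_s - work$e0) * config$on_tau_s *
        (1 - exp(-d / config$on_tau_s))
  )

  final_i <- which(states$kind == "final_recovery")
  a_session <- states$e0[final_i] * ra
  rests <- states[states$kind %in% c("intra_rest", "inter_rest", "final_recovery"), ]
  alactic_l <- sum(component_integral(a_session, config$tau_a,
                                      rests$end_s - rests$start_s))

  mech <- simulate_mechanics(config, spec, timeline)
  l_end <- mech$lactate_trace[max(which(timeline$kind == "work"))]
  delta <- max(0, l_end - config$lactate_baseline_mmol_l)
  lactic_kj <- delta * const$lactate_o2_equiv_ml_per_kg_per_mmol *
    config$body_mass_kg / 1000 * const$caloric_equiv_kj_per_l_o2

  out <- energy_components(
    aerobic_kj = aerobic_l * const$caloric_equiv_kj_per_l_o2,
    alactic_kj = alactic_l * const$caloric_equiv_kj_per_l_o2,
    lactic_kj = lactic_kj
  )
  attr(out, "kinetics") <- list(
    a = a_session, tau_a = config$tau_a,
    b = states$e0[final_i] * (1 - ra), tau_b = config$tau_b,
    c = config$baseline_vo2_l_s,
    delta_lactate_mmol_l = delta
  )
  out
}

#' Generate a paired synthetic cohort
#'
#' Generates `n_participants` participants, each completing one CS and one
#' TS session, with participant-level variation in body mass, baseline
#' uptake, work demand, recovery amplitudes and velocity, all derived from
#' one master seed.
#'
#' @param n_participants Number of participants (default 6).
#' @param seed Master seed.
#' @param config Template [synthetic_config()]; participant-level factors
#'   perturb it.
#' @param cs_spec,ts_spec The two protocols.
#' @return A tibble with one row per session (`participant`, `protocol`,
#'   `session` list-column of [generate_session()] results).
#' @export
generate_cohort <- function(n_participants = 6, seed = 1L,
                            config = synthetic_config(),
                            cs_spec = protocol_spec("CS"),
                            ts_spec = protocol_spec("TS")) {
  set.seed(seed)
  draws <- tibble::tibble(
    participant = sprintf("P%02d", seq_len(n_participants)),
    body_mass_kg = stats::runif(n_participants, 59, 85),
    baseline_scale = stats::runif(n_participants, 0.85, 1.15),
    demand_scale = stats::runif(n_participants, 0.85, 1.15),
    amp_scale = stats::runif(n_participants, 0.85, 1.15),
    base_mpv_m_s = stats::runif(n_participants, 0.60, 0.76),
    session_seed = sample.int(.Machine$integer.max %/% 2, n_participants)
  )
  sessions <- purrr::pmap(draws, function(participant, body_mass_kg,
                                          baseline_scale, demand_scale,
                                          amp_scale, base_mpv_m_s,
                                          session_seed) {
    cfg <- config
    cfg$body_mass_kg <- body_mass_kg
    cfg$baseline_vo2_l_s <- config$baseline_vo2_l_s * baseline_scale
    cfg$work_demand_l_s <- config$work_demand_l_s * demand_scale
    cfg$a <- config$a * amp_scale
    cfg$b <- config$b * amp_scale
    cfg$base_mpv_m_s <- base_mpv_m_s
    cfg_cs <- cfg
    cfg_cs$seed <- session_seed
    cfg_ts <- cfg
    cfg_ts$seed <- session_seed + 1L
    list(
      CS = generate_session(cfg_cs, cs_spec, participant_id = participant),
      TS = generate_session(cfg_ts, ts_spec, participant_id = participant)
    )
  })
  tibble::tibble(
    participant = rep(draws$participant, each = 2),
    protocol = rep(c("CS", "TS"), n_participants),
    session = purrr::flatten(sessions)
  )
}
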