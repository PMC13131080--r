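# Shared fixture builders and independent oracles.

# A 1 Hz smoothed series sampled directly from the bi-exponential model
# (no smoothing involved, so phase_shift_s = 0).
make_biexp_series <- function(truth, t = 0:900, noise_sd = 0, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  y <- truth$a * exp(-t / truth$tau_a) + truth$b * exp(-t / truth$tau_b) + truth$c
  if (noise_sd > 0) y <- y + rnorm(length(t), 0, noise_sd)
  smoothed_series(t, pmax(y, 0))
}

# Brute-force oracle for the recovery fit: a coarse grid search over the
# two time constants with a linear least-squares solve for the amplitudes
# and baseline. Independent of the package's optimiser; its resolution is
# what makes it a bound rather than a competitor.
grid_search_tau_a <- function(t, y, n_grid = 15) {
  taus_a <- exp(seq(log(5), log(120), length.out = n_grid))
  taus_b <- exp(seq(log(120), log(1800), length.out = n_grid))
  best <- list(rss = Inf, tau_a = NA_real_)
  for (ta in taus_a) {
    ea <- exp(-t / ta)
    for (tb in taus_b) {
      X <- cbind(ea, exp(-t / tb), 1)
      fit <- .lm.fit(X, y)
      rss <- sum(fit$residuals^2)
      if (rss < best$rss) best <- list(rss = rss, tau_a = ta)
    }
  }
  best$tau_a
}

# Fine-grid trapezoidal oracle for the closed-form component integral.
trapz_component <- function(amplitude, tau, duration_s, dt = 0.01) {
  t <- seq(0, duration_s, by = dt)
  if (t[length(t)] < duration_s) t <- c(t, duration_s)
  y <- amplitude * exp(-t / tau)
  sum(diff(t) * (head(y, -1) + tail(y, -1)) / 2)
}

# A minimal single-work-block timeline: baseline, work (optionally split by
# one intra-set rest), final recovery.
flat_session_timeline <- function(work_durations, intra_rest_s = NULL,
                                  baseline_s = 100, recovery_s = 900) {
  kind <- "baseline"
  dur <- baseline_s
  for (i in seq_along(work_durations)) {
    kind <- c(kind, "work")
    dur <- c(dur, work_durations[i])
    if (!is.null(intra_rest_s) && i < length(work_durations)) {
      kind <- c(kind, "intra_rest")
      dur <- c(dur, intra_rest_s)
    }
  }
  kind <- c(kind, "final_recovery")
  dur <- c(dur, recovery_s)
  end_s <- cumsum(dur)
  out <- tibble::tibble(
    kind = kind, start_s = c(0, end_s[-length(end_s)]), end_s = end_s,
    set_index = NA_integer_, cluster_index = NA_integer_
  )
  class(out) <- c("session_timeline", class(out))
  out
}

noiseless_config <- function(...) {
  synthetic_config(noise_sd_l_s = 0, mpv_noise_sd_m_s = 0,
                   lactate_noise_sd_mmol_l = 0, ...)
}
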