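# Preprocessing of breath-by-breath series and the bi-exponential
# off-kinetics fit whose parameters drive the energy partition.

#' Construct a smoothed 1-s series directly
#'
#' Mostly useful for tests and simulations; real data should go through
#' [preprocess()].
#'
#' @param grid_time_s Integer-second time grid (uniform 1-s spacing).
#' @param vo2_l_s Oxygen uptake at each grid point, L/s.
#' @param source_unit Provenance note.
#' @param phase_shift_s Effective time shift introduced by smoothing (0 for
#'   directly constructed series).
#' @return A tibble of class `smoothed_series`.
#' @export
smoothed_series <- function(grid_time_s, vo2_l_s, source_unit = "l_s",
                            phase_shift_s = 0) {
  if (length(grid_time_s) > 1 && any(abs(diff(grid_time_s) - 1) > 1e-9)) {
    rlang::abort("`grid_time_s` must have uniform 1-s spacing.")
  }
  if (any(vo2_l_s < 0)) {
    rlang::abort("`vo2_l_s` must be non-negative.")
  }
  out <- tibble::tibble(grid_time_s = as.numeric(grid_time_s),
                        vo2_l_s = as.numeric(vo2_l_s))
  class(out) <- c("smoothed_series", class(out))
  attr(out, "source_unit") <- source_unit
  attr(out, "phase_shift_s") <- phase_shift_s
  out
}

# Moving average over window i+offsets, window shrinking at the edges.
moving_average <- function(x, offsets) {
  n <- length(x)
  vapply(seq_len(n), function(i) {
    idx <- i + offsets
    idx <- idx[idx >= 1 & idx <= n]
    mean(x[idx])
  }, numeric(1))
}

#' Preprocess a breath-by-breath series
#'
#' Converts the declared unit to litres per second, resamples the irregular
#' breath times to a uniform 1-s grid by linear interpolation, and applies a
#' centred 10-point moving average. The even-length window is defined as the
#' mean of samples i-5..i+4 (`centring = "left"`); `centring = "right"` gives
#' i-4..i+5. The window shrinks at the series edges. An even window is not
#' symmetric about the sample, so it shifts the effective time base by half a
#' second (the left-heavy default window delays the curve, so
#' `phase_shift_s = -0.5`; the right variant advances it); the shift is
#' recorded on the result and compensated by [fit_recovery()].
#'
#' Negative values after smoothing (possible only with ill-behaved inputs)
#' are clipped to zero with a warning.
#'
#' @param series A [breath_series()].
#' @param body_mass_kg Body mass, required when the declared unit is
#'   relative.
#' @param centring `"left"` (i-5..i+4, default) or `"right"` (i-4..i+5).
#' @return A [smoothed_series()] on the grid `ceiling(min t) .. floor(max t)`.
#' @export
preprocess <- function(series, body_mass_kg = NULL,
                       centring = c("left", "right")) {
  centring <- match.arg(centring)
  stopifnot(inherits(series, "breath_series"))
  if (nrow(series) < 10) {
    rlang::abort("At least 10 breath samples are required.")
  }
  span <- diff(range(series$time_s))
  if (span < 60) {
    rlang::abort(sprintf("Series spans %.1f s; at least 60 s are required.", span))
  }
  unit <- attr(series, "unit")
  vo2_l_s <- vo2_to_l_s(series$vo2, unit, body_mass_kg)

  grid <- seq(ceiling(min(series$time_s)), floor(max(series$time_s)), by = 1)
  interp <- stats::approx(series$time_s, vo2_l_s, xout = grid, method = "linear")$y

  offsets <- if (centring == "left") -5:4 else -4:5
  sm <- moving_average(interp, offsets)
  if (any(sm < 0)) {
    rlang::warn(sprintf("%d smoothed values below zero clipped to 0.", sum(sm < 0)))
    sm <- pmax(sm, 0)
  }
  smoothed_series(
    grid, sm,
    source_unit = unit,
    phase_shift_s = if (centring == "left") -0.5 else 0.5
  )
}

biexp_value <- function(t, a, tau_a, b, tau_b, c) {
  a * exp(-t / tau_a) + b * exp(-t / tau_b) + c
}

#' Fit the bi-exponential recovery model
#'
#' Models post-exercise oxygen uptake as
#' \deqn{\dot{V}O_2(t) = a e^{-t/\tau_a} + b e^{-t/\tau_b} + c}
#' where `a`, `b` are the amplitudes of the fast and slow components,
#' `tau_a < tau_b` their time constants, and `c` the baseline oxygen uptake.
#' Time is re-based to 0 at `recovery_start_s` (plus the smoothing phase
#' shift recorded on the series, if any).
#'
#' Estimation is bounded nonlinear least squares (Levenberg-Marquardt via
#' \pkg{minpack.lm}). Starting values: `c0` = mean of the final 120 s of the
#' window; `a0 = 0.7 * (first value - c0)`, `b0 = 0.3 * (first value - c0)`;
#' time-constant starts default to (30, 300) s, clamped into the bounds
#' `tau_a` in \[5, 120\] s and `tau_b` in \[120, 1800\] s; amplitudes and
#' baseline are bounded by \[0, 3 x peak\]. If the first attempt fails, a
#' 5-point multi-start over the time-constant starts is tried. After
#' fitting, components are ordered so that `tau_a < tau_b`.
#'
#' @param series A [smoothed_series()].
#' @param marks [phase_marks()] giving `recovery_start_s` (alternatively a
#'   bare number).
#' @param fit_window_s Length of the fitted recovery window (default 900 s).
#' @param edge_guard_s Grid points closer than this to the recovery start
#'   are excluded from the fit (default 10 s). The centred moving average
#'   and breath interpolation smear pre-transition (work-phase) samples into
#'   the first seconds after the transition; the guard keeps that smear out
#'   of the fast component. Time is still re-based at `recovery_start_s`.
#' @param tau_start Optional length-2 numeric of starting time constants;
#'   order is irrelevant (they are clamped into the fast/slow bounds).
#' @return An object of class `biexp_fit` with elements `a`, `tau_a`, `b`,
#'   `tau_b`, `c`, `rss`, `converged`, `n_points`, `recovery_start_s`, and
#'   the fitted window (`data`).
#' @export
fit_recovery <- function(series, marks, fit_window_s = 900,
                         edge_guard_s = 10, tau_start = c(30, 300)) {
  stopifnot(inherits(series, "smoothed_series"))
  recovery_start_s <- if (inherits(marks, "phase_marks")) {
    marks$recovery_start_s
  } else {
    as.numeric(marks)
  }
  phase <- attr(series, "phase_shift_s") %||% 0

  win <- dplyr::filter(
    series,
    .data$grid_time_s >= recovery_start_s + edge_guard_s,
    .data$grid_time_s <= recovery_start_s + fit_window_s
  )
  if (nrow(win) < 120) {
    rlang::abort(sprintf(
      "Recovery window holds %d grid points; at least 120 are required.", nrow(win)
    ))
  }
  t <- win$grid_time_s - recovery_start_s + phase
  y <- win$vo2_l_s

  peak <- max(y)
  c0 <- mean(y[t >= max(t) - 120])
  amp0 <- max(y[1] - c0, 1e-4)
  lower <- c(a = 0, tau_a = 5, b = 0, tau_b = 120, c = 0)
  upper <- c(a = 3 * peak, tau_a = 120, b = 3 * peak, tau_b = 1800, c = 3 * peak)
  clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)
  tau_start <- sort(tau_start)
  tau_a0 <- clamp(tau_start[1], lower["tau_a"], upper["tau_a"])
  tau_b0 <- clamp(tau_start[2], lower["tau_b"], upper["tau_b"])

  starts <- list(c(tau_a0, tau_b0), c(15, 200), c(30, 300), c(60, 600),
                 c(90, 1200), c(45, 450))
  dat <- data.frame(t = t, y = y)

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        y ~ a * exp(-t / tau_a) + b * exp(-t / tau_b) + c,
        data = dat,
        start = list(a = 0.7 * amp0, tau_a = st[1], b = 0.3 * amp0,
                     tau_b = st[2], c = clamp(c0, 0, 3 * peak)),
        lower = lower, upper = upper,
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss - 1e-14) {
        best <- list(fit = fit, rss = rss)
      }
      if (!is.null(best)) break # first converged start is kept; extras only on failure
    }
  }

  if (is.null(best)) {
    out <- structure(
      list(a = NA_real_, tau_a = NA_real_, b = NA_real_, tau_b = NA_real_,
           c = NA_real_, rss = NA_real_, converged = FALSE,
           n_points = nrow(win), recovery_start_s = recovery_start_s,
           data = win),
      class = "biexp_fit"
    )
    rlang::warn("Bi-exponential recovery fit did not converge; result is flagged.")
    return(out)
  }

  est <- stats::coef(best$fit)
  # enforce fast/slow ordering
  if (est["tau_a"] > est["tau_b"]) {
    est[c("a", "tau_a", "b", "tau_b")] <- est[c("b", "tau_b", "a", "tau_a")]
  }
  structure(
    list(
      a = unname(est["a"]), tau_a = unname(est["tau_a"]),
      b = unname(est["b"]), tau_b = unname(est["tau_b"]),
      c = unname(est["c"]),
      rss = best$rss, converged = TRUE, n_points = nrow(win),
      recovery_start_s = recovery_start_s, data = win
    ),
    class = "biexp_fit"
  )
}

#' @export
print.biexp_fit <- function(x, ...) {
  if (!x$converged) {
    cat("<biexp_fit> NOT CONVERGED (flagged)\n")
    return(invisible(x))
  }
  cat(sprintf(
    "<biexp_fit> a = %.4f L/s (tau_a = %.1f s), b = %.4f L/s (tau_b = %.1f s), c = %.4f L/s\n",
    x$a, x$tau_a, x$b, x$tau_b, x$c
  ))
  cat(sprintf("  rss = %.3g (L/s)^2 over %d points from t = %g s\n",
              x$rss, x$n_points, x$recovery_start_s))
  invisible(x)
}

#' Tidy a bi-exponential recovery fit
#'
#' @param x A `biexp_fit`.
#' @param ... Unused.
#' @return `tidy()`: a tibble with one row per parameter. `glance()`: a
#'   one-row tibble of fit diagnostics.
#' @export
tidy.biexp_fit <- function(x, ...) {
  tibble::tibble(
    term = c("a", "tau_a", "b", "tau_b", "c"),
    estimate = c(x$a, x$tau_a, x$b, x$tau_b, x$c),
    unit = c("L/s", "s", "L/s", "s", "L/s"),
    component = c("fast", "fast", "slow", "slow", "baseline")
  )
}

#' @rdname tidy.biexp_fit
#' @export
glance.biexp_fit <- function(x, ...) {
  tibble::tibble(
    rss = x$rss, converged = x$converged, n_points = x$n_points,
    recovery_start_s = x$recovery_start_s
  )
}

#' Predicted recovery curve from a fit
#'
#' @param object A `biexp_fit`.
#' @param t Seconds since recovery start.
#' @param component `"full"`, `"fast"` (fast component plus baseline) or
#'   `"baseline"`.
#' @param ... Unused.
#' @return Numeric vector, L/s.
#' @export
predict.biexp_fit <- function(object, t, component = c("full", "fast", "baseline"),
                              ...) {
  component <- match.arg(component)
  switch(component,
    full = biexp_value(t, object$a, object$tau_a, object$b, object$tau_b, object$c),
    fast = object$a * exp(-t / object$tau_a) + object$c,
    baseline = rep(object$c, length(t))
  )
}
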