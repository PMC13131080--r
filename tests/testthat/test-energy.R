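test_that("the component integral matches its closed form and limits", {
  expect_equal(component_integral(0, 35, 30), 0)
  expect_equal(component_integral(0, 500, 1e6), 0)
  expect_equal(component_integral(0.030, 35, 30), 0.6044, tolerance = 1e-4)
  # infinite-duration limit is amplitude * tau
  expect_equal(component_integral(0.030, 35, 1e9), 0.030 * 35)
  expect_error(component_integral(0.03, -1, 30), "tau")
  expect_error(component_integral(0.03, 35, -5), "duration")
})

test_that("the component integral agrees with a fine trapezoidal oracle", {
  set.seed(42)
  for (i in 1:100) {
    amp <- runif(1, 0.001, 0.1)
    tau <- runif(1, 5, 600)
    dur <- runif(1, 1, 900)
    closed <- component_integral(amp, tau, dur)
    expect_lt(abs(closed - trapz_component(amp, tau, dur)) / closed, 1e-6)
  }
})

test_that("aerobic energy integrates baseline-adjusted uptake over work only", {
  c0 <- 0.05
  series <- smoothed_series(0:1200, rep(c0, 1201))
  tl <- flat_session_timeline(100)
  # uptake identically at baseline -> zero aerobic energy
  expect_equal(aerobic_energy(series, tl, c0), 0)

  elevated <- smoothed_series(0:1200, rep(c0 + 0.02, 1201))
  # one 100 s work segment at +0.02 L/s -> 2 L -> 41.84 kJ
  expect_equal(aerobic_energy(elevated, tl, c0), 41.84, tolerance = 1e-9)

  # a 30 s rest inside a 100 s exercise phase removes its share: 1.4 L
  tl_rest <- flat_session_timeline(c(35, 35), intra_rest_s = 30)
  expect_equal(aerobic_energy(elevated, tl_rest, c0), 1.4 * 20.92,
               tolerance = 1e-9)

  # work outside the measured span is a hard error
  short <- smoothed_series(0:150, rep(c0 + 0.02, 151))
  expect_error(aerobic_energy(short, tl, c0), "outside the measured span")
})

test_that("alactic energy sums the fast component over every rest window", {
  fit <- structure(
    list(a = 0.030, tau_a = 35, b = 0.010, tau_b = 300, c = 0.09,
         rss = 0, converged = TRUE, n_points = 900, recovery_start_s = 0),
    class = "biexp_fit"
  )
  ts_tl <- build_timeline(protocol_spec("TS"))
  # windows 900 + 3 x 180 s: ~4.1816 L -> 87.48 kJ
  expect_equal(alactic_energy(fit, ts_tl), 87.48, tolerance = 0.01)

  cs_tl <- build_timeline(protocol_spec("CS"))
  extra <- 8 * component_integral(0.030, 35, 30) * 20.92
  expect_equal(alactic_energy(fit, cs_tl) - alactic_energy(fit, ts_tl), extra,
               tolerance = 1e-9)

  zero <- fit
  zero$a <- 0
  expect_equal(alactic_energy(zero, cs_tl), 0)

  flagged <- fit
  flagged$converged <- FALSE
  expect_error(alactic_energy(flagged, ts_tl), "flagged")
  expect_no_error(alactic_energy(flagged, ts_tl, force = TRUE))
})

test_that("lactic energy converts the baseline-to-peak rise", {
  who <- participant_info("P1", 75)
  # 2.0 mmol/L rise at 75 kg: 450 mL O2 -> 9.414 kJ
  panel <- lactate_panel(1.0, c("60" = 2.6, "180" = 3.0, "300" = 2.8))
  expect_equal(lactic_energy(panel, who), 9.414, tolerance = 1e-9)

  # peak is the max across post samples
  panel2 <- lactate_panel(1.2, c("60" = 1.9, "180" = 3.1, "300" = 2.8))
  expect_equal(lactic_energy(panel2, who), 1.9 * 3 * 75 / 1000 * 20.92)

  expect_equal(lactic_energy(lactate_panel(2.0, c("60" = 2.0)), who), 0)

  # negative rise floors at zero with a warning by default, or passes through
  drop <- lactate_panel(3.0, c("60" = 2.0))
  expect_warning(e <- lactic_energy(drop, who), "floored")
  expect_equal(e, 0)
  expect_equal(lactic_energy(drop, who, negative_policy = "allow"),
               -1 * 3 * 75 / 1000 * 20.92)
})

test_that("relative shares are a partition of 100 percent", {
  ec <- energy_components(10, 10, 10)
  expect_equal(unname(unlist(ec[1, c("rel_aerobic_pct", "rel_alactic_pct",
                                     "rel_lactic_pct")])),
               rep(100 / 3, 3))
  set.seed(7)
  for (i in 1:50) {
    ec <- energy_components(runif(1, 0, 100), runif(1, 1e-6, 100),
                            runif(1, 0, 100))
    expect_equal(ec$rel_aerobic_pct + ec$rel_alactic_pct + ec$rel_lactic_pct,
                 100, tolerance = 1e-9)
    expect_true(all(ec[1, 1:3] >= 0))
  }
  expect_error(energy_components(0, 0, 0), "positive")
})

test_that("the lactic component is strictly monotone in the lactate rise", {
  who <- participant_info("P1", 70)
  aer <- 30
  ala <- 60
  deltas <- seq(0.5, 4, by = 0.5)
  lac <- vapply(deltas, function(d) {
    lactic_energy(lactate_panel(1.0, c("180" = 1.0 + d)), who)
  }, numeric(1))
  expect_true(all(diff(lac) > 0))
  shares <- vapply(lac, function(l) energy_components(aer, ala, l)$rel_lactic_pct,
                   numeric(1))
  expect_true(all(diff(shares) > 0))
})

test_that("modelled rest attribution subtracts fit components instead", {
  c0 <- 0.05
  elevated <- smoothed_series(0:1200, rep(c0 + 0.02, 1201))
  tl_rest <- flat_session_timeline(c(35, 35), intra_rest_s = 30)
  fit <- structure(
    list(a = 0.010, tau_a = 35, b = 0.002, tau_b = 300, c = c0,
         rss = 0, converged = TRUE, n_points = 900, recovery_start_s = 0),
    class = "biexp_fit"
  )
  # exercise phase 100 s at +0.02 minus the modelled fast component of the
  # single 30 s intra-set rest
  expected <- (0.02 * 100 - component_integral(0.010, 35, 30)) * 20.92
  got <- aerobic_energy(elevated, tl_rest, c0, rest_attribution = "modelled",
                        fit = fit)
  expect_equal(got, expected, tolerance = 1e-9)
  expect_error(
    aerobic_energy(elevated, tl_rest, c0, rest_attribution = "modelled"),
    "unflagged"
  )
})
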