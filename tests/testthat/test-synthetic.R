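test_that("sessions are bit-identical under the same seed", {
  cfg <- synthetic_config(seed = 123)
  s1 <- generate_session(cfg, protocol_spec("CS"))
  s2 <- generate_session(cfg, protocol_spec("CS"))
  expect_identical(s1$breath$vo2, s2$breath$vo2)
  expect_identical(s1$reps$mpv_m_s, s2$reps$mpv_m_s)
  expect_identical(s1$lactate$post_mmol_l, s2$lactate$post_mmol_l)
  s3 <- generate_session(synthetic_config(seed = 124), protocol_spec("CS"))
  expect_false(identical(s1$breath$vo2, s3$breath$vo2))
})

test_that("the noiseless recovery tail equals the truth bi-exponential", {
  cfg <- noiseless_config(seed = 5)
  s <- generate_session(cfg, protocol_spec("TS"))
  k <- attr(s$truth, "kinetics")
  rec <- s$marks$recovery_start_s
  tail_idx <- s$breath$time_s >= rec
  t <- s$breath$time_s[tail_idx] - rec
  vo2_l_s <- vo2_to_l_s(s$breath$vo2[tail_idx], attr(s$breath, "unit"))
  truth_curve <- k$a * exp(-t / k$tau_a) + k$b * exp(-t / k$tau_b) + k$c
  expect_equal(vo2_l_s, truth_curve, tolerance = 1e-12)
})

test_that("the generated streams are structurally consistent with the timeline", {
  cfg <- synthetic_config(seed = 9)
  spec <- protocol_spec("CS")
  s <- generate_session(cfg, spec)
  expect_equal(nrow(s$reps), spec$n_sets * spec$reps_per_set)
  expect_equal(max(s$breath$time_s) <= max(s$timeline$end_s) +
                 2 * cfg$breath_interval_s, TRUE)
  expect_equal(s$marks$recovery_start_s,
               s$timeline$start_s[s$timeline$kind == "final_recovery"])
  expect_equal(s$truth$rel_aerobic_pct + s$truth$rel_alactic_pct +
                 s$truth$rel_lactic_pct, 100, tolerance = 1e-9)
})

test_that("cluster sessions lose less velocity and less lactate than traditional", {
  cfg <- synthetic_config(seed = 77)
  cs <- generate_session(cfg, protocol_spec("CS"))
  ts <- generate_session(cfg, protocol_spec("TS"))
  vl_cs <- session_velocity_loss(cs$reps)$session_vl_pct
  vl_ts <- session_velocity_loss(ts$reps)$session_vl_pct
  expect_lt(vl_cs, vl_ts)
  rise <- function(s) max(s$lactate$post_mmol_l) - s$lactate$baseline_mmol_l
  expect_lt(rise(cs), rise(ts))
})

test_that("the truth ledger responds to its drivers", {
  spec <- protocol_spec("CS")
  base <- noiseless_config(seed = 1)
  # no lactate accumulation -> zero lactic share
  no_lact <- noiseless_config(seed = 1, lactate_per_rep_mmol_l = 0)
  expect_equal(truth_energy(no_lact, spec)$rel_lactic_pct, 0)
  # doubling the work demand raises the aerobic share
  hot <- noiseless_config(seed = 1, work_demand_l_s = 2 * base$work_demand_l_s)
  expect_gt(truth_energy(hot, spec)$rel_aerobic_pct,
            truth_energy(base, spec)$rel_aerobic_pct)
})

test_that("configurations violating kinetic ordering or positivity fail", {
  expect_error(synthetic_config(tau_a = 300, tau_b = 200), "tau_a")
  expect_error(synthetic_config(work_demand_l_s = -0.01), "positive")
  expect_error(synthetic_config(baseline_vo2_l_s = 0), "positive")
})

test_that("cohorts pair every participant across both protocols", {
  cohort <- generate_cohort(n_participants = 3, seed = 42)
  expect_equal(nrow(cohort), 6)
  expect_equal(unname(table(cohort$protocol)), c(3L, 3L), ignore_attr = TRUE)
  counts <- table(cohort$participant)
  expect_true(all(counts == 2))
  # reproducible under the master seed
  cohort2 <- generate_cohort(n_participants = 3, seed = 42)
  expect_identical(cohort$session[[1]]$breath$vo2,
                   cohort2$session[[1]]$breath$vo2)
})
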