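test_that("preprocessing converts, regrids and preserves constants", {
  # constant 3 L/min over 600 s -> constant 0.05 L/s
  tt <- seq(0, 600, length.out = 208)
  bs <- breath_series(tt, rep(3, length(tt)), unit = "l_min")
  sm <- preprocess(bs)
  expect_s3_class(sm, "smoothed_series")
  expect_true(all(abs(sm$vo2_l_s - 0.05) < 1e-12))
  expect_equal(sm$grid_time_s, seq(0, 600))

  # irregular breath times still land on the integer-second grid
  set.seed(3)
  t <- cumsum(c(0, runif(80, 2, 4)))
  bs2 <- breath_series(t, rep(3000, length(t)), unit = "ml_min")
  sm2 <- preprocess(bs2)
  expect_equal(sm2$grid_time_s, seq(ceiling(min(t)), floor(max(t))))
})

test_that("an impulse spreads over exactly ten grid points", {
  vo2 <- rep(0, 100)
  vo2[51] <- 6 # L/min at t = 50 -> 0.1 L/s
  bs <- breath_series(0:99, vo2, unit = "l_min")
  sm <- preprocess(bs)
  hit <- which(sm$vo2_l_s > 0)
  expect_length(hit, 10)
  expect_true(all(abs(sm$vo2_l_s[hit] - 0.01) < 1e-12))
  # left-centred window i-5..i+4: impulse at index k feeds outputs k-4..k+5
  expect_equal(range(sm$grid_time_s[hit]), c(46, 55))
})

test_that("smoothing is mass-preserving on interior windows", {
  # linear input: the moving average reproduces it away from the edges
  t <- seq(0, 300)
  bs <- breath_series(t, 2 + 0.001 * t, unit = "l_min")
  sm <- preprocess(bs)
  interior <- sm$grid_time_s >= 10 & sm$grid_time_s <= 290
  truth <- (2 + 0.001 * (sm$grid_time_s + (-0.5))) / 60 # half-sample delay
  expect_true(max(abs(sm$vo2_l_s[interior] - truth[interior])) < 1e-9)
})

test_that("preprocessing rejects short or sparse series", {
  expect_error(preprocess(breath_series(0:8, rep(3, 9), unit = "l_min")),
               "10 breath samples")
  expect_error(preprocess(breath_series(seq(0, 50, length.out = 20),
                                        rep(3, 20), unit = "l_min")),
               "60 s")
})

test_that("noiseless model data is recovered to machine precision", {
  truth <- list(a = 0.030, tau_a = 35, b = 0.010, tau_b = 300, c = 0.090)
  fit <- fit_recovery(make_biexp_series(truth), 0)
  expect_true(fit$converged)
  for (p in names(truth)) {
    expect_lt(abs(fit[[p]] - truth[[p]]) / truth[[p]], 1e-6)
  }
  expect_lt(fit$rss, 1e-10)
})

test_that("component ordering is invariant to swapped starting constants", {
  truth <- list(a = 0.030, tau_a = 35, b = 0.010, tau_b = 300, c = 0.090)
  series <- make_biexp_series(truth)
  f1 <- fit_recovery(series, 0, tau_start = c(30, 300))
  f2 <- fit_recovery(series, 0, tau_start = c(300, 30))
  expect_lt(f1$tau_a, f1$tau_b)
  expect_equal(
    unlist(f1[c("a", "tau_a", "b", "tau_b", "c")]),
    unlist(f2[c("a", "tau_a", "b", "tau_b", "c")]),
    tolerance = 1e-8
  )
})

test_that("fits respect their parameter bounds under noise", {
  truth <- list(a = 0.030, tau_a = 35, b = 0.010, tau_b = 300, c = 0.090)
  for (seed in 1:5) {
    fit <- fit_recovery(make_biexp_series(truth, noise_sd = 0.005, seed = seed), 0)
    expect_true(fit$converged)
    expect_gte(fit$tau_a, 5)
    expect_lte(fit$tau_a, 120)
    expect_gte(fit$tau_b, 120)
    expect_lte(fit$tau_b, 1800)
    expect_true(all(c(fit$a, fit$b, fit$c) >= 0))
  }
})

test_that("too-short recovery windows are rejected", {
  truth <- list(a = 0.030, tau_a = 35, b = 0.010, tau_b = 300, c = 0.090)
  expect_error(fit_recovery(make_biexp_series(truth, t = 0:100), 0),
               "at least 120")
})

test_that("tidy, glance and predict expose the fitted model", {
  truth <- list(a = 0.030, tau_a = 35, b = 0.010, tau_b = 300, c = 0.090)
  fit <- fit_recovery(make_biexp_series(truth), 0)
  td <- tidy(fit)
  expect_equal(td$term, c("a", "tau_a", "b", "tau_b", "c"))
  expect_equal(glance(fit)$n_points, fit$n_points)
  expect_equal(predict(fit, 0, "full"), fit$a + fit$b + fit$c)
  expect_equal(predict(fit, 1e9, "fast"), fit$c)
  p <- ggplot2::autoplot(fit)
  expect_s3_class(p, "ggplot")
})
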