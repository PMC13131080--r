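test_that("paired t equals the one-sample t on differences", {
  set.seed(21)
  for (i in 1:10) {
    d <- rnorm(6, mean = runif(1, -5, 5), sd = runif(1, 0.5, 3))
    ours <- paired_t(d)
    ref <- t.test(d)
    expect_equal(ours$t, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value)
    expect_equal(ours$df, unname(ref$parameter))
  }
})

test_that("six differences with mean -11 and sd 5.77 give the expected t and g", {
  p <- c(-2, -1, 0, 0, 1, 2)
  d <- -11 + sqrt(100 / 3) * (p - mean(p)) / sd(p)
  expect_equal(mean(d), -11)
  expect_equal(sd(d), sqrt(100 / 3)) # 5.7735
  res <- paired_t(d)
  expect_equal(res$t, -4.6669, tolerance = 1e-4)
  expect_equal(res$hedges_g, -1.6044, tolerance = 1e-4)
  # the correction factor for df = 5 is 1 - 3/19
  expect_equal(res$hedges_g, mean(d) / sd(d) * (1 - 3 / 19))
})

test_that("t is zero for antisymmetric differences and signed like the shift", {
  expect_equal(paired_t(c(-2, -1, 1, 2, -3, 3))$t, 0)
  set.seed(8)
  jitter <- rnorm(6, sd = 0.01)
  expect_gt(paired_t(3 + jitter)$t, 0)
  expect_lt(paired_t(-3 + jitter)$t, 0)
  expect_error(paired_t(rep(1, 6)), "Zero variance")
})

test_that("hedges g is scale-free and needs variation", {
  d <- c(-5, -9, -11, -13, -15, -13)
  expect_equal(hedges_g_paired(2.5 * d), hedges_g_paired(d))
  expect_error(hedges_g_paired(rep(2, 5)), "Zero variance")
})

test_that("exact Wilcoxon enumeration reproduces small-sample tail probabilities", {
  # n = 6, all one sign: p = 2/64
  expect_equal(wilcoxon_signed_rank(c(1.2, 0.8, 2.0, 1.4, 0.6, 3.1))$p, 0.03125)
  expect_equal(wilcoxon_signed_rank(-c(1.2, 0.8, 2.0, 1.4, 0.6, 3.1))$p, 0.03125)
  # flipping one sign can only weaken the evidence
  expect_gt(wilcoxon_signed_rank(c(-1.2, 0.8, 2.0, 1.4, 0.6, 3.1))$p, 0.03125)
  # n = 2: the smallest attainable two-sided p is 0.5
  expect_equal(wilcoxon_signed_rank(c(0.5, 1.5))$p, 0.5)
})

test_that("exact enumeration agrees with the reference routine and its approximation", {
  set.seed(13)
  for (i in 1:5) {
    d <- rnorm(10) + 0.8
    d <- d[d != 0]
    ours <- wilcoxon_signed_rank(d)
    ref <- wilcox.test(d, exact = TRUE)
    expect_true(ours$exact)
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_equal(ours$p, ref$p.value)
  }
  # large-sample agreement at n = 12 within 0.005
  set.seed(14)
  d12 <- rnorm(12) + 0.5
  exact_p <- wilcoxon_signed_rank(d12)$p
  approx_p <- wilcox.test(d12, exact = FALSE, correct = TRUE)$p.value
  expect_lt(abs(exact_p - approx_p), 0.005)
})

test_that("zero differences are dropped with a warning", {
  expect_warning(res <- wilcoxon_signed_rank(c(0, 1, 2, 3, 4, 5)), "dropped")
  expect_equal(res$n, 5)
  expect_error(suppressWarnings(wilcoxon_signed_rank(c(0, 0))), "non-zero")
})

test_that("shapiro-wilk wrapper flags skewness and rejects tiny samples", {
  res <- shapiro_wilk(c(1.01, 0.99, 1.02, 0.98, 1.00))
  expect_true(res$W > 0 && res$W <= 1)
  expect_error(shapiro_wilk(c(1, 2)), "sample size")
  set.seed(31)
  w_skew <- median(replicate(20, shapiro_wilk(rexp(6))$W))
  w_norm <- median(replicate(20, shapiro_wilk(rnorm(6))$W))
  expect_lt(w_skew, w_norm)
})

test_that("the energy mixed model detects a null interaction as null", {
  profiles <- c(aerobic = 40, alactic = 50, lactic = 10)
  base <- tidyr::expand_grid(
    participant = sprintf("P%d", 1:6),
    protocol = c("CS", "TS"),
    system = names(profiles)
  )
  set.seed(17)
  offsets <- stats::setNames(rnorm(6, sd = 2), sprintf("P%d", 1:6))
  base$rel_pct <- profiles[base$system] + offsets[base$participant] +
    rnorm(nrow(base), sd = 0.8)
  res <- fit_energy_lmm(base)
  inter <- res$anova[res$anova$term == "system:protocol", ]
  expect_gt(inter$p, 0.2)
  expect_true(all(res$contrasts$p_holm > 0.2))
})

test_that("the mixed model reports Satterthwaite dfs and Holm-ordered contrasts", {
  base <- tidyr::expand_grid(
    participant = sprintf("P%d", 1:6),
    protocol = c("CS", "TS"),
    system = c("aerobic", "alactic", "lactic")
  )
  set.seed(18)
  shift <- with(base, ifelse(system == "alactic" & protocol == "CS", 15,
                             ifelse(system == "aerobic" & protocol == "CS", -10, -5)))
  base$rel_pct <- 33 + shift + rnorm(nrow(base), sd = 3)
  res <- fit_energy_lmm(base)
  inter <- res$anova[res$anova$term == "system:protocol", ]
  # balanced 6 x 2 x 3 crossover: interaction df are (2, 30)
  expect_equal(inter$num_df, 2)
  expect_equal(inter$den_df, 30, tolerance = 1e-6)
  expect_gt(inter$f, 10)
  # Holm: adjusted never below raw, monotone in the raw order
  ord <- order(res$contrasts$p_raw)
  expect_true(all(res$contrasts$p_holm >= res$contrasts$p_raw - 1e-12))
  expect_true(all(diff(res$contrasts$p_holm[ord]) >= -1e-12))
  # the alactic contrast carries the strongest signal by construction
  expect_equal(res$contrasts$system[which.min(res$contrasts$p_holm)], "alactic")
})

test_that("incomplete designs are rejected with the missing cells named", {
  base <- tidyr::expand_grid(
    participant = sprintf("P%d", 1:4),
    protocol = c("CS", "TS"),
    system = c("aerobic", "alactic", "lactic")
  )
  base$rel_pct <- 33
  broken <- base[-1, ]
  expect_error(fit_energy_lmm(broken), "missing cells")
  expect_error(fit_energy_lmm(base[base$participant %in% c("P1", "P2"), ]),
               "3 participants")
})

test_that("paired differences align by participant and flag unpaired rows", {
  df <- tibble::tibble(
    participant = rep(c("A", "B", "C"), each = 2),
    protocol = factor(rep(c("CS", "TS"), 3), levels = c("CS", "TS")),
    value = c(10, 12, 8, 11, 9, 14)
  )
  d <- paired_differences(df, value, protocol, participant)
  expect_equal(unname(d), c(-2, -3, -5))
  expect_error(
    paired_differences(df[-1, ], value, protocol, participant),
    "Unpaired participants: A"
  )
})
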