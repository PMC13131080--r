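# Small-sample crossover inference: paired t with Hedges' g, exact Wilcoxon
# signed-rank by sign enumeration, Shapiro-Wilk, and the mixed model on
# relative energy contributions.

#' Paired differences from a long data frame
#'
#' Aligns the two conditions by participant and returns the per-participant
#' differences `first level - second level` (factor order of `condition`,
#' or alphabetical for character input).
#'
#' @param data Data frame with one row per participant x condition.
#' @param value,condition,id Unquoted column names.
#' @return Named numeric vector of differences.
#' @export
paired_differences <- function(data, value, condition, id) {
  wide <- data |>
    dplyr::select({{ id }}, {{ condition }}, {{ value }}) |>
    tidyr::pivot_wider(names_from = {{ condition }}, values_from = {{ value }})
  cond <- dplyr::pull(data, {{ condition }})
  levs <- if (is.factor(cond)) levels(cond) else sort(unique(as.character(cond)))
  if (length(levs) != 2) {
    rlang::abort("`condition` must have exactly two levels.")
  }
  if (anyNA(wide[levs])) {
    missing_ids <- dplyr::pull(wide, {{ id }})[!stats::complete.cases(wide[levs])]
    rlang::abort(paste0("Unpaired participants: ",
                        paste(missing_ids, collapse = ", ")))
  }
  stats::setNames(wide[[levs[1]]] - wide[[levs[2]]],
                  as.character(dplyr::pull(wide, {{ id }})))
}

hedges_correction <- function(df) 1 - 3 / (4 * df - 1)

#' Hedges' g for paired data
#'
#' Standardised mean difference of the difference scores with the
#' small-sample correction `1 - 3 / (4 * df - 1)` where `df = n - 1`:
#' `g = mean(d) / sd(d) * (1 - 3 / (4 * (n - 1) - 1))`.
#'
#' @param diffs Numeric vector of paired differences.
#' @return Hedges' g (scalar).
#' @export
#' @examples
#' hedges_g_paired(c(-5, -9, -11, -13, -15, -13))
hedges_g_paired <- function(diffs) {
  n <- length(diffs)
  if (n < 2) rlang::abort("At least 2 pairs are required.")
  s <- sd(diffs)
  if (s == 0) rlang::abort("Zero variance of differences; g is undefined.")
  mean(diffs) / s * hedges_correction(n - 1)
}

#' Student's paired t-test with Hedges' g
#'
#' `t = mean(d) / (sd(d) / sqrt(n))` with `df = n - 1` and a two-sided p;
#' equivalent to the one-sample t on the differences. Hedges' g uses the
#' difference-score standardisation of [hedges_g_paired()].
#'
#' @param diffs Numeric vector of paired differences, or a data frame (then
#'   give `value`, `condition`, `id`).
#' @param value,condition,id Unquoted columns when `diffs` is a data frame.
#' @return One-row tibble: `t`, `df`, `p`, `hedges_g`, `n`, `mean_diff`,
#'   `sd_diff`.
#' @export
#' @examples
#' paired_t(c(-5, -9, -11, -13, -15, -13))
paired_t <- function(diffs, value, condition, id) {
  if (is.data.frame(diffs)) {
    diffs <- paired_differences(diffs, {{ value }}, {{ condition }}, {{ id }})
  }
  n <- length(diffs)
  if (n < 2) rlang::abort("At least 2 pairs are required.")
  if (any(!is.finite(diffs))) rlang::abort("Differences must be finite.")
  s <- sd(diffs)
  if (s == 0) rlang::abort("Zero variance of differences; t is undefined.")
  tval <- mean(diffs) / (s / sqrt(n))
  df <- n - 1
  tibble::tibble(
    t = tval, df = df, p = 2 * pt(-abs(tval), df),
    hedges_g = hedges_g_paired(diffs),
    n = n, mean_diff = mean(diffs), sd_diff = s
  )
}

# Exact null distribution of the positive-rank sum by enumerating all 2^n
# sign assignments (handles midranks from tied |d| exactly).
wilcoxon_exact_p <- function(ranks, w_obs) {
  n <- length(ranks)
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% ranks)
  eps <- 1e-9
  p_le <- mean(w_all <= w_obs + eps)
  p_ge <- mean(w_all >= w_obs - eps)
  min(1, 2 * min(p_le, p_ge))
}

#' Wilcoxon signed-rank test with an exact small-sample p-value
#'
#' For `n <= 12` pairs the two-sided p-value is exact, obtained by
#' enumerating all `2^n` sign assignments of the ranked absolute differences
#' (ties handled by midranks, so the enumeration remains exact). For larger
#' n a normal approximation with continuity correction is used. Zero
#' differences are dropped with a warning and n adjusted.
#'
#' @inheritParams paired_t
#' @return One-row tibble: `statistic` (positive-rank sum V), `p`, `n`,
#'   `exact` (logical).
#' @export
#' @examples
#' wilcoxon_signed_rank(c(1.2, 0.8, 2.0, 1.4, 0.6, 3.1)) # p = 0.03125
wilcoxon_signed_rank <- function(diffs, value, condition, id) {
  if (is.data.frame(diffs)) {
    diffs <- paired_differences(diffs, {{ value }}, {{ condition }}, {{ id }})
  }
  if (any(diffs == 0)) {
    rlang::warn(sprintf("%d zero difference(s) dropped.", sum(diffs == 0)))
    diffs <- diffs[diffs != 0]
  }
  n <- length(diffs)
  if (n < 2) rlang::abort("At least 2 non-zero differences are required.")
  ranks <- rank(abs(diffs))
  w_obs <- sum(ranks[diffs > 0])
  if (n <= 12) {
    p <- wilcoxon_exact_p(ranks, w_obs)
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    sigma <- sqrt(n * (n + 1) * (2 * n + 1) / 24)
    z <- (w_obs - mu - sign(w_obs - mu) * 0.5) / sigma
    p <- min(1, 2 * stats::pnorm(-abs(z)))
    exact <- FALSE
  }
  tibble::tibble(statistic = w_obs, p = p, n = n, exact = exact)
}

#' Shapiro-Wilk normality test
#'
#' Thin wrapper around [stats::shapiro.test()] returning a tidy row; used to
#' decide between the paired t-test and the Wilcoxon signed-rank test.
#'
#' @param x Numeric vector (3 to 5000 values).
#' @return One-row tibble: `W`, `p`.
#' @export
shapiro_wilk <- function(x) {
  res <- stats::shapiro.test(x)
  tibble::tibble(W = unname(res$statistic), p = res$p.value)
}

#' Mixed model on relative energy contributions
#'
#' Fits `rel_pct ~ system * protocol + (1 | participant)` on the long energy
#' table, reports the type-III ANOVA with Satterthwaite degrees of freedom
#' for the system x protocol interaction, and the three protocol contrasts
#' (one per energy system) from estimated marginal means with a Holm
#' correction applied across the three.
#'
#' @param table Long data frame with columns `participant`, `protocol`
#'   (two levels), `system` (`aerobic`, `alactic`, `lactic`) and `rel_pct`.
#' @return An object of class `energy_lmm`: `model` (the `lmerModLmerTest`
#'   fit), `anova` (tidy type-III table), `contrasts` (tidy EMM contrasts
#'   with raw and Holm-adjusted p-values).
#' @export
fit_energy_lmm <- function(table) {
  needed <- c("participant", "protocol", "system", "rel_pct")
  missing <- setdiff(needed, names(table))
  if (length(missing) > 0) {
    rlang::abort(paste0("Long energy table lacks columns: ",
                        paste(missing, collapse = ", ")))
  }
  grid <- table |>
    dplyr::count(.data$participant, .data$protocol, .data$system)
  full <- tidyr::expand_grid(
    participant = unique(table$participant),
    protocol = unique(table$protocol),
    system = unique(table$system)
  )
  absent <- dplyr::anti_join(full, grid,
                             by = c("participant", "protocol", "system"))
  if (nrow(absent) > 0) {
    rlang::abort(paste0(
      "Incomplete design; missing cells: ",
      paste(sprintf("%s/%s/%s", absent$participant, absent$protocol,
                    absent$system), collapse = "; ")
    ))
  }
  if (dplyr::n_distinct(table$participant) < 3) {
    rlang::abort("At least 3 participants are required.")
  }
  dat <- table |>
    dplyr::mutate(
      participant = factor(.data$participant),
      protocol = factor(.data$protocol),
      system = factor(.data$system)
    )
  model <- lmerTest::lmer(rel_pct ~ system * protocol + (1 | participant),
                          data = dat)
  aov3 <- stats::anova(model, type = 3, ddf = "Satterthwaite")
  anova_tbl <- tibble::tibble(
    term = rownames(aov3),
    f = aov3$`F value`,
    num_df = aov3$NumDF,
    den_df = aov3$DenDF,
    p = aov3$`Pr(>F)`
  )
  emm <- emmeans::emmeans(model, ~ protocol | system,
                          lmer.df = "satterthwaite")
  raw <- summary(emmeans::contrast(emm, method = "revpairwise"),
                 by = NULL, adjust = "none")
  holm <- summary(emmeans::contrast(emm, method = "revpairwise"),
                  by = NULL, adjust = "holm")
  contrasts_tbl <- tibble::tibble(
    system = as.character(raw$system),
    contrast = as.character(raw$contrast),
    estimate = raw$estimate,
    se = raw$SE,
    df = raw$df,
    t = raw$t.ratio,
    p_raw = raw$p.value,
    p_holm = holm$p.value
  )
  structure(
    list(model = model, anova = anova_tbl, contrasts = contrasts_tbl),
    class = "energy_lmm"
  )
}

#' @export
print.energy_lmm <- function(x, ...) {
  cat("<energy_lmm> rel_pct ~ system * protocol + (1 | participant)\n")
  cat("Type III ANOVA (Satterthwaite):\n")
  print(as.data.frame(x$anova), digits = 4)
  cat("Protocol contrasts per system (Holm-adjusted):\n")
  print(as.data.frame(x$contrasts), digits = 4)
  invisible(x)
}

#' @export
tidy.energy_lmm <- function(x, ...) x$contrasts

#' @export
glance.energy_lmm <- function(x, ...) {
  inter <- x$anova[x$anova$term == "system:protocol", ]
  tibble::tibble(
    interaction_f = inter$f,
    interaction_num_df = inter$num_df,
    interaction_den_df = inter$den_df,
    interaction_p = inter$p
  )
}
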