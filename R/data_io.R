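# Readers for the three measurement streams and the session annotations.
# Parsing and unit bookkeeping only; no physiology happens here.

vo2_units <- c("l_min", "ml_min", "ml_kg_min")

normalise_vo2_unit <- function(unit) {
  key <- gsub("[^a-z]+", "_", tolower(trimws(unit)))
  key <- gsub("^_|_$", "", key)
  key <- switch(key,
    "l_min" = , "l_per_min" = "l_min",
    "ml_min" = , "ml_per_min" = "ml_min",
    "ml_kg_min" = , "ml_per_kg_per_min" = "ml_kg_min",
    key
  )
  if (!key %in% vo2_units) {
    rlang::abort(sprintf(
      "Unknown VO2 unit '%s'. Use one of: %s.", unit,
      paste(vo2_units, collapse = ", ")
    ))
  }
  key
}

#' Construct a breath-by-breath series
#'
#' A breath series holds raw, irregularly spaced oxygen-uptake samples on the
#' session clock together with their declared unit. Timestamps must be
#' strictly increasing and values non-negative.
#'
#' @param time_s Numeric vector of sample times, seconds on the session clock.
#' @param vo2 Oxygen uptake at each breath, in `unit`.
#' @param unit Declared unit: `"l_min"`, `"ml_min"` or `"ml_kg_min"`
#'   (common spellings such as `"L/min"` are normalised).
#' @param participant_id Optional identifier carried through reports.
#' @return A tibble of class `breath_series` with columns `time_s`, `vo2`.
#' @export
breath_series <- function(time_s, vo2, unit, participant_id = NA_character_) {
  unit <- normalise_vo2_unit(unit)
  if (length(time_s) != length(vo2)) {
    rlang::abort("`time_s` and `vo2` must have equal length.")
  }
  bad <- which(diff(time_s) <= 0)
  if (length(bad) > 0) {
    rlang::abort(sprintf(
      "Breath timestamps must be strictly increasing; violation at row %d (t = %g followed by t = %g).",
      bad[1] + 1L, time_s[bad[1]], time_s[bad[1] + 1L]
    ))
  }
  if (any(vo2 < 0)) {
    rlang::abort(sprintf("Negative VO2 at row %d.", which(vo2 < 0)[1]))
  }
  out <- tibble::tibble(time_s = as.numeric(time_s), vo2 = as.numeric(vo2))
  class(out) <- c("breath_series", class(out))
  attr(out, "unit") <- unit
  attr(out, "participant_id") <- participant_id
  out
}

#' @export
print.breath_series <- function(x, ...) {
  cat(sprintf("<breath_series> %d breaths over %.1f s, unit %s\n",
              nrow(x), diff(range(x$time_s)), attr(x, "unit")))
  NextMethod()
}

#' Read a breath-by-breath CSV export
#'
#' Reads a long CSV with one row per breath. The export schema is adapted via
#' `col_map`; the unit is declared by the caller (vendor exports rarely embed
#' it reliably).
#'
#' @param path CSV file path.
#' @param unit Declared oxygen-uptake unit (see [breath_series()]).
#' @param col_map Named list mapping the internal names `time` and `vo2` to
#'   the file's column names.
#' @param decimal_mark Decimal separator in the file (default `"."`).
#' @param participant_id Optional identifier.
#' @return A validated [breath_series()].
#' @export
read_breath_csv <- function(path, unit,
                            col_map = list(time = "time_s", vo2 = "vo2"),
                            decimal_mark = ".",
                            participant_id = NA_character_) {
  raw <- readr::read_delim(
    path, delim = if (decimal_mark == ",") ";" else ",",
    locale = readr::locale(decimal_mark = decimal_mark),
    show_col_types = FALSE, progress = FALSE
  )
  for (col in unlist(col_map)) {
    if (!col %in% names(raw)) {
      rlang::abort(sprintf("Column '%s' not found in %s.", col, path))
    }
  }
  time_s <- raw[[col_map$time]]
  vo2 <- raw[[col_map$vo2]]
  if (anyNA(time_s) || anyNA(vo2)) {
    rlang::abort(sprintf(
      "Unparseable value at row %d of %s.",
      which(is.na(time_s) | is.na(vo2))[1], path
    ))
  }
  breath_series(time_s, vo2, unit = unit, participant_id = participant_id)
}

#' Participant metadata
#'
#' @param id Identifier.
#' @param body_mass_kg Body mass in kg (required for relative-unit conversion
#'   and the lactate oxygen equivalent).
#' @param sex `"F"`, `"M"` or `"unspecified"`.
#' @param squat_1rm_kg Back-squat one-repetition maximum (metadata).
#' @return A one-row tibble of class `participant_info`.
#' @export
participant_info <- function(id, body_mass_kg,
                             sex = c("unspecified", "F", "M"),
                             squat_1rm_kg = NA_real_) {
  sex <- match.arg(sex)
  if (!is.finite(body_mass_kg) || body_mass_kg <= 0) {
    rlang::abort("`body_mass_kg` must be positive.")
  }
  out <- tibble::tibble(
    id = as.character(id), body_mass_kg = body_mass_kg,
    sex = sex, squat_1rm_kg = squat_1rm_kg
  )
  class(out) <- c("participant_info", class(out))
  out
}

#' Blood lactate panel for one session
#'
#' Holds the baseline sample, the optional sample taken 1 min before the
#' final set (quality control only; it enters no energy formula), and the
#' post-exercise samples at +60, +180 and +300 s used to capture peak
#' lactate.
#'
#' @param baseline_mmol_l Baseline concentration, mmol/L.
#' @param post_mmol_l Named numeric vector of post-exercise samples; names
#'   are seconds after exercise end (e.g. `c("60" = 2.1, "180" = 2.4,
#'   "300" = 2.2)`). At least one sample required.
#' @param pre_final_set_mmol_l Optional pre-final-set concentration.
#' @return An object of class `lactate_panel`.
#' @export
lactate_panel <- function(baseline_mmol_l, post_mmol_l,
                          pre_final_set_mmol_l = NA_real_) {
  post_mmol_l <- post_mmol_l[!is.na(post_mmol_l)]
  if (length(post_mmol_l) < 1) {
    rlang::abort("At least one post-exercise lactate sample is required.")
  }
  conc <- c(baseline_mmol_l, post_mmol_l,
            pre_final_set_mmol_l[!is.na(pre_final_set_mmol_l)])
  if (any(conc < 0)) {
    rlang::abort("Lactate concentrations must be non-negative.")
  }
  if (is.null(names(post_mmol_l))) {
    names(post_mmol_l) <- as.character(c(60, 180, 300)[seq_along(post_mmol_l)])
  }
  structure(
    list(
      baseline_mmol_l = baseline_mmol_l,
      pre_final_set_mmol_l = pre_final_set_mmol_l,
      post_mmol_l = post_mmol_l
    ),
    class = "lactate_panel"
  )
}

#' @export
print.lactate_panel <- function(x, ...) {
  cat(sprintf("<lactate_panel> baseline %.2f, peak post %.2f mmol/L (%d post samples)\n",
              x$baseline_mmol_l, max(x$post_mmol_l), length(x$post_mmol_l)))
  invisible(x)
}

#' Read a lactate panel CSV
#'
#' Long format with columns `sample` (`baseline`, `pre_final_set`,
#' `post_60`, `post_180`, `post_300`) and `lactate_mmol_l`.
#'
#' @param path CSV file path.
#' @return A [lactate_panel()].
#' @export
read_lactate_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("sample", "lactate_mmol_l")) {
    if (!col %in% names(raw)) {
      rlang::abort(sprintf("Column '%s' not found in %s.", col, path))
    }
  }
  get1 <- function(name) {
    v <- raw$lactate_mmol_l[raw$sample == name]
    if (length(v) == 0) NA_real_ else v[[1]]
  }
  post_rows <- grepl("^post_", raw$sample)
  post <- raw$lactate_mmol_l[post_rows]
  names(post) <- sub("^post_", "", raw$sample[post_rows])
  if (is.na(get1("baseline"))) {
    rlang::abort(sprintf("No baseline sample in %s.", path))
  }
  lactate_panel(get1("baseline"), post, get1("pre_final_set"))
}

#' Read a per-repetition velocity CSV
#'
#' Expects columns `set_index`, `rep_index`, `mpv_m_s` (mean propulsive
#' velocity, m/s). The (set, rep) grid must be unique and all velocities
#' positive.
#'
#' @param path CSV file path.
#' @return A tibble of class `repetition_table`.
#' @export
read_repetition_csv <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  repetition_table(raw)
}

#' @rdname read_repetition_csv
#' @param data Data frame with columns `set_index`, `rep_index`, `mpv_m_s`.
#' @export
repetition_table <- function(data) {
  for (col in c("set_index", "rep_index", "mpv_m_s")) {
    if (!col %in% names(data)) {
      rlang::abort(sprintf("Repetition table lacks column '%s'.", col))
    }
  }
  if (any(data$mpv_m_s <= 0)) {
    rlang::abort("All MPV values must be positive.")
  }
  if (anyDuplicated(data[c("set_index", "rep_index")]) > 0) {
    rlang::abort("Duplicate (set_index, rep_index) rows in repetition table.")
  }
  out <- tibble::as_tibble(data[c("set_index", "rep_index", "mpv_m_s")])
  out <- dplyr::arrange(out, .data$set_index, .data$rep_index)
  class(out) <- c("repetition_table", class(out))
  out
}

#' Manual phase marks for one session
#'
#' The start of exercise and the manually defined start of the post-exercise
#' recovery (end of the last set) on the session clock.
#'
#' @param exercise_start_s Seconds.
#' @param recovery_start_s Seconds; must exceed `exercise_start_s`.
#' @return A one-row tibble of class `phase_marks`.
#' @export
phase_marks <- function(exercise_start_s, recovery_start_s) {
  if (!is.finite(exercise_start_s) || !is.finite(recovery_start_s) ||
      recovery_start_s <= exercise_start_s) {
    rlang::abort("`recovery_start_s` must be greater than `exercise_start_s`.")
  }
  out <- tibble::tibble(
    exercise_start_s = exercise_start_s,
    recovery_start_s = recovery_start_s
  )
  class(out) <- c("phase_marks", class(out))
  out
}

#' @rdname phase_marks
#' @param path CSV with columns `exercise_start_s`, `recovery_start_s`.
#' @export
read_marks <- function(path) {
  raw <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("exercise_start_s", "recovery_start_s")) {
    if (!col %in% names(raw)) {
      rlang::abort(sprintf("Column '%s' not found in %s.", col, path))
    }
  }
  phase_marks(raw$exercise_start_s[[1]], raw$recovery_start_s[[1]])
}

#' Convert oxygen uptake to litres per second
#'
#' @param vo2 Numeric vector in `unit`.
#' @param unit Declared unit (see [breath_series()]).
#' @param body_mass_kg Body mass, required when `unit` is relative
#'   (`ml_kg_min`).
#' @return Numeric vector in L/s.
#' @export
#' @examples
#' vo2_to_l_s(3000, "ml_min") # 0.05
vo2_to_l_s <- function(vo2, unit, body_mass_kg = NULL) {
  unit <- normalise_vo2_unit(unit)
  switch(unit,
    l_min = vo2 / 60,
    ml_min = vo2 / 60000,
    ml_kg_min = {
      if (is.null(body_mass_kg) || !is.finite(body_mass_kg) || body_mass_kg <= 0) {
        rlang::abort("`body_mass_kg` is required to convert relative VO2 units.")
      }
      vo2 * body_mass_kg / 60000
    }
  )
}

#' Convert litres per second to mL per kg per minute
#'
#' The unit in which baseline oxygen uptake is conventionally reported.
#'
#' @param vo2_l_s Numeric vector, L/s.
#' @param body_mass_kg Body mass in kg.
#' @return Numeric vector in mL/kg/min.
#' @export
vo2_l_s_to_ml_kg_min <- function(vo2_l_s, body_mass_kg) {
  vo2_l_s * 60000 / body_mass_kg
}
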