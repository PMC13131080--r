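#' Define a resistance-exercise set protocol
#'
#' A protocol specification describes the set structure of one experimental
#' session: the number of sets, repetitions per set, and the rest scheme.
#' Cluster-set (CS) protocols insert short intra-set rests after every
#' `cluster_size` repetitions; traditional-set (TS) protocols perform all
#' repetitions of a set continuously. The defaults encode the two study
#' protocols: 4 sets of 6 back squats at 75% 1RM, 180 s between sets, a
#' 900 s seated recovery, and (CS only) 30 s intra-set rests after
#' repetitions 2 and 4.
#'
#' @param label `"CS"` or `"TS"`.
#' @param n_sets Number of sets (default 4).
#' @param reps_per_set Repetitions per set (default 6).
#' @param cluster_size Repetitions per cluster for CS (default 2, i.e. rests
#'   after reps 2 and 4 of a 6-rep set). Ignored for TS, where each set is a
#'   single cluster. Must divide `reps_per_set`.
#' @param intra_set_rest_s Intra-set rest duration in seconds (CS only,
#'   default 30).
#' @param inter_set_rest_s Rest between sets in seconds (default 180).
#' @param final_recovery_s Seated recovery after the last set in seconds
#'   (default 900).
#' @param load_pct_1rm Load as a percentage of the one-repetition maximum
#'   (metadata only, default 75).
#'
#' @return An object of class `protocol_spec`.
#' @seealso [build_timeline()]
#' @export
#' @examples
#' cs <- protocol_spec("CS")
#' ts <- protocol_spec("TS")
#' n_intra_rests(cs) # 8
#' n_intra_rests(ts) # 0
protocol_spec <- function(label = c("CS", "TS"),
                          n_sets = 4L,
                          reps_per_set = 6L,
                          cluster_size = 2L,
                          intra_set_rest_s = 30,
                          inter_set_rest_s = 180,
                          final_recovery_s = 900,
                          load_pct_1rm = 75) {
  label <- match.arg(label)
  n_sets <- as.integer(n_sets)
  reps_per_set <- as.integer(reps_per_set)
  if (n_sets < 1L) {
    rlang::abort("`n_sets` must be at least 1.")
  }
  if (reps_per_set < 1L) {
    rlang::abort("`reps_per_set` must be at least 1.")
  }
  if (label == "TS") {
    cluster_size <- reps_per_set # one continuous cluster per set
  } else {
    cluster_size <- as.integer(cluster_size)
    if (cluster_size < 1L || reps_per_set %% cluster_size != 0L) {
      rlang::abort("`cluster_size` must be a positive divisor of `reps_per_set`.")
    }
  }
  durations <- c(intra_set_rest_s, inter_set_rest_s, final_recovery_s)
  if (any(!is.finite(durations)) || any(durations <= 0)) {
    rlang::abort("All rest durations must be positive and finite.")
  }
  structure(
    list(
      label = label,
      n_sets = n_sets,
      reps_per_set = reps_per_set,
      cluster_size = cluster_size,
      intra_set_rest_s = intra_set_rest_s,
      inter_set_rest_s = inter_set_rest_s,
      final_recovery_s = final_recovery_s,
      load_pct_1rm = load_pct_1rm
    ),
    class = "protocol_spec"
  )
}

#' @export
print.protocol_spec <- function(x, ...) {
  cat(sprintf(
    "<protocol_spec> %s: %d sets x %d reps (clusters of %d), intra %gs, inter %gs, recovery %gs, %g%% 1RM\n",
    x$label, x$n_sets, x$reps_per_set, x$cluster_size,
    x$intra_set_rest_s, x$inter_set_rest_s, x$final_recovery_s, x$load_pct_1rm
  ))
  invisible(x)
}

#' Segment counts implied by a protocol
#'
#' @param spec A [protocol_spec()].
#' @return Integer count.
#' @export
n_intra_rests <- function(spec) {
  spec$n_sets * (spec$reps_per_set %/% spec$cluster_size - 1L)
}

#' @rdname n_intra_rests
#' @export
n_work_segments <- function(spec) {
  spec$n_sets * (spec$reps_per_set %/% spec$cluster_size)
}

#' @rdname n_intra_rests
#' @export
n_inter_rests <- function(spec) {
  spec$n_sets - 1L
}

#' Build the session timeline for a protocol
#'
#' Expands a [protocol_spec()] into an ordered, contiguous sequence of
#' segments (baseline, work, intra-set rest, inter-set rest, final recovery)
#' on a single session clock with `t = 0` at the start of the baseline
#' segment. Every downstream integration window is expressed on this clock.
#'
#' Work-segment durations are inputs (annotations or synthetic configuration)
#' because repetition tempo is not part of the protocol definition; the
#' default assumes 3.5 s per repetition.
#'
#' @param spec A [protocol_spec()].
#' @param work_durations Numeric vector of per-work-segment durations in
#'   seconds, one per continuous block of repetitions (`n_sets` for TS,
#'   `n_sets * reps_per_set / cluster_size` for CS). Defaults to
#'   `rep_duration_s` times the repetitions in each block.
#' @param baseline_duration_s Duration of the pre-exercise baseline segment
#'   (default 120 s).
#' @param rep_duration_s Seconds per repetition used when `work_durations`
#'   is not given (default 3.5).
#'
#' @return A tibble of class `session_timeline` with columns `kind`
#'   (`baseline`, `work`, `intra_rest`, `inter_rest`, `final_recovery`),
#'   `start_s`, `end_s`, `set_index`, `cluster_index`.
#' @export
#' @examples
#' tl <- build_timeline(protocol_spec("CS"))
#' table(tl$kind)
build_timeline <- function(spec, work_durations = NULL,
                           baseline_duration_s = 120,
                           rep_duration_s = 3.5) {
  stopifnot(inherits(spec, "protocol_spec"))
  if (baseline_duration_s <= 0) {
    rlang::abort("`baseline_duration_s` must be positive.")
  }
  clusters_per_set <- spec$reps_per_set %/% spec$cluster_size
  n_work <- n_work_segments(spec)
  if (is.null(work_durations)) {
    work_durations <- rep(spec$cluster_size * rep_duration_s, n_work)
  }
  if (length(work_durations) != n_work) {
    rlang::abort(sprintf(
      "`work_durations` has length %d but the protocol implies %d work segments (%d sets x %d clusters).",
      length(work_durations), n_work, spec$n_sets, clusters_per_set
    ))
  }
  if (any(work_durations <= 0)) {
    rlang::abort("All work durations must be positive.")
  }

  kind <- "baseline"
  dur <- baseline_duration_s
  set_idx <- NA_integer_
  clus_idx <- NA_integer_
  w <- 0L
  for (s in seq_len(spec$n_sets)) {
    for (k in seq_len(clusters_per_set)) {
      w <- w + 1L
      kind <- c(kind, "work")
      dur <- c(dur, work_durations[[w]])
      set_idx <- c(set_idx, s)
      clus_idx <- c(clus_idx, k)
      if (k < clusters_per_set) {
        kind <- c(kind, "intra_rest")
        dur <- c(dur, spec$intra_set_rest_s)
        set_idx <- c(set_idx, s)
        clus_idx <- c(clus_idx, k)
      }
    }
    if (s < spec$n_sets) {
      kind <- c(kind, "inter_rest")
      dur <- c(dur, spec$inter_set_rest_s)
      set_idx <- c(set_idx, s)
      clus_idx <- c(clus_idx, NA_integer_)
    }
  }
  kind <- c(kind, "final_recovery")
  dur <- c(dur, spec$final_recovery_s)
  set_idx <- c(set_idx, NA_integer_)
  clus_idx <- c(clus_idx, NA_integer_)

  end_s <- cumsum(dur)
  out <- tibble::tibble(
    kind = kind,
    start_s = c(0, end_s[-length(end_s)]),
    end_s = end_s,
    set_index = set_idx,
    cluster_index = clus_idx
  )
  class(out) <- c("session_timeline", class(out))
  attr(out, "spec") <- spec
  out
}

timeline_validate <- function(timeline) {
  stopifnot(is.data.frame(timeline))
  needed <- c("kind", "start_s", "end_s")
  missing <- setdiff(needed, names(timeline))
  if (length(missing) > 0) {
    rlang::abort(paste0("Timeline lacks columns: ", paste(missing, collapse = ", ")))
  }
  if (any(timeline$end_s <= timeline$start_s)) {
    rlang::abort("Timeline has segments with non-positive duration.")
  }
  gaps <- timeline$start_s[-1] - timeline$end_s[-nrow(timeline)]
  if (any(abs(gaps) > 1e-9)) {
    rlang::abort("Timeline segments are not contiguous.")
  }
  invisible(timeline)
}

timeline_segments <- function(timeline, kinds) {
  dplyr::filter(timeline, .data$kind %in% kinds)
}

#' Total duration of a session timeline
#' @param timeline A `session_timeline`.
#' @return Duration in seconds.
#' @export
timeline_duration <- function(timeline) {
  max(timeline$end_s) - min(timeline$start_s)
}

#' Read or write a session timeline as CSV
#'
#' @param timeline A `session_timeline` tibble.
#' @param path File path.
#' @return `write_timeline_csv()` returns `path` invisibly;
#'   `read_timeline_csv()` returns a validated `session_timeline`.
#' @export
write_timeline_csv <- function(timeline, path) {
  timeline_validate(timeline)
  readr::write_csv(as.data.frame(timeline), path)
  invisible(path)
}

#' @rdname write_timeline_csv
#' @export
read_timeline_csv <- function(path) {
  out <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(
                           kind = readr::col_character(),
                           start_s = readr::col_double(),
                           end_s = readr::col_double(),
                           set_index = readr::col_integer(),
                           cluster_index = readr::col_integer()
                         ))
  timeline_validate(out)
  class(out) <- c("session_timeline", class(out))
  out
}
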