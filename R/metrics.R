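#' Detect organ-level contractions in a pressure trace
#'
#' An event is a maximal contiguous run of steps (after an initial transient)
#' in which pressure is at or above a detection level set relative to the
#' trace: `floor + level_fraction * (max - floor)`. Adjacent events are
#' separated by at least one sub-level step by construction. The relative
#' level makes the event count invariant under uniform rescaling of the
#' trace; a flat trace has no events.
#'
#' @param trace numeric pressure vector (entry 1 is step 0).
#' @param level_fraction detection level as a fraction of the post-transient
#'   excursion above the floor, in (0, 1).
#' @param transient_skip steps discarded at the start so that the decaying
#'   imprint of the initial pressure is never counted as a contraction.
#' @param floor baseline pressure; defaults to the post-transient minimum
#'   (pass the configured minimum pressure when available).
#' @return A data.frame with one row per event: `onset_step`, `offset_step`,
#'   `peak_step`, `peak_pressure` (steps are 0-based like the trace).
#' @examples
#' run <- run_simulation(preset_config(9), single_strip_fields())
#' detect_contractions(run$pressure_trace, floor = 0.6)
#' @export
detect_contractions <- function(trace, level_fraction = 0.5,
                                transient_skip = 20, floor = NULL) {
  stopifnot(is.numeric(trace), level_fraction > 0, level_fraction < 1)
  if (length(trace) <= transient_skip + 1L)
    stop("detect_contractions: trace shorter than the transient window",
         call. = FALSE)
  empty <- data.frame(onset_step = integer(0), offset_step = integer(0),
                      peak_step = integer(0), peak_pressure = numeric(0))
  idx <- (transient_skip + 2L):length(trace)   # trace[i] is step i-1
  sub <- trace[idx]
  if (is.null(floor)) floor <- min(sub)
  mx <- max(sub)
  if (mx - floor < 1e-9) return(empty)
  level <- floor + level_fraction * (mx - floor)
  above <- sub >= level
  if (!any(above)) return(empty)
  starts <- which(diff(c(FALSE, above)) == 1L)
  ends <- which(diff(c(above, FALSE)) == -1L)
  peaks <- vapply(seq_along(starts), function(k) {
    w <- starts[k]:ends[k]
    w[which.max(sub[w])]
  }, numeric(1))
  data.frame(
    onset_step = idx[starts] - 1L,
    offset_step = idx[ends] - 1L,
    peak_step = idx[peaks] - 1L,
    peak_pressure = vapply(seq_along(starts), function(k)
      max(sub[starts[k]:ends[k]]), numeric(1)))
}

#' Pseudo-Montevideo units of a pressure trace
#'
#' The simulation analog of the clinical Montevideo unit: mean per-event peak
#' pressure times the number of events, normalized to a 300-step window
#' (about 25 minutes at ~5 s per step). Zero when no events are detected.
#' Using the mean of per-event peaks (rather than the single global peak)
#' keeps the statistic robust to one outlier contraction.
#'
#' @param trace numeric pressure vector.
#' @param window normalization window in steps.
#' @param events optional precomputed event table from
#'   [detect_contractions()]; detected from `trace` when absent.
#' @param ... passed to [detect_contractions()].
#' @return A non-negative scalar.
#' @examples
#' run <- run_simulation(preset_config(9), single_strip_fields())
#' pseudo_montevideo(run$pressure_trace, floor = 0.6)   # ~90
#' @export
pseudo_montevideo <- function(trace, window = 300, events = NULL, ...) {
  if (is.null(events)) events <- detect_contractions(trace, ...)
  if (nrow(events) == 0L) return(0)
  n_steps <- length(trace) - 1L
  mean(events$peak_pressure) * nrow(events) * window / n_steps
}

#' Identify the apparent pacemaker of each contraction
#'
#' For every detected event, the apparent pacemaker is the first region to
#' enter a burst in the window between the previous event's offset (or the
#' start of the trace) and the event's peak, whose burst persists into the
#' event's rising phase (i.e. is still running at the event onset or later).
#' Ties at the same onset step go to the region with the larger total
#' sensitivity. The run-level `dominant` region is the one with the most
#' burst onsets over the whole trace — the highest-frequency firing site,
#' which is how a pacemaker would be sought experimentally.
#'
#' @param run a `uterus_run`.
#' @param events optional event table from [detect_contractions()].
#' @param ... passed to [detect_contractions()] when `events` is absent.
#' @return A list with `per_event` (data.frame: event, onset_step, row, col;
#'   `NA` row/col when undetermined) and `dominant` (length-2 integer vector
#'   row/col, or `NA` if nothing ever bursts).
#' @export
identify_pacemaker <- function(run, events = NULL, ...) {
  stopifnot(inherits(run, "uterus_run"))
  if (is.null(events))
    events <- detect_contractions(run$pressure_trace,
                                  floor = run$config$min_pressure, ...)
  ph <- run$phase_tensor
  nt <- dim(ph)[1]
  nr <- dim(ph)[2]; nc <- dim(ph)[3]
  ts <- total_sensitivity(run$fields)

  # burst-onset indicator per step (tensor index = step + 1)
  bursting <- ph == PHASE_BURSTING
  onset <- bursting
  onset[2:nt, , ] <- bursting[2:nt, , , drop = FALSE] &
    !bursting[1:(nt - 1), , , drop = FALSE]

  per_event <- data.frame(event = integer(0), onset_step = integer(0),
                          row = integer(0), col = integer(0))
  prev_offset <- 0L
  for (k in seq_len(nrow(events))) {
    win <- (prev_offset + 1L):events$peak_step[k]
    found <- c(NA_integer_, NA_integer_)
    for (s in win) {
      starts <- which(onset[s + 1L, , , drop = TRUE], arr.ind = nr > 1 | nc > 1)
      cand <- .as_rowcol(starts, nr, nc)
      if (nrow(cand) == 0L) next
      # burst must persist into the rising phase of the event
      keep <- vapply(seq_len(nrow(cand)), function(i) {
        r <- cand[i, 1]; cc <- cand[i, 2]
        to <- s
        while (to + 1L < nt && bursting[to + 2L, r, cc]) to <- to + 1L
        to >= events$onset_step[k]
      }, logical(1))
      cand <- cand[keep, , drop = FALSE]
      if (nrow(cand) == 0L) next
      best <- which.max(ts[cand])
      found <- c(cand[best, 1], cand[best, 2])
      break
    }
    per_event <- rbind(per_event, data.frame(
      event = k, onset_step = events$onset_step[k],
      row = found[1], col = found[2]))
    prev_offset <- events$offset_step[k]
  }

  onset_counts <- apply(onset, c(2, 3), sum)
  dominant <- if (all(onset_counts == 0)) c(NA_integer_, NA_integer_) else {
    w <- which(onset_counts == max(onset_counts), arr.ind = TRUE)
    unname(c(w[1, 1], w[1, 2]))
  }
  list(per_event = per_event, dominant = dominant)
}

.as_rowcol <- function(starts, nr, nc) {
  if (is.matrix(starts)) return(starts)
  if (length(starts) == 0L) return(matrix(integer(0), 0, 2))
  # linear indices into an nr x nc matrix
  cbind(((starts - 1L) %% nr) + 1L, ((starts - 1L) %/% nr) + 1L)
}

#' Classify a run into the input-based automaton classes
#'
#' Operational version of a Wolfram-style four-class scheme applied to input
#' sets rather than rules: class 1 when the post-transient pressure is
#' constant (uniform state); class 2 when at least `min_events` contractions
#' recur with inter-onset intervals of coefficient of variation below
#' `cv_threshold` (repetitive state); class 4 when contractions recur but
#' their intervals vary at or above the threshold (complex, emergent state);
#' class 3 otherwise (sustained non-repeating fluctuation that never
#' organizes into events — a fallback bucket: no input set is known to
#' produce it). Physiological-relevance modifiers (normal/pathological/never
#' observed) are domain judgement, not computation: `modifier` is a free-text
#' annotation slot the caller may set.
#'
#' @param trace numeric pressure vector.
#' @param events optional event table from [detect_contractions()].
#' @param transient_skip steps to discard before assessing uniformity.
#' @param cv_threshold class 2 vs 4 boundary on the interval coefficient of
#'   variation.
#' @param eps variance tolerance for calling a trace constant.
#' @param min_events minimum recurring contractions for class 2/4.
#' @param modifier optional annotation (e.g. "N", "P", "X"), stored verbatim.
#' @param ... passed to [detect_contractions()] when `events` is absent.
#' @return A `behavior_class`: list with `class_id` (1, 2, 3 or 4),
#'   `n_events`, `interval_cv` (NA when fewer than `min_events` events), and
#'   `modifier`.
#' @export
classify_behavior <- function(trace, events = NULL, transient_skip = 20,
                              cv_threshold = 0.05, eps = 1e-9,
                              min_events = 3L, modifier = NA_character_, ...) {
  if (length(trace) <= transient_skip + 1L)
    stop("classify_behavior: trace shorter than the transient window",
         call. = FALSE)
  post <- trace[(transient_skip + 2L):length(trace)]
  if (is.null(events))
    events <- detect_contractions(trace, transient_skip = transient_skip, ...)
  cv <- NA_real_
  if (max(post) - min(post) < eps) {
    cls <- 1L
  } else if (nrow(events) >= min_events) {
    iv <- diff(events$onset_step)
    cv <- stats::sd(iv) / mean(iv)
    cls <- if (cv < cv_threshold) 2L else 4L
  } else {
    cls <- 3L
  }
  structure(list(class_id = cls, n_events = nrow(events), interval_cv = cv,
                 modifier = modifier),
            class = "behavior_class")
}

#' @export
print.behavior_class <- function(x, ...) {
  cat(sprintf("<behavior_class> class %d%s (%d events, interval CV %s)\n",
              x$class_id,
              if (is.na(x$modifier)) "" else paste0("-", x$modifier),
              x$n_events,
              if (is.na(x$interval_cv)) "NA" else sprintf("%.3f", x$interval_cv)))
  invisible(x)
}

#' Full metrics report for a run
#'
#' Bundles the event table, pseudo-Montevideo units, mean total sensitivity,
#' per-event and dominant pacemakers, peak pressure, and the behavior class.
#'
#' @param run a `uterus_run`.
#' @param ... passed to [detect_contractions()].
#' @return A list of class `uterus_metrics`.
#' @export
metrics_report <- function(run, ...) {
  stopifnot(inherits(run, "uterus_run"))
  cfg <- run$config
  events <- detect_contractions(run$pressure_trace,
                                floor = cfg$min_pressure, ...)
  pm <- identify_pacemaker(run, events)
  structure(list(
    events = events,
    pmv = pseudo_montevideo(run$pressure_trace, events = events),
    peak_pressure = max(run$pressure_trace),
    mean_total_sensitivity = mean_total_sensitivity(run$fields),
    pacemaker_per_event = pm$per_event,
    dominant_pacemaker = pm$dominant,
    behavior = classify_behavior(run$pressure_trace, events = events)
  ), class = "uterus_metrics")
}

#' @export
print.uterus_metrics <- function(x, ...) {
  cat("<uterus_metrics>\n")
  cat(sprintf("  contractions : %d (peak pressure %.3f)\n",
              nrow(x$events), x$peak_pressure))
  cat(sprintf("  pMV          : %.2f\n", x$pmv))
  cat(sprintf("  mean total sensitivity: %.3f\n", x$mean_total_sensitivity))
  cat(sprintf("  behavior     : class %d\n", x$behavior$class_id))
  if (!anyNA(x$dominant_pacemaker))
    cat(sprintf("  dominant pacemaker: region (%d, %d)\n",
                x$dominant_pacemaker[1], x$dominant_pacemaker[2]))
  invisible(x)
}

#' Write a metrics report as JSON (plus an optional CSV event table)
#'
#' @param metrics a `uterus_metrics`.
#' @param json_path output JSON path.
#' @param events_csv optional CSV path for the event table.
#' @return `json_path`, invisibly.
#' @export
write_metrics_json <- function(metrics, json_path, events_csv = NULL) {
  stopifnot(inherits(metrics, "uterus_metrics"))
  doc <- list(
    events = metrics$events,
    pMV = metrics$pmv,
    peak_pressure = metrics$peak_pressure,
    mean_total_sensitivity = metrics$mean_total_sensitivity,
    pacemaker_per_event = metrics$pacemaker_per_event,
    dominant_pacemaker = metrics$dominant_pacemaker,
    behavior_class = metrics$behavior$class_id,
    interval_cv = metrics$behavior$interval_cv)
  jsonlite::write_json(doc, json_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA, na = "null")
  if (!is.null(events_csv))
    utils::write.csv(metrics$events, events_csv, row.names = FALSE)
  invisible(json_path)
}
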