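# Phase codes used throughout the engine: integer matrices keep the hot loop
# vectorized; the exported constants give them names.

#' Region phase codes
#'
#' Regions cycle QUIESCENT -> BURSTING -> REFRACTORY -> QUIESCENT. The phase
#' tensors produced by [run_simulation()] store the integer codes; these
#' constants name them.
#' @format Integer scalars.
#' @export
PHASE_QUIESCENT <- 0L
#' @rdname PHASE_QUIESCENT
#' @export
PHASE_BURSTING <- 1L
#' @rdname PHASE_QUIESCENT
#' @export
PHASE_REFRACTORY <- 2L

#' Organ-level pressure from regional activities
#'
#' Rule 1: pressure is the mean over regions of activity divided by anatomy
#' sensitivity (inverting the Law-of-Laplace conversion region by region),
#' floored at the configured minimum pressure — the uterus never falls below
#' its baseline tone.
#'
#' @param activity numeric matrix of regional activities.
#' @param fields a `region_fields` of matching shape.
#' @param cfg a `uterus_config` (supplies `min_pressure`).
#' @return A non-negative scalar pressure.
#' @examples
#' f <- region_fields(matrix(c(1, 1), 1), matrix(c(1, 1), 1))
#' cfg <- uterus_config(1, 2)
#' compute_pressure(matrix(c(3, 0), 1), f, cfg)  # (3/1 + 0/1)/2 = 1.5
#' @export
compute_pressure <- function(activity, fields, cfg) {
  max(cfg$min_pressure, mean(activity / fields$anatomy))
}

#' Initial engine state
#'
#' All regions start quiescent with age 0; initial activities are the passive
#' tensions implied by the starting pressure (`initial_pressure * anatomy`,
#' clipped to the activity range), and the recorded pressure is recomputed
#' from those activities, which by the Rule 1/Rule 2 round trip equals
#' `max(min_pressure, initial_pressure)` whenever the clip is inactive.
#'
#' @param cfg a validated `uterus_config`.
#' @param fields a `region_fields` matching the configured grid.
#' @return An `engine_state`: list with `t`, `activity`, `pressure`, `phase`,
#'   `age`.
#' @export
initial_state <- function(cfg, fields) {
  stopifnot(inherits(cfg, "uterus_config"), inherits(fields, "region_fields"))
  if (!all(dim(fields$anatomy) == c(cfg$rows, cfg$columns)))
    stop("initial_state: fields shape (", paste(dim(fields$anatomy), collapse = "x"),
         ") does not match the configured grid (", cfg$rows, "x", cfg$columns, ")",
         call. = FALSE)
  activity <- pmin(pmax(cfg$initial_pressure * fields$anatomy, 0),
                   cfg$activity_cap)
  structure(list(
    t = 0L,
    activity = activity,
    pressure = compute_pressure(activity, fields, cfg),
    phase = matrix(PHASE_QUIESCENT, cfg$rows, cfg$columns),
    age = matrix(0L, cfg$rows, cfg$columns)
  ), class = "engine_state")
}

#' Advance the per-region phase machines by one step
#'
#' Rule 3's state machine, decided from the passive tensions of the current
#' pressure. A quiescent region starts bursting when its passive tension
#' strictly exceeds its threshold (at exact equality no burst initiates). A
#' bursting region keeps bursting while its amplified activity
#' (`passive * ap_multiplier`) stays at or above threshold and its burst age
#' has not hit `burst_duration`; otherwise it enters the refractory period,
#' which lasts exactly `refractory_duration` steps and is followed by one
#' quiescent step before the region can re-burst.
#'
#' @param state an `engine_state`.
#' @param passive numeric matrix of passive tensions
#'   (`pressure * anatomy`).
#' @param cfg a `uterus_config`.
#' @param fields a `region_fields`.
#' @return List with updated integer matrices `phase` and `age`.
#' @export
update_phases <- function(state, passive, cfg, fields) {
  phase <- state$phase; age <- state$age
  th <- fields$threshold

  q <- phase == PHASE_QUIESCENT
  b <- phase == PHASE_BURSTING
  r <- phase == PHASE_REFRACTORY

  ignite <- q & (passive > th)
  b_stop <- b & (age + 1L > cfg$burst_duration |
                 passive * cfg$ap_multiplier < th)
  r_done <- r & (age + 1L > cfg$refractory_duration)

  new_phase <- phase
  new_age <- age + 1L
  new_phase[ignite] <- PHASE_BURSTING;   new_age[ignite] <- 1L
  new_phase[b_stop] <- PHASE_REFRACTORY; new_age[b_stop] <- 1L
  new_phase[r_done] <- PHASE_QUIESCENT;  new_age[r_done] <- 0L
  list(phase = new_phase, age = new_age)
}

#' Advance the automaton by one time step
#'
#' With the current pressure p: passive tensions are `p * anatomy` (Rule 2),
#' phases advance per [update_phases()], each region's activity becomes its
#' passive tension times its phase factor (`ap_multiplier` while bursting,
#' `refractory_multiplier` while refractory, 1 otherwise), clipped to
#' `[0, activity_cap]` (Rule 3), and the new pressure follows from
#' [compute_pressure()] (Rule 1).
#'
#' @param state an `engine_state`.
#' @param cfg a `uterus_config`.
#' @param fields a `region_fields`.
#' @return The next `engine_state`.
#' @export
step_state <- function(state, cfg, fields) {
  passive <- state$pressure * fields$anatomy
  ph <- update_phases(state, passive, cfg, fields)
  factor <- matrix(1, nrow(passive), ncol(passive))
  factor[ph$phase == PHASE_BURSTING] <- cfg$ap_multiplier
  factor[ph$phase == PHASE_REFRACTORY] <- cfg$refractory_multiplier
  activity <- pmin(pmax(passive * factor, 0), cfg$activity_cap)
  structure(list(
    t = state$t + 1L,
    activity = activity,
    pressure = compute_pressure(activity, fields, cfg),
    phase = ph$phase,
    age = ph$age
  ), class = "engine_state")
}

#' Run the cellular automaton
#'
#' Applies [initial_state()] then `timesteps` iterations of [step_state()],
#' recording the full pressure trace and the activity and phase tensors. The
#' result is a deterministic function of `(cfg, fields)`.
#'
#' @param cfg a validated `uterus_config`.
#' @param fields optional `region_fields`; sampled via [build_fields()] when
#'   absent.
#' @return A `uterus_run`: list with `pressure_trace` (length
#'   `timesteps + 1`, entry 1 is the state at step 0), `activity_tensor` and
#'   `phase_tensor` (`(timesteps + 1) x rows x columns`), plus `config` and
#'   `fields`.
#' @examples
#' run <- run_simulation(preset_config(9), single_strip_fields())
#' max(run$pressure_trace)
#' @export
run_simulation <- function(cfg, fields = NULL) {
  validate_config(cfg)
  if (is.null(fields)) fields <- build_fields(cfg)
  state <- initial_state(cfg, fields)
  nt <- cfg$timesteps
  pressure_trace <- numeric(nt + 1L)
  activity_tensor <- array(NA_real_, dim = c(nt + 1L, cfg$rows, cfg$columns))
  phase_tensor <- array(NA_integer_, dim = c(nt + 1L, cfg$rows, cfg$columns))
  pressure_trace[1L] <- state$pressure
  activity_tensor[1L, , ] <- state$activity
  phase_tensor[1L, , ] <- state$phase
  for (t in seq_len(nt)) {
    state <- step_state(state, cfg, fields)
    pressure_trace[t + 1L] <- state$pressure
    activity_tensor[t + 1L, , ] <- state$activity
    phase_tensor[t + 1L, , ] <- state$phase
  }
  structure(list(
    pressure_trace = pressure_trace,
    activity_tensor = activity_tensor,
    phase_tensor = phase_tensor,
    config = cfg,
    fields = fields
  ), class = "uterus_run")
}

#' @export
print.uterus_run <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("<uterus_run> %d x %d regions, %d steps (%s)\n",
              cfg$rows, cfg$columns, cfg$timesteps, format_descriptor(cfg)))
  cat(sprintf("  pressure: floor %g, peak %.3f\n",
              cfg$min_pressure, max(x$pressure_trace)))
  ev <- detect_contractions(x$pressure_trace, floor = cfg$min_pressure)
  cat(sprintf("  contractions detected: %d\n", nrow(ev)))
  invisible(x)
}

#' Export a run to plain-text files
#'
#' Writes `pressure.csv` (columns step, pressure), `activity.csv` (columns
#' step, row, col, activity, phase; one record per region per step), and
#' `run.json` (configuration, descriptor, seeds, fields provenance, and the
#' engine's semantic constants) into `dir`.
#'
#' @param run a `uterus_run`.
#' @param dir output directory (created if needed).
#' @return The directory path, invisibly.
#' @export
export_run <- function(run, dir) {
  stopifnot(inherits(run, "uterus_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  cfg <- run$config
  nt <- cfg$timesteps
  utils::write.csv(
    data.frame(step = 0:nt, pressure = run$pressure_trace),
    file.path(dir, "pressure.csv"), row.names = FALSE)
  grid <- expand.grid(step = 0:nt, row = seq_len(cfg$rows),
                      col = seq_len(cfg$columns))
  grid$activity <- as.vector(run$activity_tensor)
  grid$phase <- as.vector(run$phase_tensor)
  utils::write.csv(grid, file.path(dir, "activity.csv"), row.names = FALSE)
  cfg_doc <- lapply(unclass(cfg), function(v)
    if (inherits(v, "weibull_spec")) unclass(v) else v)
  meta <- list(
    descriptor = format_descriptor(cfg),
    config = cfg_doc,
    fields_provenance = run$fields$provenance,
    semantics = list(
      threshold_comparison = "strict: burst initiates only when passive tension exceeds threshold",
      burst_continuation = "amplified activity (passive x ap_multiplier) compared to threshold",
      refractory_exit = "one quiescent step before re-burst; onset period = burst + refractory + 1",
      activity_range = c(0, cfg$activity_cap),
      step_seconds_approx = 5))
  jsonlite::write_json(meta, file.path(dir, "run.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(dir)
}
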