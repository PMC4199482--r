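#' Drug-exposure sweep over the action-potential multiplier
#'
#' Runs the automaton once per multiplier value with everything else held
#' fixed — including the heterogeneity fields, which are sampled once from
#' the base configuration so that the sweep isolates the drug effect.
#' Lowering the multiplier emulates an L-type calcium-channel blocker
#' (nifedipine); raising it emulates oxytocin's increase of burst force.
#'
#' @param base a `uterus_config`; its multiplier is ignored.
#' @param multipliers numeric vector of action-potential multipliers (> 1).
#' @param fields optional `region_fields` reused across the sweep; sampled
#'   from `base` when absent.
#' @param organ_level_peak events with peaks at or above this pressure count
#'   as organ-level contractions in the `n_organ_events` column.
#' @return A data.frame with one row per multiplier: `ap_multiplier`,
#'   `n_events`, `n_organ_events`, `pmv`, `peak_pressure`, `behavior_class`.
#' @export
scenario_drug_sweep <- function(base, multipliers, fields = NULL,
                                organ_level_peak = 5) {
  stopifnot(inherits(base, "uterus_config"), length(multipliers) >= 1,
            all(multipliers > 1))
  if (is.null(fields)) fields <- build_fields(base)
  rows <- lapply(multipliers, function(m) {
    cfg <- base; cfg$ap_multiplier <- as.numeric(m)
    run <- run_simulation(cfg, fields)
    ev <- detect_contractions(run$pressure_trace, floor = cfg$min_pressure)
    data.frame(
      ap_multiplier = m,
      n_events = nrow(ev),
      n_organ_events = sum(ev$peak_pressure >= organ_level_peak),
      pmv = pseudo_montevideo(run$pressure_trace, events = ev),
      peak_pressure = max(run$pressure_trace),
      behavior_class = classify_behavior(run$pressure_trace,
                                         events = ev)$class_id)
  })
  do.call(rbind, rows)
}

#' Region-count sweep
#'
#' Runs the automaton once per grid with the scalar inputs of `base` held
#' fixed. Because the matrix shapes change, the heterogeneity fields are
#' freshly sampled for every grid (from the base seeds, which are the same
#' for every grid unless `seed_offset` varies them); the per-row mean total
#' sensitivity is reported so force changes can be checked against sampling
#' drift.
#'
#' @param base a `uterus_config`; its grid is ignored.
#' @param grids list of `c(rows, columns)` pairs, each within 1..64 regions.
#' @param seed_offset integer added to both seeds (use to replicate the sweep
#'   on a different "patient").
#' @return A data.frame with one row per grid: `rows`, `columns`,
#'   `n_regions`, `n_events`, `pmv`, `peak_pressure`,
#'   `mean_total_sensitivity`.
#' @export
scenario_region_sweep <- function(base, grids, seed_offset = 0L) {
  stopifnot(inherits(base, "uterus_config"))
  rows <- lapply(grids, function(g) {
    stopifnot(length(g) == 2)
    cfg <- base
    cfg$rows <- as.integer(g[1]); cfg$columns <- as.integer(g[2])
    cfg$anatomy_seed <- base$anatomy_seed + as.integer(seed_offset)
    cfg$threshold_seed <- base$threshold_seed + as.integer(seed_offset)
    validate_config(cfg)
    fields <- build_fields(cfg)
    run <- run_simulation(cfg, fields)
    ev <- detect_contractions(run$pressure_trace, floor = cfg$min_pressure)
    data.frame(
      rows = cfg$rows, columns = cfg$columns,
      n_regions = cfg$rows * cfg$columns,
      n_events = nrow(ev),
      pmv = pseudo_montevideo(run$pressure_trace, events = ev),
      peak_pressure = max(run$pressure_trace),
      mean_total_sensitivity = mean_total_sensitivity(fields))
  })
  do.call(rbind, rows)
}

#' Paired tissue-strip experiment
#'
#' Runs a 1x2 grid — two mechanically linked strips sharing one pressure —
#' and summarizes the phase relation between them: per-region burst-onset
#' intervals and the burst overlap, the fraction of steps in which both
#' regions are simultaneously bursting (0 = strictly alternating, values
#' near the burst duty cycle = in-phase).
#'
#' @param fixture a 1x2 `region_fields` (e.g. [two_strip_fields()]).
#' @param base a `uterus_config` with `rows = 1, columns = 2`.
#' @return A list with the `run`, `overlap`, `burst_steps` (per-region count
#'   of bursting steps), `onsets` (list of per-region burst-onset steps) and
#'   `mean_interval` (per-region mean onset-to-onset interval).
#' @export
scenario_two_tissue <- function(fixture, base) {
  stopifnot(inherits(fixture, "region_fields"), inherits(base, "uterus_config"))
  if (!all(dim(fixture$anatomy) == c(1L, 2L)))
    stop("scenario_two_tissue: fixture must be a 1x2 grid", call. = FALSE)
  if (base$rows != 1L || base$columns != 2L)
    stop("scenario_two_tissue: base config must use rows = 1, columns = 2",
         call. = FALSE)
  run <- run_simulation(base, fixture)
  ph <- run$phase_tensor   # (steps+1) x 1 x 2
  b1 <- ph[, 1, 1] == PHASE_BURSTING
  b2 <- ph[, 1, 2] == PHASE_BURSTING
  onsets <- lapply(list(b1, b2), function(b)
    which(diff(c(FALSE, b)) == 1L) - 1L)
  list(
    run = run,
    overlap = mean(b1 & b2),
    burst_steps = c(sum(b1), sum(b2)),
    onsets = onsets,
    mean_interval = vapply(onsets, function(o)
      if (length(o) >= 2) mean(diff(o)) else NA_real_, numeric(1)))
}
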