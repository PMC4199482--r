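# Table of the 14 preset input sets: the nine scalar inputs of the published
# parameterizations. Set 14 leaves the grid symbolic (NA rows/columns) so the
# caller chooses it, e.g. for region-count sweeps.
.preset_table <- list(
  list(1L,  4L,  4L, 300L, 0.5, 0.5,  10L, 20L, 3,   0.2),
  list(2L,  4L,  4L, 300L, 0.5, 0.5,  10L, 20L, 2,   0.2),
  list(3L,  4L,  4L, 300L, 0.5, 0.5,  10L, 20L, 1.5, 0.2),
  list(4L,  5L,  5L, 300L, 0.5, 0.5,  8L,  26L, 1.5, 0.2),
  list(5L,  5L,  5L, 300L, 0.5, 0.5,  8L,  26L, 2,   0.2),
  list(6L,  5L,  5L, 300L, 0.5, 0.5,  8L,  26L, 4,   0.2),
  list(7L,  5L,  5L, 300L, 0.5, 0.5,  8L,  26L, 8,   0.2),
  list(8L,  5L,  5L, 300L, 0.5, 0.5,  10L, 12L, 3,   0.2),
  list(9L,  1L,  1L, 300L, 1,   0.6,  10L, 20L, 3,   0.2),
  list(10L, 1L,  1L, 300L, 1,   0.55, 10L, 20L, 3,   0.2),
  list(11L, 1L,  2L, 300L, 0.5, 0.5,  10L, 14L, 3,   0.1),
  list(12L, 1L,  2L, 300L, 1,   0.5,  10L, 14L, 3,   0.1),
  list(13L, 1L,  2L, 300L, 0.5, 0.5,  10L, 10L, 3,   0.1),
  list(14L, NA,  NA, 300L, 0.5, 0.5,  10L, 20L, 2,   0.2)
)

.scalar_fields <- c("rows", "columns", "timesteps", "initial_pressure",
                    "min_pressure", "burst_duration", "refractory_duration",
                    "ap_multiplier", "refractory_multiplier")

#' Retrieve one of the published preset input sets
#'
#' Returns the nine scalar inputs (grid, time steps, pressures, burst and
#' refractory durations, multipliers) of the requested preset. Presets 1-3 are
#' the 4x4 default/tocolytic series, 4-7 the 5x5 uterotonic dose series, 8 the
#' 5x5 midrange set, 9-10 the single-strip bench-top analogs, 11-13 the paired
#' two-strip analogs, and 14 the region-count-sweep template whose grid is
#' left for the caller to choose.
#'
#' @param set_number integer in 1..14.
#' @return An object of class `uterus_input_set`: a list with `set_number`
#'   plus the nine scalar configuration fields. For set 14 `rows` and
#'   `columns` are `NA`.
#' @examples
#' preset_input_set(1)
#' @export
preset_input_set <- function(set_number) {
  if (!is.numeric(set_number) || length(set_number) != 1L ||
      is.na(set_number) || set_number != as.integer(set_number) ||
      set_number < 1 || set_number > 14)
    stop("preset_input_set: invalid preset; 'set_number' must be an integer in 1..14",
         call. = FALSE)
  row <- .preset_table[[as.integer(set_number)]]
  out <- stats::setNames(row, c("set_number", .scalar_fields))
  structure(out, class = "uterus_input_set")
}

#' @export
print.uterus_input_set <- function(x, ...) {
  cat(sprintf("<uterus_input_set #%d> %s/%s/%d  P %g/%g  dur %d/%d  mult %g/%g\n",
              x$set_number,
              ifelse(is.na(x$rows), "i", x$rows),
              ifelse(is.na(x$columns), "j", x$columns),
              x$timesteps, x$initial_pressure, x$min_pressure,
              x$burst_duration, x$refractory_duration,
              x$ap_multiplier, x$refractory_multiplier))
  invisible(x)
}

#' Full simulation configuration
#'
#' Bundles the nine scalar inputs with the two heterogeneity distributions,
#' their seeds, and the activity ceiling. Regional activity is expressed on a
#' 0..`activity_cap` scale (0 fully relaxed, cap fully contracted); with the
#' default cap of 10 the clinically reasonable baseline ("minimum") pressure
#' is near 0.5, i.e. the ~1/20 ratio of resting to maximal intrauterine
#' pressure (~15 vs ~300 torr).
#'
#' @param rows,columns grid dimensions; `rows * columns` must be in 1..64.
#' @param timesteps number of update steps (one step is on the order of 5 s).
#' @param initial_pressure starting pressure used to seed the initial regional
#'   activities, activity units.
#' @param min_pressure floor applied to organ-level pressure (baseline tone),
#'   activity units. Need not be below `initial_pressure`.
#' @param burst_duration maximum length of an action-potential burst, steps.
#' @param refractory_duration length of the post-burst refractory period,
#'   steps.
#' @param ap_multiplier factor > 1 applied to passive tension while a region
#'   bursts (uterotonics raise it, tocolytics lower it).
#' @param refractory_multiplier factor in (0, 1) applied while a region is
#'   refractory.
#' @param anatomy_weibull,threshold_weibull [weibull_spec()]s for the anatomy
#'   sensitivity and action-potential threshold fields.
#' @param anatomy_seed,threshold_seed integer seeds for the two independent
#'   sampling streams (conventionally 1000-1999 and 2000-2999).
#' @param activity_cap ceiling on regional activity, activity units.
#' @return An object of class `uterus_config` (validated).
#' @examples
#' cfg <- uterus_config(rows = 4, columns = 4, timesteps = 300,
#'                      initial_pressure = 0.5, min_pressure = 0.5,
#'                      burst_duration = 10, refractory_duration = 20,
#'                      ap_multiplier = 3, refractory_multiplier = 0.2)
#' @export
uterus_config <- function(rows, columns, timesteps = 300,
                          initial_pressure = 0.5, min_pressure = 0.5,
                          burst_duration = 10, refractory_duration = 20,
                          ap_multiplier = 3, refractory_multiplier = 0.2,
                          anatomy_weibull = weibull_spec(1.8, 1, 0.3),
                          threshold_weibull = weibull_spec(4, 0.6, 0.4),
                          anatomy_seed = 1000, threshold_seed = 2000,
                          activity_cap = 10) {
  cfg <- structure(list(
    rows = as.integer(rows), columns = as.integer(columns),
    timesteps = as.integer(timesteps),
    initial_pressure = as.numeric(initial_pressure),
    min_pressure = as.numeric(min_pressure),
    burst_duration = as.integer(burst_duration),
    refractory_duration = as.integer(refractory_duration),
    ap_multiplier = as.numeric(ap_multiplier),
    refractory_multiplier = as.numeric(refractory_multiplier),
    anatomy_weibull = anatomy_weibull,
    threshold_weibull = threshold_weibull,
    anatomy_seed = as.integer(anatomy_seed),
    threshold_seed = as.integer(threshold_seed),
    activity_cap = as.numeric(activity_cap)
  ), class = "uterus_config")
  validate_config(cfg)
  cfg
}

#' Build a configuration from a preset
#'
#' Convenience wrapper around [preset_input_set()] and [uterus_config()].
#' Arguments in `...` (seeds, Weibull specs, or scalar overrides, and for
#' preset 14 the grid) win over the preset values.
#'
#' @param set_number integer preset number in 1..14.
#' @param ... overrides passed to [uterus_config()].
#' @return A validated `uterus_config`.
#' @examples
#' preset_config(1)                          # the default parameterization
#' preset_config(14, rows = 6, columns = 3)  # sweep template needs a grid
#' @export
preset_config <- function(set_number, ...) {
  ps <- preset_input_set(set_number)
  args <- ps[.scalar_fields]
  dots <- list(...)
  args[names(dots)] <- dots
  if (is.na(args$rows) || is.na(args$columns))
    stop("preset_config: preset ", set_number,
         " leaves the grid symbolic; supply 'rows' and 'columns'", call. = FALSE)
  do.call(uterus_config, args)
}

#' Validate a simulation configuration
#'
#' Checks the structural invariants (1-64 regions, positive durations,
#' `ap_multiplier > 1`, `refractory_multiplier` in (0,1),
#' `activity_cap > min_pressure`) and emits a physiological-plausibility
#' warning (class `uterosim_plausibility`) when the minimum pressure strays
#' far from the ~0.5 baseline implied by the 0..10 activity scale; the uterus
#' always maintains a non-zero baseline tone, so e.g. `min_pressure = 0` is
#' structurally legal but physiologically unclassifiable.
#'
#' @param cfg a `uterus_config`.
#' @return `cfg`, unchanged, invisibly classed; errors on violated bounds.
#' @export
validate_config <- function(cfg) {
  stopifnot(inherits(cfg, "uterus_config"))
  n <- cfg$rows * cfg$columns
  if (is.na(n) || cfg$rows < 1L || cfg$columns < 1L || n > 64L)
    stop("validate_config: rows x columns must be between 1 and 64 regions (got ",
         n, ")", call. = FALSE)
  if (cfg$timesteps < 1L)
    stop("validate_config: 'timesteps' must be >= 1", call. = FALSE)
  if (cfg$burst_duration < 1L)
    stop("validate_config: 'burst_duration' must be >= 1", call. = FALSE)
  if (cfg$refractory_duration < 0L)
    stop("validate_config: 'refractory_duration' must be >= 0", call. = FALSE)
  if (cfg$initial_pressure < 0 || cfg$min_pressure < 0)
    stop("validate_config: pressures must be non-negative", call. = FALSE)
  if (cfg$ap_multiplier <= 1)
    stop("validate_config: 'ap_multiplier' must be > 1", call. = FALSE)
  if (cfg$refractory_multiplier <= 0 || cfg$refractory_multiplier >= 1)
    stop("validate_config: 'refractory_multiplier' must be in (0, 1)", call. = FALSE)
  if (cfg$activity_cap <= cfg$min_pressure)
    stop("validate_config: 'activity_cap' must exceed 'min_pressure'", call. = FALSE)
  stopifnot(inherits(cfg$anatomy_weibull, "weibull_spec"),
            inherits(cfg$threshold_weibull, "weibull_spec"))
  if (cfg$min_pressure < 0.25 || cfg$min_pressure > 0.75) {
    warning(warningCondition(
      sprintf(paste0("min_pressure = %g is far from the physiologically ",
                     "reasonable baseline (~0.5 on the 0..%g activity scale); ",
                     "results may not be classifiable"),
              cfg$min_pressure, cfg$activity_cap),
      class = "uterosim_plausibility"))
  }
  invisible(cfg)
}

#' @export
print.uterus_config <- function(x, ...) {
  cat("<uterus_config>\n")
  cat(sprintf("  grid          : %d x %d (%d regions), %d steps\n",
              x$rows, x$columns, x$rows * x$columns, x$timesteps))
  cat(sprintf("  pressures     : start %g, floor %g, activity cap %g\n",
              x$initial_pressure, x$min_pressure, x$activity_cap))
  cat(sprintf("  burst         : %d steps x%g; refractory %d steps x%g\n",
              x$burst_duration, x$ap_multiplier,
              x$refractory_duration, x$refractory_multiplier))
  cat(sprintf("  anatomy       : Weibull %s, seed %d\n",
              format(x$anatomy_weibull), x$anatomy_seed))
  cat(sprintf("  threshold     : Weibull %s, seed %d\n",
              format(x$threshold_weibull), x$threshold_seed))
  cat(sprintf("  descriptor    : %s\n", format_descriptor(x)))
  invisible(x)
}

# ---- descriptor grammar ------------------------------------------------------

#' Parse a run-descriptor string into a configuration
#'
#' Accepts the compact descriptor format
#' `"<head>.S<aaaa>:<w1>/<w2>/<w3>;S<bbbb>:<w4>/<w5>/<w6>"` (whitespace around
#' `.`, `:`, `;`, `/` is ignored). `head` is either a preset number (short
#' form, e.g. `"1.S1000:1.8/1/0.3; S2000:4/0.6/0.4"`) or all nine scalar
#' inputs slash-separated in the order rows/columns/timesteps/initial
#' pressure/minimum pressure/burst duration/refractory duration/AP
#' multiplier/refractory multiplier (long form). The two `S` fields carry the
#' anatomy and threshold seeds (conventionally 1000-1999 and 2000-2999; values
#' outside those ranges are accepted with a warning since the ranges are a
#' bookkeeping convention, not physiology), and the six numbers are the two
#' Weibull parameter triples (shape/scale/location).
#'
#' @param text the descriptor string.
#' @param base optional `uterus_input_set` (or `uterus_config`) supplying the
#'   nine scalar fields when the short form is used; defaults to the preset
#'   named in the head. Required grid fields for preset 14 may come from here.
#' @return A validated `uterus_config`.
#' @examples
#' parse_descriptor("1.S1000:1.8/1/0.3; S2000:4/0.6/0.4")
#' parse_descriptor("4/4/300/0.5/0.7/8/24/3/0.2.S1246:1.8/0.6/0.55;S2648:4/0.8/0.1")
#' @export
parse_descriptor <- function(text, base = NULL) {
  stopifnot(is.character(text), length(text) == 1L)
  s <- gsub("[[:space:]]+", "", text)
  m <- regexpr("\\.S[0-9]", s)
  if (m < 0)
    stop("parse_descriptor: malformed descriptor; expected '.S<seed>:' after the ",
         "input-set head in ", sQuote(text), call. = FALSE)
  head <- substr(s, 1L, m - 1L)
  rest <- substr(s, m + 1L, nchar(s))
  rx <- "^S([0-9]+):([^:;]+);S([0-9]+):([^:;]+)$"
  mm <- regmatches(rest, regexec(rx, rest))[[1]]
  if (length(mm) != 5L)
    stop("parse_descriptor: malformed seed/Weibull blocks in ", sQuote(rest),
         "; expected 'S<seed>:<shape>/<scale>/<location>;S<seed>:<shape>/<scale>/<location>'",
         call. = FALSE)
  anatomy_seed <- as.integer(mm[2]); threshold_seed <- as.integer(mm[4])
  if (anatomy_seed < 1000L || anatomy_seed > 1999L)
    warning("parse_descriptor: anatomy seed ", anatomy_seed,
            " is outside the conventional 1000-1999 range", call. = FALSE)
  if (threshold_seed < 2000L || threshold_seed > 2999L)
    warning("parse_descriptor: threshold seed ", threshold_seed,
            " is outside the conventional 2000-2999 range", call. = FALSE)
  w1 <- .parse_triple(mm[3], "anatomy Weibull")
  w2 <- .parse_triple(mm[5], "threshold Weibull")

  scalars <- .parse_head(head, base)
  do.call(uterus_config, c(scalars, list(
    anatomy_weibull = weibull_spec(w1[1], w1[2], w1[3]),
    threshold_weibull = weibull_spec(w2[1], w2[2], w2[3]),
    anatomy_seed = anatomy_seed, threshold_seed = threshold_seed)))
}

.parse_triple <- function(txt, what) {
  parts <- strsplit(txt, "/", fixed = TRUE)[[1]]
  vals <- suppressWarnings(as.numeric(parts))
  if (length(vals) != 3L || anyNA(vals))
    stop("parse_descriptor: ", what, " block ", sQuote(txt),
         " is not three numbers separated by '/'", call. = FALSE)
  vals
}

.parse_head <- function(head, base) {
  if (nzchar(head) && !grepl("/", head, fixed = TRUE)) {
    x <- suppressWarnings(as.numeric(head))
    if (is.na(x))
      stop("parse_descriptor: input-set head ", sQuote(head),
           " is neither a preset number nor nine slash-separated values",
           call. = FALSE)
    ps <- if (is.null(base)) preset_input_set(x) else base
    out <- ps[.scalar_fields]
    if (is.na(out$rows) || is.na(out$columns))
      stop("parse_descriptor: preset ", x, " has a symbolic grid; supply a ",
           "'base' with explicit rows and columns", call. = FALSE)
    return(out)
  }
  parts <- strsplit(head, "/", fixed = TRUE)[[1]]
  vals <- suppressWarnings(as.numeric(parts))
  if (length(vals) != 9L || anyNA(vals))
    stop("parse_descriptor: long-form head ", sQuote(head),
         " must contain nine slash-separated numbers", call. = FALSE)
  stats::setNames(as.list(vals), .scalar_fields)
}

#' Serialize a configuration as a descriptor string
#'
#' Inverse of [parse_descriptor()]: emits the short form when the nine scalar
#' fields match a preset exactly, otherwise the explicit nine-value long form.
#'
#' @param cfg a `uterus_config`.
#' @return A descriptor string; `parse_descriptor(format_descriptor(cfg))`
#'   reproduces `cfg`.
#' @export
format_descriptor <- function(cfg) {
  stopifnot(inherits(cfg, "uterus_config"))
  head <- NULL
  for (ps in .preset_table) {
    vals <- stats::setNames(ps, c("set_number", .scalar_fields))
    if (!is.na(vals$rows) &&
        all(vapply(.scalar_fields,
                   function(f) isTRUE(all.equal(as.numeric(vals[[f]]),
                                                as.numeric(cfg[[f]]))),
                   logical(1)))) {
      head <- as.character(vals$set_number)
      break
    }
  }
  if (is.null(head))
    head <- paste(vapply(.scalar_fields,
                         function(f) format(as.numeric(cfg[[f]]),
                                            drop0trailing = TRUE),
                         character(1)),
                  collapse = "/")
  sprintf("%s.S%d:%s;S%d:%s", head,
          cfg$anatomy_seed, format(cfg$anatomy_weibull),
          cfg$threshold_seed, format(cfg$threshold_weibull))
}

# ---- config file I/O ---------------------------------------------------------

#' Read or write a configuration as a flat YAML document
#'
#' The file mirrors the program variable names of the input roster:
#' `rows, columns, timesteps, initialpressure, minpressure, timeburst,
#' timerefractory, burstmultiplier, refractorymultiplier, weibullvar1..6`,
#' plus `anatomyseed`, `thresholdseed` and `activitycap`.
#'
#' @param cfg a `uterus_config`.
#' @param path file path.
#' @return `read_config` returns a validated `uterus_config`; `write_config`
#'   returns `path` invisibly.
#' @export
write_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "uterus_config"))
  doc <- list(
    rows = cfg$rows, columns = cfg$columns, timesteps = cfg$timesteps,
    initialpressure = cfg$initial_pressure, minpressure = cfg$min_pressure,
    timeburst = cfg$burst_duration, timerefractory = cfg$refractory_duration,
    burstmultiplier = cfg$ap_multiplier,
    refractorymultiplier = cfg$refractory_multiplier,
    weibullvar1 = cfg$anatomy_weibull$shape,
    weibullvar2 = cfg$anatomy_weibull$scale,
    weibullvar3 = cfg$anatomy_weibull$location,
    weibullvar4 = cfg$threshold_weibull$shape,
    weibullvar5 = cfg$threshold_weibull$scale,
    weibullvar6 = cfg$threshold_weibull$location,
    anatomyseed = cfg$anatomy_seed, thresholdseed = cfg$threshold_seed,
    activitycap = cfg$activity_cap)
  yaml::write_yaml(doc, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  doc <- yaml::read_yaml(path)
  need <- c("rows", "columns", "timesteps", "initialpressure", "minpressure",
            "timeburst", "timerefractory", "burstmultiplier",
            "refractorymultiplier", paste0("weibullvar", 1:6))
  missing <- setdiff(need, names(doc))
  if (length(missing))
    stop("read_config: missing fields: ", paste(missing, collapse = ", "),
         call. = FALSE)
  uterus_config(
    rows = doc$rows, columns = doc$columns, timesteps = doc$timesteps,
    initial_pressure = doc$initialpressure, min_pressure = doc$minpressure,
    burst_duration = doc$timeburst, refractory_duration = doc$timerefractory,
    ap_multiplier = doc$burstmultiplier,
    refractory_multiplier = doc$refractorymultiplier,
    anatomy_weibull = weibull_spec(doc$weibullvar1, doc$weibullvar2,
                                   doc$weibullvar3),
    threshold_weibull = weibull_spec(doc$weibullvar4, doc$weibullvar5,
                                     doc$weibullvar6),
    anatomy_seed = doc$anatomyseed %||% 1000,
    threshold_seed = doc$thresholdseed %||% 2000,
    activity_cap = doc$activitycap %||% 10)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
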