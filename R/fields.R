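#' Construct per-region heterogeneity fields from explicit matrices
#'
#' A `region_fields` object pairs the two per-region matrices the automaton
#' needs: the anatomy sensitivity (the Law-of-Laplace r/w factor converting
#' organ pressure to regional passive tension) and the action-potential
#' threshold (the tension above which a region bursts). Both are held constant
#' for the duration of a run. Use this constructor to inject explicit
#' matrices, e.g. the printed bench-top fixtures; use [build_fields()] to
#' sample them from a configuration's Weibull specs.
#'
#' @param anatomy numeric matrix of positive anatomy-sensitivity factors.
#' @param threshold numeric matrix of positive action-potential thresholds,
#'   same shape as `anatomy`.
#' @param provenance free-form list recording where the matrices came from.
#' @return An object of class `region_fields`.
#' @examples
#' region_fields(matrix(1), matrix(0.558))   # single isometric strip
#' @export
region_fields <- function(anatomy, threshold,
                          provenance = list(source = "explicit")) {
  anatomy <- as.matrix(anatomy); threshold <- as.matrix(threshold)
  if (!all(dim(anatomy) == dim(threshold)))
    stop("region_fields: 'anatomy' and 'threshold' must have the same shape",
         call. = FALSE)
  if (any(!is.finite(anatomy)) || any(anatomy <= 0))
    stop("region_fields: anatomy sensitivities must be positive and finite",
         call. = FALSE)
  if (any(!is.finite(threshold)) || any(threshold <= 0))
    stop("region_fields: thresholds must be positive and finite", call. = FALSE)
  structure(list(anatomy = anatomy, threshold = threshold,
                 provenance = provenance),
            class = "region_fields")
}

#' @export
print.region_fields <- function(x, ...) {
  cat(sprintf("<region_fields> %d x %d regions (%s)\n",
              nrow(x$anatomy), ncol(x$anatomy),
              x$provenance$source %||% "unknown"))
  cat(sprintf("  anatomy   in [%.3f, %.3f]\n", min(x$anatomy), max(x$anatomy)))
  cat(sprintf("  threshold in [%.3f, %.3f]\n", min(x$threshold), max(x$threshold)))
  invisible(x)
}

#' Sample the heterogeneity fields prescribed by a configuration
#'
#' Draws the anatomy matrix from `(anatomy_weibull, anatomy_seed)` and the
#' threshold matrix from `(threshold_weibull, threshold_seed)` via
#' [sample_weibull_matrix()]. The two streams are independent, and the result
#' is a deterministic function of the configuration.
#'
#' @param cfg a validated `uterus_config`.
#' @return A `region_fields` whose provenance records both seeds and specs.
#' @examples
#' f <- build_fields(preset_config(1))
#' all(f$anatomy >= 0.3) && all(f$threshold >= 0.4)
#' @export
build_fields <- function(cfg) {
  stopifnot(inherits(cfg, "uterus_config"))
  region_fields(
    anatomy = sample_weibull_matrix(cfg$anatomy_weibull, cfg$rows, cfg$columns,
                                    cfg$anatomy_seed),
    threshold = sample_weibull_matrix(cfg$threshold_weibull, cfg$rows,
                                      cfg$columns, cfg$threshold_seed),
    provenance = list(source = "weibull",
                      anatomy_seed = cfg$anatomy_seed,
                      threshold_seed = cfg$threshold_seed,
                      anatomy_weibull = unclass(cfg$anatomy_weibull),
                      threshold_weibull = unclass(cfg$threshold_weibull)))
}

#' Total sensitivity of each region
#'
#' Elementwise anatomy sensitivity divided by action-potential threshold: a
#' region is more likely to fire the larger its anatomy factor and the lower
#' its threshold. The region with the largest total sensitivity is the model's
#' nominal pacemaker.
#'
#' @param fields a `region_fields`.
#' @return A numeric matrix of anatomy/threshold ratios.
#' @examples
#' total_sensitivity(region_fields(matrix(0.991), matrix(0.558)))  # 1.776
#' @export
total_sensitivity <- function(fields) {
  stopifnot(inherits(fields, "region_fields"))
  fields$anatomy / fields$threshold
}

#' Mean total sensitivity of a fields sample
#'
#' Arithmetic mean of [total_sensitivity()] over all regions; used in
#' region-count sweeps to check that force changes are not explained by
#' sampling drift of the fields.
#'
#' @param fields a `region_fields`.
#' @return A positive scalar.
#' @export
mean_total_sensitivity <- function(fields) {
  mean(total_sensitivity(fields))
}

#' Read or write field matrices as CSV fixtures
#'
#' One plain CSV per matrix, one line per grid row, no header: the fixture
#' format accepted by the CLI's `--anatomy-file`/`--threshold-file`.
#'
#' @param anatomy_path,threshold_path CSV file paths.
#' @return `read_fields_csv` returns a `region_fields`; `write_fields_csv`
#'   returns the paths invisibly.
#' @export
read_fields_csv <- function(anatomy_path, threshold_path) {
  a <- as.matrix(utils::read.csv(anatomy_path, header = FALSE))
  th <- as.matrix(utils::read.csv(threshold_path, header = FALSE))
  dimnames(a) <- dimnames(th) <- NULL
  region_fields(a, th, provenance = list(source = "csv",
                                         anatomy = anatomy_path,
                                         threshold = threshold_path))
}

#' @rdname read_fields_csv
#' @param fields a `region_fields` to serialize.
#' @export
write_fields_csv <- function(fields, anatomy_path, threshold_path) {
  stopifnot(inherits(fields, "region_fields"))
  utils::write.table(fields$anatomy, anatomy_path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  utils::write.table(fields$threshold, threshold_path, sep = ",",
                     row.names = FALSE, col.names = FALSE)
  invisible(c(anatomy_path, threshold_path))
}

#' Bench-top fixtures with the published strip values
#'
#' `single_strip_fields()` is the isolated-strip analog: anatomy sensitivity
#' 0.991 (isometric conditions make it ~1) and threshold 0.558.
#' `two_strip_fields()` is the paired, mechanically linked strip analog: a
#' 1x2 grid with anatomy sensitivities 0.986/0.989 and thresholds 0.428/0.670,
#' the baseline pressure of the paired presets (0.5) falling between the two
#' thresholds. These are synthetic stand-ins for the original seed-specific
#' draws, which belong to a different RNG and are not reproducible here.
#'
#' @return A `region_fields`.
#' @export
single_strip_fields <- function() {
  region_fields(matrix(0.991), matrix(0.558),
                provenance = list(source = "synthetic single-strip fixture"))
}

#' @rdname single_strip_fields
#' @export
two_strip_fields <- function() {
  region_fields(matrix(c(0.986, 0.989), nrow = 1),
                matrix(c(0.428, 0.670), nrow = 1),
                provenance = list(source = "synthetic two-strip fixture"))
}
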