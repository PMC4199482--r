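# Shared fixtures and an independent scalar reference implementation.

# Canonical single-strip bench-top configuration: anatomy exactly 1 (true
# isometric conditions), threshold 0.558, baseline above threshold.
canonical_config <- function(min_pressure = 0.6, timesteps = 300) {
  uterus_config(rows = 1, columns = 1, timesteps = timesteps,
                initial_pressure = 1, min_pressure = min_pressure,
                burst_duration = 10, refractory_duration = 20,
                ap_multiplier = 3, refractory_multiplier = 0.2)
}

unit_strip_fields <- function(threshold = 0.558) {
  region_fields(matrix(1), matrix(threshold),
                provenance = list(source = "test fixture"))
}

# Naive scalar reference engine: same three rules written as an unvectorized
# per-region loop with explicit state, used to cross-check the array
# implementation on small grids.
naive_run <- function(cfg, fields) {
  a <- as.vector(t(fields$anatomy))      # row-major region order
  th <- as.vector(t(fields$threshold))
  n <- length(a)
  act <- pmin(pmax(cfg$initial_pressure * a, 0), cfg$activity_cap)
  p <- max(cfg$min_pressure, mean(act / a))
  phase <- rep(0L, n); age <- rep(0L, n)
  trace <- numeric(cfg$timesteps + 1); trace[1] <- p
  for (t in seq_len(cfg$timesteps)) {
    passive <- p * a
    for (k in seq_len(n)) {
      if (phase[k] == 0L) {
        if (passive[k] > th[k]) { phase[k] <- 1L; age[k] <- 1L }
        else age[k] <- age[k] + 1L
      } else if (phase[k] == 1L) {
        if (age[k] + 1L > cfg$burst_duration ||
            passive[k] * cfg$ap_multiplier < th[k]) {
          phase[k] <- 2L; age[k] <- 1L
        } else age[k] <- age[k] + 1L
      } else {
        if (age[k] + 1L > cfg$refractory_duration) {
          phase[k] <- 0L; age[k] <- 0L
        } else age[k] <- age[k] + 1L
      }
    }
    fac <- ifelse(phase == 1L, cfg$ap_multiplier,
                  ifelse(phase == 2L, cfg$refractory_multiplier, 1))
    act <- pmin(pmax(passive * fac, 0), cfg$activity_cap)
    p <- max(cfg$min_pressure, mean(act / a))
    trace[t + 1] <- p
  }
  trace
}

# Count of detected events whose peak reaches organ-level pressure.
n_organ_events <- function(run, level = 5) {
  ev <- detect_contractions(run$pressure_trace, floor = run$config$min_pressure)
  sum(ev$peak_pressure >= level)
}
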