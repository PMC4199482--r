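test_that("initial state seeds activities from the starting pressure", {
  cfg <- preset_config(1)
  f <- build_fields(cfg)
  s <- initial_state(cfg, f)
  expect_equal(s$activity, 0.5 * f$anatomy)
  expect_equal(s$pressure, 0.5)
  expect_true(all(s$phase == PHASE_QUIESCENT) && all(s$age == 0L))

  # bench-top strip: starting pressure above the floor
  s2 <- initial_state(canonical_config(), single_strip_fields())
  expect_equal(s2$activity[1, 1], 0.991)
  expect_equal(s2$pressure, 1)

  # zero starting pressure engages the floor
  cfg0 <- preset_config(1, initial_pressure = 0)
  expect_equal(initial_state(cfg0, f)$pressure, 0.5)

  expect_error(initial_state(cfg, single_strip_fields()), "shape")
})

test_that("pressure inverts the Laplace conversion and floors at baseline", {
  cfg <- uterus_config(1, 2)
  f <- region_fields(matrix(c(1, 1), 1), matrix(c(1, 1), 1))
  expect_equal(compute_pressure(matrix(c(3, 0), 1), f, cfg), 1.5)
  expect_equal(compute_pressure(matrix(c(0, 0), 1), f, cfg), 0.5)
  # exact algebraic round trip p -> activities -> p for any p >= floor
  cfg4 <- preset_config(1)
  f4 <- build_fields(cfg4)
  for (p in c(0.5, 1.3, 7)) {
    expect_equal(compute_pressure(p * f4$anatomy, f4, cfg4), p)
  }
})

test_that("phase machine ignites, persists and recovers per the rules", {
  cfg <- canonical_config()
  f <- region_fields(matrix(0.991), matrix(0.558))
  st <- initial_state(cfg, f)

  # passive 0.6 * 0.991 = 0.5946 > 0.558: a quiescent strip ignites
  up <- update_phases(st, matrix(0.6 * 0.991), cfg, f)
  expect_equal(up$phase[1, 1], PHASE_BURSTING)
  expect_equal(up$age[1, 1], 1L)

  # passive 0.55 * 0.991 = 0.5451 < 0.558: stays quiescent
  up2 <- update_phases(st, matrix(0.55 * 0.991), cfg, f)
  expect_equal(up2$phase[1, 1], PHASE_QUIESCENT)

  # exact equality does not ignite (strict comparison)
  up3 <- update_phases(st, matrix(0.558), cfg, f)
  expect_equal(up3$phase[1, 1], PHASE_QUIESCENT)

  # a burst at its duration cap goes refractory regardless of tension
  st$phase[1, 1] <- PHASE_BURSTING; st$age[1, 1] <- cfg$burst_duration
  up4 <- update_phases(st, matrix(100), cfg, f)
  expect_equal(up4$phase[1, 1], PHASE_REFRACTORY)
  expect_equal(up4$age[1, 1], 1L)
})

test_that("single steps match hand-evaluated rule applications", {
  cfg <- canonical_config()
  f <- unit_strip_fields()
  st <- initial_state(cfg, f)   # p = 1, quiescent
  st1 <- step_state(st, cfg, f)
  expect_equal(st1$activity[1, 1], 3)   # passive 1 > 0.558, x3
  expect_equal(st1$pressure, 3)

  # burst at the cap: next step is refractory, activity 10 * 0.2
  st$phase[1, 1] <- PHASE_BURSTING; st$age[1, 1] <- cfg$burst_duration
  st$pressure <- 10
  st2 <- step_state(st, cfg, f)
  expect_equal(st2$phase[1, 1], PHASE_REFRACTORY)
  expect_equal(st2$activity[1, 1], 2)
  expect_equal(st2$pressure, 2)
})

test_that("canonical strip run reproduces the hand-simulated trace", {
  run <- run_simulation(canonical_config(), unit_strip_fields())
  act <- run$activity_tensor[, 1, 1]
  expect_equal(act[1:4], c(1, 3, 9, 10))
  expect_equal(max(run$pressure_trace), 10)

  onsets <- which(diff(c(FALSE, run$phase_tensor[, 1, 1] == PHASE_BURSTING)) == 1) - 1
  # onset-to-onset period = burst + refractory + one quiescent step
  expect_true(all(diff(onsets) == 31))
  ev <- detect_contractions(run$pressure_trace, floor = 0.6)
  expect_gte(nrow(ev), 9)
  expect_equal(unique(ev$peak_pressure), 10)
  expect_true(all(diff(ev$onset_step) == 31))
})

test_that("baseline below threshold yields one initial contraction then rest", {
  run <- run_simulation(canonical_config(min_pressure = 0.55),
                        unit_strip_fields())
  tr <- run$pressure_trace
  expect_equal(max(tr), 10)                        # the initial transient
  expect_true(all(abs(tail(tr, 250) - 0.55) < 1e-12))
  expect_equal(nrow(detect_contractions(tr, floor = 0.55)), 0)
  # only one burst ever ignites
  onsets <- sum(diff(run$phase_tensor[, 1, 1] == PHASE_BURSTING) == 1)
  expect_equal(onsets, 1)
})

test_that("minimum pressure separates repetitive from silent strip behavior", {
  # the two bench-top presets with the printed strip fixture
  rep_run <- run_simulation(preset_config(9), single_strip_fields())
  sil_run <- run_simulation(preset_config(10), single_strip_fields())
  expect_gte(nrow(detect_contractions(rep_run$pressure_trace, floor = 0.6)), 9)
  expect_equal(nrow(detect_contractions(sil_run$pressure_trace, floor = 0.55)), 0)
})

test_that("trace invariants hold across random configurations", {
  for (s in 1:5) {
    cfg <- preset_config(1, anatomy_seed = 1000 + s, threshold_seed = 2000 + s)
    run <- run_simulation(cfg)
    f <- run$fields
    nt <- cfg$timesteps + 1

    # Rule-1 round trip at every recorded step
    recomputed <- vapply(seq_len(nt), function(i)
      compute_pressure(run$activity_tensor[i, , ], f, cfg), numeric(1))
    expect_equal(run$pressure_trace, recomputed)

    # bounds
    expect_true(all(run$pressure_trace >= cfg$min_pressure))
    expect_true(all(run$pressure_trace <=
                    cfg$activity_cap * mean(1 / f$anatomy) + 1e-12))
    expect_true(all(run$activity_tensor >= 0 &
                    run$activity_tensor <= cfg$activity_cap))

    # phase legality and duration caps per region
    for (i in seq_len(cfg$rows)) for (j in seq_len(cfg$columns)) {
      ph <- run$phase_tensor[, i, j]
      tr <- cbind(ph[-nt], ph[-1])
      tr <- tr[tr[, 1] != tr[, 2], , drop = FALSE]
      legal <- rbind(c(PHASE_QUIESCENT, PHASE_BURSTING),
                     c(PHASE_BURSTING, PHASE_REFRACTORY),
                     c(PHASE_REFRACTORY, PHASE_QUIESCENT))
      ok <- apply(tr, 1, function(x)
        any(x[1] == legal[, 1] & x[2] == legal[, 2]))
      expect_true(all(ok))
      r <- rle(ph)
      expect_true(all(r$lengths[r$values == PHASE_BURSTING] <=
                      cfg$burst_duration))
      # completed refractory periods have exactly the configured length
      rf <- which(r$values == PHASE_REFRACTORY)
      rf <- rf[rf < length(r$values)]
      expect_true(all(r$lengths[rf] == cfg$refractory_duration))
    }
  }
})

test_that("a fully subthreshold start is a fixed point", {
  cfg <- preset_config(1)
  f <- build_fields(cfg)
  # thresholds strictly above any achievable passive tension at the floor
  quiet <- region_fields(f$anatomy,
                         pmax(cfg$min_pressure, cfg$initial_pressure) *
                           f$anatomy + 0.01)
  run <- run_simulation(cfg, quiet)
  expect_true(all(abs(run$pressure_trace - 0.5) < 1e-12))
  expect_true(all(run$phase_tensor == PHASE_QUIESCENT))
})

test_that("runs are bit-deterministic and match a scalar reference engine", {
  cfg <- preset_config(8, anatomy_seed = 1474, threshold_seed = 2500)
  expect_identical(run_simulation(cfg), run_simulation(cfg))

  for (k in c(9, 11, 1)) {
    cfg <- suppressWarnings(preset_config(k, timesteps = 120))
    f <- build_fields(cfg)
    run <- run_simulation(cfg, f)
    expect_equal(run$pressure_trace, naive_run(cfg, f))
  }
})

test_that("export_run writes consistent plain-text artifacts", {
  run <- run_simulation(preset_config(9, timesteps = 50), single_strip_fields())
  dir <- tempfile()
  export_run(run, dir)
  pr <- utils::read.csv(file.path(dir, "pressure.csv"))
  expect_equal(pr$pressure, run$pressure_trace)
  act <- utils::read.csv(file.path(dir, "activity.csv"))
  expect_equal(nrow(act), 51)
  meta <- jsonlite::read_json(file.path(dir, "run.json"))
  # timesteps differ from the preset, so the long form is emitted
  expect_match(meta$descriptor, "^1/1/50/.*\\.S1000:")
  expect_equal(meta$config$min_pressure, 0.6)
})
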