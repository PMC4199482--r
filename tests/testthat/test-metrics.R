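test_that("the detector finds isolated pulses and ignores flat traces", {
  flat <- rep(0.5, 301)
  expect_equal(nrow(detect_contractions(flat, floor = 0.5)), 0)

  pulse <- rep(0.5, 301); pulse[101:110] <- 10
  ev <- detect_contractions(pulse, floor = 0.5)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$peak_pressure, 10)
  expect_equal(ev$onset_step, 100)   # steps are 0-based
  expect_equal(ev$offset_step, 109)

  # a pulse entirely inside the transient window is not an event
  early <- rep(0.5, 301); early[2:12] <- 10
  expect_equal(nrow(detect_contractions(early, floor = 0.5)), 0)

  expect_error(detect_contractions(rep(1, 10)), "transient")
})

test_that("event counts are invariant under uniform trace rescaling", {
  run <- run_simulation(preset_config(9), single_strip_fields())
  tr <- run$pressure_trace
  ev <- detect_contractions(tr, floor = 0.6)
  ev2 <- detect_contractions(tr * 3, floor = 1.8)
  expect_equal(nrow(ev), nrow(ev2))
  expect_equal(ev$onset_step, ev2$onset_step)
  expect_equal(3 * ev$peak_pressure, ev2$peak_pressure)
})

test_that("pseudo-Montevideo units scale with peaks and count", {
  expect_equal(pseudo_montevideo(rep(0.5, 301), floor = 0.5), 0)

  # canonical strip: 9 contractions of peak 10 in 300 steps
  run <- run_simulation(canonical_config(), unit_strip_fields())
  expect_equal(pseudo_montevideo(run$pressure_trace, floor = 0.6), 90)

  # linear in peak force: doubling every peak doubles pMV
  ev <- detect_contractions(run$pressure_trace, floor = 0.6)
  ev2 <- ev; ev2$peak_pressure <- 2 * ev2$peak_pressure
  expect_equal(pseudo_montevideo(run$pressure_trace, events = ev2),
               2 * pseudo_montevideo(run$pressure_trace, events = ev))

  # normalization: half-length trace with the same event density scales up
  half <- run_simulation(canonical_config(timesteps = 150), unit_strip_fields())
  ev_h <- detect_contractions(half$pressure_trace, floor = 0.6)
  expect_equal(pseudo_montevideo(half$pressure_trace, events = ev_h),
               mean(ev_h$peak_pressure) * nrow(ev_h) * 2)

  # pMV is zero exactly when no events are detected
  expect_identical(pseudo_montevideo(rep(0.5, 301), floor = 0.5) == 0,
                   nrow(detect_contractions(rep(0.5, 301), floor = 0.5)) == 0)
})

test_that("pacemaker identification follows the first persistent burst", {
  # single strip: the only region is the pacemaker of every event
  run <- run_simulation(preset_config(9), single_strip_fields())
  pm <- identify_pacemaker(run)
  expect_true(all(pm$per_event$row == 1 & pm$per_event$col == 1))
  expect_equal(pm$dominant, c(1, 1))

  # constructed run where one region ignites first every time: a 2x3 grid
  # with one region far more sensitive than the rest
  anatomy <- matrix(1, 2, 3); threshold <- matrix(10, 2, 3)
  threshold[2, 3] <- 0.45   # only this region can self-ignite at the floor
  cfg <- uterus_config(2, 3, timesteps = 200, min_pressure = 0.5,
                       initial_pressure = 0.5)
  f <- region_fields(anatomy, threshold)
  run2 <- run_simulation(cfg, f)
  ev2 <- detect_contractions(run2$pressure_trace, floor = 0.5)
  expect_gt(nrow(ev2), 0)
  pm2 <- identify_pacemaker(run2, ev2)
  expect_true(all(pm2$per_event$row == 2 & pm2$per_event$col == 3))
  expect_equal(pm2$dominant, c(2, 3))
})

test_that("midrange grids express shifting pacemakers for some seeds", {
  shifting <- FALSE
  for (s in 0:5) {
    run <- run_simulation(preset_config(8, anatomy_seed = 1474 + s,
                                        threshold_seed = 2500 + s))
    ev <- detect_contractions(run$pressure_trace, floor = 0.5)
    if (nrow(ev) < 3) next
    pm <- identify_pacemaker(run, ev)$per_event
    pm <- pm[!is.na(pm$row), ]
    if (nrow(pm) >= 3 &&
        length(unique(paste(pm$row, pm$col))) > 1) {
      shifting <- TRUE
      break
    }
  }
  expect_true(shifting)
})

test_that("behavior classes separate uniform, repetitive and complex runs", {
  # silent strip (one initial transient, then rest): uniform state
  silent <- run_simulation(canonical_config(min_pressure = 0.55),
                           unit_strip_fields())
  expect_equal(classify_behavior(silent$pressure_trace)$class_id, 1)

  # strictly periodic strip: repetitive state with zero interval CV
  periodic <- run_simulation(canonical_config(), unit_strip_fields())
  cls <- classify_behavior(periodic$pressure_trace, floor = 0.6)
  expect_equal(cls$class_id, 2)
  expect_equal(cls$interval_cv, 0)

  # irregular-interval trace classifies as complex
  irr <- rep(0.5, 301)
  for (on in c(51, 101, 171, 221)) irr[on:(on + 4)] <- 10
  b4 <- classify_behavior(irr, floor = 0.5)
  expect_equal(b4$class_id, 4)
  expect_gte(b4$interval_cv, 0.05)

  # never class 1 when an event exists after the transient
  pulse <- rep(0.5, 301); pulse[101:110] <- 10
  expect_false(classify_behavior(pulse, floor = 0.5)$class_id == 1)
  # too few events without a flat trace: fallback bucket
  expect_equal(classify_behavior(pulse, floor = 0.5)$class_id, 3)

  expect_error(classify_behavior(rep(1, 5)), "transient")
})

test_that("the default parameterization yields complex traces for some seeds", {
  classes <- vapply(0:5, function(s) {
    run <- run_simulation(preset_config(1, anatomy_seed = 1000 + s,
                                        threshold_seed = 2000 + s))
    classify_behavior(run$pressure_trace, floor = 0.5)$class_id
  }, numeric(1))
  expect_true(any(classes == 4))
})

test_that("metrics_report bundles a consistent summary", {
  run <- run_simulation(preset_config(1))
  m <- metrics_report(run)
  expect_s3_class(m, "uterus_metrics")
  expect_equal(m$peak_pressure, max(run$pressure_trace))
  expect_equal(m$pmv,
               pseudo_montevideo(run$pressure_trace, events = m$events))
  expect_equal(m$mean_total_sensitivity, mean_total_sensitivity(run$fields))
  expect_equal(nrow(m$pacemaker_per_event), nrow(m$events))

  path <- tempfile(fileext = ".json")
  csv <- tempfile(fileext = ".csv")
  write_metrics_json(m, path, events_csv = csv)
  doc <- jsonlite::read_json(path)
  expect_equal(doc$pMV, m$pmv)
  expect_equal(doc$behavior_class, m$behavior$class_id)
  expect_equal(nrow(utils::read.csv(csv)), nrow(m$events))
})
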