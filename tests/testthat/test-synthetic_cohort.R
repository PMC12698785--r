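test_that("generators are pure functions of config and seed", {
  cfg <- cohort_config(n_participants = 4, seed = 13)
  expect_identical(generate_cohort(cfg), generate_cohort(cfg))

  a <- generate_cohort(cfg)[[1]]
  t1 <- generate_gait_trial(a, 0.4, cfg, seed = 5)
  t2 <- generate_gait_trial(a, 0.4, cfg, seed = 5)
  expect_identical(t1$xy, t2$xy)

  g1 <- generate_metabolic_data(4, 0.5, 77, cfg, seed = 9)
  g2 <- generate_metabolic_data(4, 0.5, 77, cfg, seed = 9)
  expect_identical(g1$walk, g2$walk)
  expect_identical(g1$rest, g2$rest)
})

test_that("cohort anthropometrics follow the configured distributions", {
  cfg <- cohort_config(n_participants = 9, seed = 11)
  cohort <- generate_cohort(cfg)
  masses <- vapply(cohort, `[[`, numeric(1), "mass")
  statures <- vapply(cohort, `[[`, numeric(1), "stature")
  # sample mean within 3 standard errors of the target
  expect_lt(abs(mean(masses) - 77.1), 3 * 9.8 / sqrt(9))
  expect_lt(abs(mean(statures) - 1.78), 3 * 0.04 / sqrt(9))
  # truncation bound
  expect_true(all(abs(masses - 77.1) <= 3 * 9.8))
  # every anthropometry is valid by construction
  for (a in cohort) expect_s3_class(a, "anthropometry")

  expect_error(cohort_config(n_participants = 0), "n_participants")
})

test_that("noiseless trials reproduce the requested gait", {
  cfg <- noiseless_config()
  a <- generate_cohort(cfg)[[1]]
  for (v in c(0.2, 0.8)) {
    tr <- generate_gait_trial(a, v, cfg, seed = 31)
    st <- detect_strides(filter_markers(tr))
    interior <- st[2:(nrow(st) - 1), ]
    expect_equal(mean(interior$v), v, tolerance = 0.02)
    expect_equal(mean(interior$SL), attr(tr, "truth")$SL, tolerance = 0.02)
  }
  expect_error(generate_gait_trial(a, -1, cfg, seed = 1), "positive")
})

test_that("doubling speed at fixed waveform quadruples drag", {
  # fixed stride length: doubling cadence doubles every velocity
  cfg <- noiseless_config(sl_intercept = 0.8, sl_slope = 0)
  a <- generate_cohort(cfg)[[1]]
  model <- build_segment_model(a)
  strips <- discretize_model(model, 20)
  water <- water_properties(surface_height = 1.12)
  drf <- vapply(c(0.3, 0.6), function(v) {
    tr <- generate_gait_trial(a, v, cfg, seed = 41)
    f <- filter_markers(tr)
    st <- detect_strides(f)
    st_in <- st[2:(nrow(st) - 1), ]
    attributes(st_in)[c("contact", "half_stride_samples")] <-
      attributes(st)[c("contact", "half_stride_samples")]
    mean(stride_drag(segment_states(f), model, strips, st_in, water)$drf)
  }, numeric(1))
  expect_equal(drf[2] / drf[1], 4, tolerance = 0.05)
})

test_that("metabolic generation inverts exactly without noise", {
  cfg <- noiseless_config()
  gas <- generate_metabolic_data(5.2, 0.6, 80, cfg, seed = 3)
  walk_t <- max(gas$walk$time)
  walk <- metabolic_power(gas$walk, 80, window = c(walk_t - 120, walk_t))
  rest <- metabolic_power(gas$rest, 80)
  rec <- measured_cot(walk$power, rest$power, 0.6)
  expect_equal(rec$cot, 5.2, tolerance = 0.01)
  expect_true(walk$rer >= 0.79 && walk$rer <= 0.87)

  expect_error(generate_metabolic_data(0, 0.6, 80, cfg, seed = 3),
               "positive")
})

test_that("noisy metabolic records recover the cohort-mean cost closely", {
  cfg <- cohort_config(n_participants = 9, seed = 2, metabolic_noise_cv = 0.05)
  recovered <- vapply(1:9, function(i) {
    gas <- generate_metabolic_data(6.0, 0.5, 77, cfg, seed = 100 + i)
    walk_t <- max(gas$walk$time)
    walk <- metabolic_power(gas$walk, 77, window = c(walk_t - 120, walk_t))
    rest <- metabolic_power(gas$rest, 77)
    measured_cot(walk$power, rest$power, 0.5)$cot
  }, numeric(1))
  expect_equal(mean(recovered), 6.0, tolerance = 0.05)
})
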