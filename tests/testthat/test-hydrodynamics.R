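test_that("strip drag matches the closed-form cylinder at any discretisation", {
  for (n in c(1, 5, 20, 100)) {
    s <- discretize(0.5, 0.05, 0.05, n)
    total <- sum(strip_drag(0.8, s$local_radius, s$strip_length,
                            immersed_fraction = 1, cd = 1, density = 995.7))
    expect_equal(total, 0.5 * 995.7 * 1 * (0.10 * 0.5) * 0.64,
                 tolerance = 1e-12)
    expect_equal(total, 15.93, tolerance = 1e-3)
  }
  expect_identical(strip_drag(0, 0.05, 0.1), 0)
  expect_identical(strip_drag(0.8, 0.05, 0.1, immersed_fraction = 0), 0)
  expect_error(strip_drag(NaN, 0.05, 0.1), "non-finite")
})

test_that("rigid whole-body translation matches the analytic frustum sum", {
  a <- rigid_posture_anthro()
  model <- build_segment_model(a)
  strips <- discretize_model(model, 20)
  markers <- rigid_translation_markers(speed = 0.5)
  states <- segment_states(markers)
  strides <- manual_strides(length(markers$time))
  water <- water_properties(surface_height = 2.0)  # fully immersed

  drag <- stride_drag(states, model, strips, strides, water)
  segs <- a$segments
  oracle <- 0
  for (seg in c("shank", "thigh", "trunk")) {
    row <- segs[segs$segment == seg, ]
    f1 <- frustum_drag_uniform(row$length,
                               row$proximal_circumference / (2 * pi),
                               row$distal_circumference / (2 * pi),
                               speed = 0.5)
    oracle <- oracle + if (seg == "trunk") f1 else 2 * f1
  }
  # horizontal foot sees no cross-flow from horizontal motion
  expect_equal(drag$drf, oracle, tolerance = 0.005)

  # raised fully above the surface: zero drag
  dry <- water_properties(surface_height = 1e-6)
  expect_equal(stride_drag(states, model, strips, strides, dry)$drf, 0)
})

test_that("drag scales quadratically with velocity", {
  cfg <- noiseless_config()
  a <- generate_cohort(cfg)[[1]]
  model <- build_segment_model(a)
  strips <- discretize_model(model, 20)
  tr <- generate_gait_trial(a, 0.6, cfg, seed = 21)
  f <- filter_markers(tr)
  st <- detect_strides(f)
  states <- segment_states(f)
  water <- water_properties(surface_height = 1.12)

  base <- stride_drag(states, model, strips, st, water)

  scaled <- states
  vel_fields <- c("omega", "vx_prox", "vy_prox", "vx_dist", "vy_dist")
  for (s in names(scaled$segments)) {
    for (fld in vel_fields) {
      scaled$segments[[s]][[fld]] <- 2 * scaled$segments[[s]][[fld]]
    }
  }
  doubled <- stride_drag(scaled, model, strips, st, water)
  expect_equal(doubled$drf, 4 * base$drf, tolerance = 1e-6)
})

test_that("drag never decreases when the water rises, and strips converge", {
  cfg <- noiseless_config()
  a <- generate_cohort(cfg)[[1]]
  model <- build_segment_model(a)
  tr <- generate_gait_trial(a, 0.6, cfg, seed = 22)
  f <- filter_markers(tr)
  st <- detect_strides(f)
  states <- segment_states(f)

  strips20 <- discretize_model(model, 20)
  levels <- c(0.3, 0.5, 0.85, 1.12, 1.3)
  drf <- vapply(levels, function(h) {
    mean(stride_drag(states, model, strips20,
                     st, water_properties(surface_height = h))$drf)
  }, numeric(1))
  expect_true(all(diff(drf) >= -1e-9))

  strips40 <- discretize_model(model, 40)
  d20 <- mean(stride_drag(states, model, strips20, st,
                          water_properties(surface_height = 1.12))$drf)
  d40 <- mean(stride_drag(states, model, strips40, st,
                          water_properties(surface_height = 1.12))$drf)
  expect_lt(abs(d20 - d40) / d20, 0.01)
})

test_that("stride drag combines phases consistently and reports breakdowns", {
  cfg <- noiseless_config()
  a <- generate_cohort(cfg)[[1]]
  model <- build_segment_model(a)
  strips <- discretize_model(model, 20)
  tr <- generate_gait_trial(a, 0.4, cfg, seed = 23)
  f <- filter_markers(tr)
  st <- detect_strides(f)
  states <- segment_states(f)
  water <- water_properties(surface_height = 0.85)
  d <- stride_drag(states, model, strips, st, water)

  expect_true(all(d$drf >= 0))
  # duration-weighted phase combination equals the whole-stride average
  contact <- attr(st, "contact")
  k <- 3
  win <- st$start[k]:(st$end[k] - 1)
  n_c <- sum(contact[win]); n_s <- sum(!contact[win])
  expect_equal(d$drf[k],
               (d$drf_contact[k] * n_c + d$drf_swing[k] * n_s) / (n_c + n_s),
               tolerance = 1e-9)
  expect_named(attr(d, "per_segment"))
  re <- attr(d, "reynolds_range")
  expect_true(re[2] > 1e4)  # turbulent-regime magnitudes
  expect_error(stride_drag(states, model, strips, st[0, ], water), "empty")
})
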