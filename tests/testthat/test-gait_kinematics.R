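test_that("marker ingestion validates columns, time and gaps", {
  cfg <- noiseless_config()
  a <- generate_cohort(cfg)[[1]]
  tr <- generate_gait_trial(a, 0.5, cfg, seed = 3)
  df <- cbind(time = tr$time, tr$xy)

  expect_s3_class(as_marker_set(df), "marker_set")
  expect_equal(as_marker_set(df)$sampling_rate, 60, tolerance = 1e-6)

  expect_error(as_marker_set(df[setdiff(names(df), "calcaneus_y")]),
               "calcaneus_y")

  bad_time <- df; bad_time$time[10] <- bad_time$time[8]
  expect_error(as_marker_set(bad_time), "increasing")

  gap2 <- df; gap2$calcaneus_y[50:51] <- NA
  expect_message(m <- as_marker_set(gap2), "interpolated 2")
  expect_false(anyNA(m$xy$calcaneus_y))

  gap4 <- df; gap4$xiphoid_x[60:63] <- NA
  expect_error(as_marker_set(gap4), "gap longer than 3")
})

test_that("zero-phase Butterworth filter has unit DC gain and strong stopband", {
  x <- rep(2.5, 300)
  expect_equal(lowpass_filter(x, 4.5, 60), x, tolerance = 1e-9)

  t <- seq(0, 5, by = 1 / 60)
  s <- sin(2 * pi * 20 * t)
  y <- lowpass_filter(s, 4.5, 60)
  core <- y[100:200]
  # two passes of a 2nd-order filter at 20 Hz vs 4.5 Hz cutoff: > 90% gone
  expect_lt(max(abs(core)), 0.1)

  expect_error(lowpass_filter(s, 40, 60), "Nyquist")
  expect_error(lowpass_filter(s, 30, 60), "Nyquist")
})

test_that("segment states recover static, rigid and pendular motion", {
  # static vertical shank: malleolus straight below epicondyle
  t <- seq(0, 1, by = 1 / 60)
  base <- data.frame(time = t)
  pos <- list(fifth_metatarsal = c(0.25, 0), calcaneus = c(0, 0),
              lateral_malleolus = c(0, 0.1), femoral_epicondyle = c(0, 0.5),
              greater_trochanter = c(0, 0.9), umbilicus = c(0, 1.1),
              xiphoid = c(0, 1.35))
  for (lm in names(pos)) {
    base[[paste0(lm, "_x")]] <- pos[[lm]][1]
    base[[paste0(lm, "_y")]] <- pos[[lm]][2]
  }
  st <- segment_states(as_marker_set(base))
  expect_equal(st$segments$shank$theta, rep(0, length(t)), tolerance = 1e-12)
  expect_equal(st$segments$shank$omega, rep(0, length(t)), tolerance = 1e-12)

  # rigid translation at 0.5 m/s: all endpoint velocities 0.5, no rotation
  rig <- segment_states(rigid_translation_markers(speed = 0.5))
  for (seg in rig$segments) {
    expect_equal(seg$vx_prox, rep(0.5, length(seg$vx_prox)), tolerance = 1e-9)
    expect_equal(seg$vy_dist, rep(0, length(seg$vy_dist)), tolerance = 1e-9)
    expect_equal(seg$omega, rep(0, length(seg$omega)), tolerance = 1e-9)
  }

  # shank swinging at constant 1 rad/s about the epicondyle
  pend <- base
  th <- 0.3 * 0 + 1 * t - 0.5   # theta(t) = t - 0.5 rad
  pend$lateral_malleolus_x <- 0 + 0.4 * sin(th)
  pend$lateral_malleolus_y <- 0.5 - 0.4 * cos(th)
  ps <- segment_states(as_marker_set(pend))
  interior <- 3:(length(t) - 2)
  expect_equal(ps$segments$shank$omega[interior],
               rep(1, length(interior)), tolerance = 1e-3)

  # coincident landmarks are rejected
  degenerate <- base
  degenerate$lateral_malleolus_x <- degenerate$femoral_epicondyle_x
  degenerate$lateral_malleolus_y <- degenerate$femoral_epicondyle_y
  expect_error(segment_states(as_marker_set(degenerate)), "zero-length")
})

test_that("stride detection recovers the generator's gait", {
  cfg <- noiseless_config()
  a <- generate_cohort(cfg)[[1]]
  tr <- generate_gait_trial(a, 0.6, cfg, seed = 9)
  truth <- attr(tr, "truth")
  st <- detect_strides(filter_markers(tr))

  expect_equal(nrow(st), truth$n_strides, tolerance = 1)
  interior <- st[2:(nrow(st) - 1), ]
  expect_equal(mean(interior$SL), truth$SL, tolerance = 0.02)
  expect_equal(mean(interior$v), truth$speed, tolerance = 0.02)
  # v * duration = SL by construction
  expect_equal(interior$v * interior$duration, interior$SL, tolerance = 1e-9)
  # periodic gait: interior strides have equal length
  expect_lt(diff(range(interior$SL)), 1e-6 + 1e-6 * truth$SL)

  expect_error(detect_strides(rigid_translation_markers(speed = 0)),
               "no strides")
})

test_that("zero-phase filtering commutes with differentiation inside the series", {
  t <- seq(0, 4, by = 1 / 60)
  set.seed(4)
  x <- cumsum(rnorm(length(t), 0, 0.01)) + sin(2 * pi * 1.2 * t)
  dt <- 1 / 60
  cd <- function(v) (c(v[-1], NA) - c(NA, v[-length(v)])) / (2 * dt)
  a <- cd(lowpass_filter(x, 4.5, 60))
  b <- lowpass_filter(cd(x)[2:(length(x) - 1)], 4.5, 60)
  interior <- 40:(length(t) - 40)
  expect_equal(a[interior], b[interior - 1], tolerance = 1e-6)
})
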