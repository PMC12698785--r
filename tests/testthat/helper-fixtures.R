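# shared in-code fixtures for the test suite

# a small adult anthropometry with round numbers
test_anthro <- function() {
  anthropometry(
    "T01", mass = 75, stature = 1.80, leg_length = 0.90,
    segments = data.frame(
      segment = c("foot", "shank", "thigh", "trunk"),
      length = c(0.25, 0.40, 0.40, 0.45),
      proximal_circumference = c(0.25, 0.30, 0.60, 0.90),
      distal_circumference = c(0.25, 0.20, 0.40, 0.80)
    )
  )
}

# standing posture (all leg segments vertical, foot horizontal) translating
# rigidly at `speed` for `duration` seconds; every landmark shares the same
# horizontal velocity, so analytic frustum drag applies exactly
rigid_translation_markers <- function(speed = 0.5, duration = 2, fs = 60) {
  t <- seq(0, duration, by = 1 / fs)
  x0 <- c(fifth_metatarsal = 0.25, calcaneus = 0, lateral_malleolus = 0,
          femoral_epicondyle = 0, greater_trochanter = 0, umbilicus = 0,
          xiphoid = 0)
  y0 <- c(fifth_metatarsal = 0, calcaneus = 0, lateral_malleolus = 0.10,
          femoral_epicondyle = 0.50, greater_trochanter = 0.90,
          umbilicus = 1.10, xiphoid = 1.35)
  df <- data.frame(time = t)
  for (lm in names(x0)) {
    df[[paste0(lm, "_x")]] <- x0[[lm]] + speed * t
    df[[paste0(lm, "_y")]] <- rep(y0[[lm]], length(t))
  }
  as_marker_set(df)
}

# anthropometry whose nominal segment lengths match the rigid posture above
rigid_posture_anthro <- function() {
  anthropometry(
    "R01", mass = 75, stature = 1.80, leg_length = 0.90,
    segments = data.frame(
      segment = c("foot", "shank", "thigh", "trunk"),
      length = c(0.25, 0.40, 0.40, 0.45),
      proximal_circumference = c(0.25, 0.30, 0.50, 0.90),
      distal_circumference = c(0.25, 0.20, 0.35, 0.80)
    )
  )
}

# a hand-built stride table spanning the interior of a series of n frames
manual_strides <- function(n, fs = 60, margin = 10L) {
  start <- margin; end <- n - margin
  out <- data.frame(stride = 1L, start = start, end = end,
                    duration = (end - start) / fs,
                    SL = 1, v = 1, L_sc = 0.4)
  attr(out, "half_stride_samples") <- 0L
  class(out) <- c("stride_metrics", "data.frame")
  out
}

# noiseless single-participant config for deterministic kinematics checks
noiseless_config <- function(...) {
  cohort_config(n_participants = 1L, seed = 101L, marker_noise_sd = 0,
                metabolic_noise_cv = 0, ...)
}
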