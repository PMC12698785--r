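#' Synthetic cohort configuration
#'
#' Defines the simulated study conditions: cohort size and anthropometric
#' distributions (healthy adult men, mass 77.1 +/- 9.8 kg, stature
#' 1.78 +/- 0.04 m), the four immersion depths and four nominal speeds, five
#' analysed strides per condition, marker noise, metabolic noise and the
#' assumed muscle efficiency. All generators are pure functions of
#' `(config, seed)`.
#'
#' @param n_participants Cohort size, default 9.
#' @param seed Integer seed.
#' @param mass_mean,mass_sd Body-mass distribution (kg), truncated at
#'   +/- 3 sd.
#' @param stature_mean,stature_sd Stature distribution (m).
#' @param depths Named immersion depths (m).
#' @param speeds Nominal walking speeds (m/s).
#' @param strides_per_condition Strides analysed per condition, default 5.
#' @param marker_noise_sd Additive Gaussian marker noise (m), default
#'   0.003 — of the order of manual video digitisation error.
#' @param metabolic_noise_cv Multiplicative lognormal noise on breath-wise
#'   gas volumes (coefficient of variation), default 0.05.
#' @param efficiency True muscle efficiency of the forward model,
#'   default 0.25.
#' @param sl_intercept,sl_slope Stride length model `SL = a + b * speed`
#'   (m), defaults 0.5 and 0.5 — slow-walking stride lengths of 0.6-0.9 m
#'   over the tested speed range.
#' @param duty_factor Stance fraction of the stride, default 0.6.
#' @param rest_power Resting gross metabolic power (J/kg/min), default 85.
#' @param rer_range Breath-wise respiratory exchange ratio band, default
#'   `c(0.79, 0.87)` — the span of the per-speed means observed in water
#'   walking.
#' @return A list of class `"cohort_config"`.
#' @export
cohort_config <- function(n_participants = 9L, seed = 1L,
                          mass_mean = 77.1, mass_sd = 9.8,
                          stature_mean = 1.78, stature_sd = 0.04,
                          depths = c(knee = 0.5, hip = 0.85,
                                     umbilicus = 1.12, xiphoid = 1.3),
                          speeds = c(0.2, 0.4, 0.6, 0.8),
                          strides_per_condition = 5L,
                          marker_noise_sd = 0.003,
                          metabolic_noise_cv = 0.05,
                          efficiency = 0.25,
                          sl_intercept = 0.5, sl_slope = 0.5,
                          duty_factor = 0.6,
                          rest_power = 85, rer_range = c(0.79, 0.87)) {
  if (n_participants < 1) stop("n_participants must be >= 1", call. = FALSE)
  stopifnot(mass_sd >= 0, stature_sd >= 0, marker_noise_sd >= 0,
            metabolic_noise_cv >= 0, efficiency > 0, efficiency <= 1,
            duty_factor > 0.5, duty_factor < 1)
  structure(as.list(environment()), class = "cohort_config")
}

# landmark standing heights as fractions of stature; chosen to reproduce the
# study's immersion-depth fractions (knee 0.28, trochanter 0.48,
# umbilicus 0.63, xiphoid 0.73)
landmark_height_fractions <- function() {
  c(calcaneus = 0.005, lateral_malleolus = 0.039, femoral_epicondyle = 0.28,
    greater_trochanter = 0.48, umbilicus = 0.63, xiphoid = 0.73)
}

#' Generate a synthetic cohort of anthropometries
#'
#' Masses and statures are drawn from the configured distributions (masses
#' truncated at +/- 3 sd). Segment lengths scale with stature using the
#' landmark height fractions; circumferences scale with the girth factor
#' `sqrt((mass / 77.1) / (stature / 1.78))` applied to reference adult
#' girths.
#'
#' @param config A `"cohort_config"`.
#' @return A list of [anthropometry()] objects, length `n_participants`.
#' @export
generate_cohort <- function(config) {
  set.seed(config$seed)
  h <- landmark_height_fractions()
  lapply(seq_len(config$n_participants), function(i) {
    mass <- config$mass_mean
    if (config$mass_sd > 0) {
      repeat {
        mass <- stats::rnorm(1, config$mass_mean, config$mass_sd)
        if (abs(mass - config$mass_mean) <= 3 * config$mass_sd) break
      }
    }
    stature <- stats::rnorm(1, config$stature_mean, config$stature_sd)
    gs <- sqrt((mass / 77.1) / (stature / 1.78))
    segments <- data.frame(
      segment = c("foot", "shank", "thigh", "trunk"),
      length = stature * c(0.152,
                           h[["femoral_epicondyle"]] - h[["lateral_malleolus"]],
                           h[["greater_trochanter"]] - h[["femoral_epicondyle"]],
                           h[["xiphoid"]] - h[["greater_trochanter"]]),
      proximal_circumference = gs * c(0.24, 0.37, 0.60, 0.96),
      distal_circumference   = gs * c(0.23, 0.23, 0.40, 0.88)
    )
    anthropometry(sprintf("P%02d", i), mass, stature,
                  leg_length = h[["greater_trochanter"]] * stature,
                  segments = segments)
  })
}

#' Generate one synthetic gait trial
#'
#' Builds 60 Hz sagittal marker trajectories for walking at a target speed:
#' the digitised (right) foot alternates stance (calcaneus fixed on the
#' floor) and swing (cosine-profile advance of one stride length with a
#' sinusoidal lift), the greater trochanter advances at the target speed,
#' and the knee follows from two-link inverse kinematics between hip and
#' ankle. Trunk landmarks ride rigidly above the trochanter with a small
#' constant forward lean. Stride length follows the configured
#' `SL = a + b * speed` relation and cadence is `speed / SL`, so the
#' generated mean trochanter speed equals the requested speed by
#' construction. Additive Gaussian marker noise is applied per the config.
#'
#' @param anthro An [anthropometry()] object.
#' @param speed Target walking speed (m/s), positive.
#' @param config A `"cohort_config"`.
#' @param seed Integer seed for this trial.
#' @param n_strides Full strides to generate (default
#'   `strides_per_condition + 3`; at least 6).
#' @return A `"marker_set"` with ground truth attached as attribute
#'   `"truth"` (list: `SL`, `speed`, `period`, `n_strides`).
#' @export
generate_gait_trial <- function(anthro, speed, config, seed,
                                n_strides = NULL) {
  if (speed <= 0) stop("speed must be positive", call. = FALSE)
  if (is.null(n_strides)) {
    n_strides <- max(6L, config$strides_per_condition + 3L)
  }
  set.seed(seed)
  fs <- 60
  h <- landmark_height_fractions() * anthro$stature
  sl <- config$sl_intercept + config$sl_slope * speed
  period <- sl / speed
  duty <- config$duty_factor
  l_thigh <- h[["greater_trochanter"]] - h[["femoral_epicondyle"]]
  l_shank <- h[["femoral_epicondyle"]] - h[["lateral_malleolus"]]
  if (0.35 * sl >= 0.98 * (l_thigh + l_shank)) {
    stop("unreachable speed/stride-length combination", call. = FALSE)
  }
  duration <- (n_strides + 1) * period
  t <- seq(0, duration, by = 1 / fs)
  t0 <- 0.25 * period

  # right calcaneus: stance fixed at the floor, cosine-profile swing
  phase <- (t - t0) / period
  k <- floor(phase)
  ph <- phase - k
  in_stance <- ph < duty
  tau <- pmax((ph - duty) / (1 - duty), 0)
  heel_x <- k * sl + ifelse(in_stance, 0, sl * (1 - cos(pi * tau)) / 2)
  heel_y <- 0.005 + ifelse(in_stance, 0, 0.05 * sin(pi * tau))

  foot_len <- anthro$segments$length[anthro$segments$segment == "foot"]
  met_x <- heel_x + 0.95 * foot_len
  met_y <- heel_y + 0.005
  ank_x <- heel_x + 0.04
  ank_y <- heel_y + (h[["lateral_malleolus"]] - 0.005)

  # trochanter: constant-height forward progression at the target speed,
  # height chosen so the two-link chain to the ankle always closes
  hip_h <- sqrt((0.98 * (l_thigh + l_shank))^2 - (0.35 * sl)^2) +
    h[["lateral_malleolus"]]
  hip_x <- 0.45 * sl + speed * (t - t0) + 0.008 * sin(4 * pi * phase)
  hip_y <- rep(hip_h, length(t))

  # knee by two-link inverse kinematics, knee ahead of the hip-ankle line
  dx <- ank_x - hip_x; dy <- ank_y - hip_y
  d <- pmin(sqrt(dx^2 + dy^2), 0.999 * (l_thigh + l_shank))
  ca <- (l_thigh^2 + d^2 - l_shank^2) / (2 * l_thigh * d)
  alpha <- acos(pmin(pmax(ca, -1), 1))
  base <- atan2(dy, dx)
  knee_x <- hip_x + l_thigh * cos(base - alpha)
  knee_y <- hip_y + l_thigh * sin(base - alpha)

  lean <- 0.03
  umb_x <- hip_x + lean
  umb_y <- hip_y + (h[["umbilicus"]] - h[["greater_trochanter"]])
  xip_x <- hip_x + 1.6 * lean
  xip_y <- hip_y + (h[["xiphoid"]] - h[["greater_trochanter"]])

  df <- data.frame(
    time = t,
    fifth_metatarsal_x = met_x, fifth_metatarsal_y = met_y,
    calcaneus_x = heel_x, calcaneus_y = heel_y,
    lateral_malleolus_x = ank_x, lateral_malleolus_y = ank_y,
    femoral_epicondyle_x = knee_x, femoral_epicondyle_y = knee_y,
    greater_trochanter_x = hip_x, greater_trochanter_y = hip_y,
    umbilicus_x = umb_x, umbilicus_y = umb_y,
    xiphoid_x = xip_x, xiphoid_y = xip_y
  )
  if (config$marker_noise_sd > 0) {
    noise_cols <- setdiff(names(df), "time")
    df[noise_cols] <- lapply(df[noise_cols], function(v) {
      v + stats::rnorm(length(v), 0, config$marker_noise_sd)
    })
  }
  markers <- as_marker_set(df)
  attr(markers, "truth") <- list(SL = sl, speed = speed, period = period,
                                 n_strides = n_strides)
  markers
}

#' Generate synthetic breath-by-breath gas exchange
#'
#' Inverts the indirect-calorimetry equations: the walking net power implied
#' by the true cost of transport (`net = COT * speed * 60` J/kg/min) is added
#' to the resting baseline, converted breath-by-breath to VO2 through the
#' configured energy equivalent at a respiratory exchange ratio drawn
#' uniformly in the configured band, then degraded with multiplicative
#' lognormal noise (unit mean). Breath intervals are ~3 s. With zero noise,
#' processing the records back through [metabolic_power()] and
#' [measured_cot()] recovers the true cost exactly (the energy equivalent is
#' linear in RER, so window means invert exactly).
#'
#' @param cot_true True net cost of transport (J/kg/m), positive.
#' @param speed Walking speed (m/s).
#' @param mass Body mass (kg).
#' @param config A `"cohort_config"`.
#' @param seed Integer seed.
#' @param walk_duration Walking record length (s), default 300 (5 min).
#' @param rest_duration Resting record length (s), default 420 (7 min).
#' @param equation Energy-equivalent form, see [energy_equivalent()].
#' @return List of two `data.frame`s, `walk` and `rest`, each with columns
#'   `time`, `vo2`, `vco2` (ml/min); the true values are attached as
#'   attribute `"truth"`.
#' @export
generate_metabolic_data <- function(cot_true, speed, mass, config, seed,
                                    walk_duration = 300, rest_duration = 420,
                                    equation = "garby_astrup") {
  if (cot_true <= 0 || speed <= 0 || mass <= 0) {
    stop("cot_true, speed and mass must be positive", call. = FALSE)
  }
  set.seed(seed)
  net <- cot_true * speed * 60                     # J/kg/min
  gross_walk <- net + config$rest_power
  make_record <- function(gross_power, duration) {
    times <- cumsum(stats::runif(ceiling(duration / 2), 2.4, 3.6))
    times <- times[times <= duration]
    rer <- stats::runif(length(times), config$rer_range[1],
                        config$rer_range[2])
    vo2 <- gross_power * mass / energy_equivalent(rer, equation)
    if (config$metabolic_noise_cv > 0) {
      sdlog <- sqrt(log(1 + config$metabolic_noise_cv^2))
      vo2 <- vo2 * stats::rlnorm(length(vo2), -sdlog^2 / 2, sdlog)
    }
    data.frame(time = times, vo2 = vo2, vco2 = rer * vo2)
  }
  out <- list(walk = make_record(gross_walk, walk_duration),
              rest = make_record(config$rest_power, rest_duration))
  attr(out, "truth") <- list(cot = cot_true, net_power = net,
                             gross_walk = gross_walk,
                             gross_rest = config$rest_power)
  out
}
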