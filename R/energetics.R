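#' Horizontal (drag) work per stride
#'
#' Work done against the stride-representative drag force over one stride:
#' `W_D = DrF * SL`.
#'
#' @param drf Stride drag force (N), non-negative.
#' @param sl Stride length (m), positive.
#' @return Work (J).
#' @export
horizontal_work <- function(drf, sl) {
  if (any(drf < 0)) stop("drf must be non-negative", call. = FALSE)
  if (any(sl <= 0)) stop("sl must be positive", call. = FALSE)
  drf * sl
}

#' Vertical displacement of the centre of mass per contact phase
#'
#' Compass-gait (inverted pendulum) arc: the centre of mass rides over the
#' stance leg of length `L_leg`, covering a forward distance `L_sc` during
#' single support, so it rises by
#' `COM_vert = L_leg * (1 - cos(0.5 * L_sc / L_leg))`.
#'
#' @param l_leg Lower-limb length (m).
#' @param l_sc Forward displacement during single contact (m); the arc
#'   `l_sc / l_leg` must stay below `pi`.
#' @return Vertical displacement (m).
#' @export
com_vertical_displacement <- function(l_leg, l_sc) {
  if (any(l_leg <= 0)) stop("l_leg must be positive", call. = FALSE)
  if (any(l_sc < 0)) stop("l_sc must be non-negative", call. = FALSE)
  if (any(l_sc / l_leg >= pi)) {
    stop("l_sc / l_leg must be below pi", call. = FALSE)
  }
  l_leg * (1 - cos(0.5 * l_sc / l_leg))
}

#' Vertical work per stride
#'
#' Work to lift the centre of mass against the apparent (buoyancy-reduced)
#' body weight, twice per stride (two contact phases):
#' `W_v = GRF_v * COM_vert * 2`.
#'
#' @param grf_v Stride-mean vertical ground reaction force (N).
#' @param com_vert Vertical displacement per contact phase (m).
#' @return Work (J).
#' @export
vertical_work <- function(grf_v, com_vert) {
  if (any(grf_v < 0) || any(com_vert < 0)) {
    stop("inputs must be non-negative", call. = FALSE)
  }
  grf_v * com_vert * 2
}

#' Total mechanical work per stride in water
#'
#' `W_Aqua = W_D + W_v`.
#'
#' @param w_d Horizontal (drag) work (J).
#' @param w_v Vertical work (J).
#' @return Total work (J).
#' @export
total_work <- function(w_d, w_v) w_d + w_v

#' Predicted cost of transport from mechanical work
#'
#' `COT_predicted = W_Aqua / (SL * mass * efficiency)` in J/kg/m. The default
#' muscle efficiency of 0.25 reflects the predominance of concentric actions
#' when buoyancy and drag suppress eccentric braking work.
#'
#' @param w_aqua Total mechanical work per stride (J).
#' @param sl Stride length (m), positive.
#' @param mass Body mass (kg), positive.
#' @param efficiency Muscle efficiency in `(0, 1]`, default 0.25.
#' @return Predicted cost of transport (J/kg/m).
#' @export
cot_predicted <- function(w_aqua, sl, mass, efficiency = 0.25) {
  if (any(sl <= 0) || any(mass <= 0)) {
    stop("sl and mass must be positive", call. = FALSE)
  }
  if (any(efficiency <= 0) || any(efficiency > 1)) {
    stop("efficiency must lie in (0, 1]", call. = FALSE)
  }
  w_aqua / (sl * mass * efficiency)
}

#' Per-stride energetics table
#'
#' Applies the work and cost equations stride by stride and returns the
#' per-stride quantities plus their condition mean.
#'
#' @param strides A `"stride_metrics"` data frame.
#' @param drag A `"drag_summary"` data frame (same strides).
#' @param grf_v Stride-mean vertical ground reaction force (N).
#' @param l_leg Lower-limb length (m).
#' @param mass Body mass (kg).
#' @param efficiency Muscle efficiency, default 0.25.
#' @return A `data.frame` with per-stride `SL`, `v`, `drf`, `W_D`,
#'   `COM_vert`, `W_v`, `W_Aqua`, `cot_predicted`; the across-stride mean
#'   COT is attached as attribute `"mean_cot_predicted"`.
#' @export
stride_energetics <- function(strides, drag, grf_v, l_leg, mass,
                              efficiency = 0.25) {
  stopifnot(nrow(strides) == nrow(drag))
  w_d <- horizontal_work(drag$drf, strides$SL)
  com <- com_vertical_displacement(l_leg, strides$L_sc)
  w_v <- vertical_work(grf_v, com)
  w_aqua <- total_work(w_d, w_v)
  cot <- cot_predicted(w_aqua, strides$SL, mass, efficiency)
  out <- data.frame(stride = strides$stride, SL = strides$SL, v = strides$v,
                    drf = drag$drf, W_D = w_d, COM_vert = com, W_v = w_v,
                    W_Aqua = w_aqua, cot_predicted = cot)
  attr(out, "mean_cot_predicted") <- mean(cot)
  out
}

#' Energy equivalent of oxygen
#'
#' J per ml O2 as a function of the respiratory exchange ratio. Forms:
#' `"garby_astrup"` (default), `E = 16.04 + 4.94 * RER`; `"brockway"`,
#' `E = 16.58 + 4.51 * RER`.
#'
#' @param rer Respiratory exchange ratio VCO2/VO2.
#' @param equation `"garby_astrup"` or `"brockway"`.
#' @return Energy equivalent (J/ml O2).
#' @export
energy_equivalent <- function(rer, equation = c("garby_astrup", "brockway")) {
  equation <- match.arg(equation)
  switch(equation,
         garby_astrup = 16.04 + 4.94 * rer,
         brockway = 16.58 + 4.51 * rer)
}

#' Gross metabolic power from breath-by-breath gas exchange
#'
#' Indirect calorimetry over an analysis window: mean VO2 and RER set the
#' energy equivalent of oxygen, giving gross power in J/kg/min. Steady-state
#' aerobic metabolism is assumed; a window RER above 1.0 (or outside the
#' 0.6-1.3 sanity band) triggers a warning.
#'
#' @param records `data.frame` with columns `time` (s), `vo2` (ml/min),
#'   `vco2` (ml/min).
#' @param mass Body mass (kg).
#' @param window Optional `c(t0, t1)` analysis window (s); default the whole
#'   record. Trials conventionally use the final 2 min of a 5-min bout.
#' @param equation Energy-equivalent form, see [energy_equivalent()].
#' @return List with `power` (J/kg/min), `vo2` (ml/min), `rer`.
#' @export
metabolic_power <- function(records, mass, window = NULL,
                            equation = "garby_astrup") {
  stopifnot(all(c("time", "vo2", "vco2") %in% names(records)))
  if (!is.null(window)) {
    records <- records[records$time >= window[1] & records$time <= window[2], ]
  }
  if (nrow(records) == 0) stop("empty analysis window", call. = FALSE)
  vo2 <- mean(records$vo2)
  if (vo2 < 0) stop("negative mean VO2", call. = FALSE)
  if (vo2 == 0) {
    return(list(power = 0, vo2 = 0, rer = NA_real_))
  }
  rer <- mean(records$vco2) / vo2
  if (rer < 0.6 || rer > 1.3) {
    warning(sprintf("window RER %.2f outside the 0.6-1.3 sanity band", rer))
  } else if (rer > 1.0) {
    warning(sprintf("window RER %.2f > 1.0: aerobic assumption questionable",
                    rer))
  }
  e <- energy_equivalent(rer, equation)
  list(power = vo2 * e / mass, vo2 = vo2, rer = rer)
}

#' Measured net cost of transport
#'
#' Net metabolic power is walking gross power minus at-rest gross power at
#' the same immersion depth; dividing by speed converts J/kg/min into
#' J/kg/m: `COT = net / (60 * speed)`.
#'
#' @param gross_walk Walking gross power (J/kg/min).
#' @param gross_rest Resting gross power (J/kg/min).
#' @param speed Walking speed (m/s), positive.
#' @return List with `net_power` (J/kg/min), `cot` (J/kg/m),
#'   `gross_walk`, `gross_rest`.
#' @export
measured_cot <- function(gross_walk, gross_rest, speed) {
  if (any(speed <= 0)) stop("speed must be positive", call. = FALSE)
  if (any(gross_walk < gross_rest)) {
    warning("walking gross power below resting gross power")
  }
  net <- gross_walk - gross_rest
  list(net_power = net, cot = net / (60 * speed),
       gross_walk = gross_walk, gross_rest = gross_rest)
}
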