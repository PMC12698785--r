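#' Water and drag-model properties
#'
#' @param surface_height Water-surface height above the pool floor (m), i.e.
#'   the immersion depth.
#' @param density Water density (kg/m^3). Default 995.7, water at 31-32 C.
#' @param cd_limb,cd_trunk Pressure-drag coefficients for limb and trunk
#'   strips (dimensionless). Default 1.0: circular cylinder in cross-flow at
#'   the high Reynolds numbers (turbulent regime) typical of walking in
#'   water.
#' @param gravity Gravitational acceleration (m/s^2), default 9.81.
#' @param kinematic_viscosity Kinematic viscosity (m^2/s), default 7.7e-7
#'   (water at ~32 C); used only for Reynolds-number reporting.
#' @return A list of class `"water_properties"`.
#' @export
water_properties <- function(surface_height, density = 995.7,
                             cd_limb = 1.0, cd_trunk = 1.0,
                             gravity = 9.81, kinematic_viscosity = 7.7e-7) {
  stopifnot(surface_height >= 0, density > 0, cd_limb > 0, cd_trunk > 0,
            gravity > 0, kinematic_viscosity > 0)
  structure(list(surface_height = surface_height, density = density,
                 cd_limb = cd_limb, cd_trunk = cd_trunk, gravity = gravity,
                 kinematic_viscosity = kinematic_viscosity),
            class = "water_properties")
}

#' Instantaneous pressure drag on strips
#'
#' Strip-theory pressure drag: only the velocity component normal to the
#' strip's long axis (in the sagittal plane) generates drag,
#' `F = 1/2 * rho * Cd * A * v_n * |v_n|` with reference area
#' `A = 2 * local_radius * strip_length * immersed_fraction` (the frontal
#' projection of the strip). Strips fully above the surface contribute 0.
#' The returned value is the signed force magnitude along the strip normal;
#' the drag force on the body opposes the normal motion.
#'
#' @param v_normal Normal velocity component(s) (m/s).
#' @param local_radius Strip radius(-ii) (m).
#' @param strip_length Strip length(s) (m).
#' @param immersed_fraction Fraction of the strip length below the surface,
#'   in `[0, 1]`.
#' @param cd Drag coefficient.
#' @param density Water density (kg/m^3).
#' @return Signed drag magnitude(s) (N), same shape as `v_normal`.
#' @export
strip_drag <- function(v_normal, local_radius, strip_length,
                       immersed_fraction = 1, cd = 1.0, density = 995.7) {
  if (any(!is.finite(v_normal))) {
    stop("non-finite strip velocity", call. = FALSE)
  }
  area <- 2 * local_radius * strip_length * immersed_fraction
  0.5 * density * cd * area * v_normal * abs(v_normal)
}

# immersed fraction of a strip spanning vertical coordinates [y0, y1]
immersed_fraction_of <- function(y0, y1, surface) {
  lo <- pmin(y0, y1); hi <- pmax(y0, y1)
  span <- hi - lo
  frac <- ifelse(span < 1e-12, as.numeric(lo < surface),
                 (surface - lo) / pmax(span, 1e-12))
  pmin(pmax(frac, 0), 1)
}

# Per-frame horizontal drag force (N) of one segment, summed over strips.
# state: one element of segment_states$segments; strips: a strip_set;
# nominal_length: the frustum length used to place strips as fractions of
# the (possibly noisy) marker-to-marker axis.
# Returns list(fx = per-frame force, re = Reynolds-number range).
segment_horizontal_drag <- function(state, strips, nominal_length,
                                    cd, water, src_idx = NULL) {
  take <- function(v) if (is.null(src_idx)) v else v[src_idx]
  px <- take(state$prox_x); py <- take(state$prox_y)
  dx <- take(state$dist_x); dy <- take(state$dist_y)
  vpx <- take(state$vx_prox); vpy <- take(state$vy_prox)
  vdx <- take(state$vx_dist); vdy <- take(state$vy_dist)

  ax <- dx - px; ay <- dy - py
  len <- sqrt(ax^2 + ay^2)
  ux <- ax / len; uy <- ay / len            # unit axis, proximal -> distal
  nx <- -uy; ny <- ux                       # in-plane normal

  f <- strips$axial_position / nominal_length       # strip midpoint fraction
  h <- 0.5 * strips$strip_length / nominal_length   # half strip, fractional
  n_frame <- length(px); n_strip <- nrow(strips)

  # frames x strips matrices via outer products on fractions
  Fm <- matrix(f, n_frame, n_strip, byrow = TRUE)
  Hm <- matrix(h, n_frame, n_strip, byrow = TRUE)
  Rm <- matrix(strips$local_radius, n_frame, n_strip, byrow = TRUE)
  Lm <- matrix(strips$strip_length, n_frame, n_strip, byrow = TRUE)

  vx <- (1 - Fm) * vpx + Fm * vdx           # rigid-body interpolation
  vy <- (1 - Fm) * vpy + Fm * vdy
  vn <- vx * nx + vy * ny
  if (any(!is.finite(vn))) stop("non-finite strip velocity", call. = FALSE)

  y_lo <- py + (Fm - Hm) * ay               # strip end heights
  y_hi <- py + (Fm + Hm) * ay
  wet <- immersed_fraction_of(y_lo, y_hi, water$surface_height)

  s <- 0.5 * water$density * cd * (2 * Rm * Lm * wet) * vn * abs(vn)
  fx <- rowSums(-s * nx)                    # drag opposes normal motion
  re <- abs(vn) * 2 * Rm / water$kinematic_viscosity
  re_wet <- re[wet > 0]
  list(fx = fx,
       re_range = if (length(re_wet)) range(re_wet) else c(NA_real_, NA_real_))
}

#' Stride-level drag force summary
#'
#' Computes the instantaneous horizontal drag of every immersed strip of
#' every segment at every frame, sums across segments, and reduces each
#' stride to the time-average of the magnitude of the net horizontal drag
#' (`DrF`). Contact and swing phases of the stride are averaged separately
#' and combined as a duration-weighted mean, which equals the whole-stride
#' time average; both per-phase values are reported. This stride-
#' representative force in newtons is the `DrF` that multiplies stride
#' length to give drag work. Alternatively `aggregate = "time_sum"` returns
#' the impulse-like per-frame sum divided by the sampling rate times stride
#' count (exposed for sensitivity to the aggregation convention).
#'
#' The contralateral leg is included by phase-shifting the digitised leg's
#' states by half a stride.
#'
#' @param states A `"segment_states"` object.
#' @param model The `"segment_model"` (for nominal lengths and Cd classes).
#' @param strip_sets Named list from [discretize_model()].
#' @param strides A `"stride_metrics"` data frame (with contact attribute).
#' @param water A `"water_properties"` object.
#' @param include_contralateral Include the mirrored leg (default `TRUE`).
#' @param aggregate `"time_average"` (default) or `"time_sum"`.
#' @return A `data.frame` of class `"drag_summary"`: per stride `drf`,
#'   `drf_contact`, `drf_swing` (N). Attributes: `"per_segment"` (named
#'   mean |Fx| contribution per segment over the analysed strides),
#'   `"reynolds_range"`, `"fx_total"` (per-frame net horizontal drag).
#' @export
stride_drag <- function(states, model, strip_sets, strides, water,
                        include_contralateral = TRUE,
                        aggregate = c("time_average", "time_sum")) {
  aggregate <- match.arg(aggregate)
  if (nrow(strides) == 0) stop("empty stride set", call. = FALSE)
  half <- attr(strides, "half_stride_samples")
  if (is.null(half)) half <- 0L
  contact <- attr(strides, "contact")
  n_frame_all <- length(states$time)
  # contralateral frames come from the digitised leg half a stride earlier;
  # gait periodicity lets us step whole strides away from the series edges,
  # where filter and derivative transients would otherwise leak in
  contra_idx <- contralateral_index(n_frame_all, half)

  n_frame <- length(states$time)
  fx_total <- numeric(n_frame)
  fx_by_segment <- list()
  re_lo <- Inf; re_hi <- -Inf
  for (i in seq_len(nrow(model))) {
    seg_name <- model$segment[i]
    side <- model$side[i]
    if (side == "left" && !include_contralateral) next
    state <- states$segments[[seg_name]]
    if (is.null(state)) next
    cd <- if (seg_name == "trunk") water$cd_trunk else water$cd_limb
    idx <- if (side == "left") contra_idx else NULL
    res <- segment_horizontal_drag(state, strip_sets[[model$name[i]]],
                                   model$length[i], cd, water, idx)
    fx_total <- fx_total + res$fx
    fx_by_segment[[model$name[i]]] <- res$fx
    if (is.finite(res$re_range[1])) {
      re_lo <- min(re_lo, res$re_range[1]); re_hi <- max(re_hi, res$re_range[2])
    }
  }
  analysed <- unlist(lapply(seq_len(nrow(strides)), function(k) {
    strides$start[k]:(strides$end[k] - 1L)
  }))
  per_segment <- vapply(fx_by_segment,
                        function(fx) mean(abs(fx[analysed])), numeric(1))

  dt <- 1 / states$sampling_rate
  rows <- lapply(seq_len(nrow(strides)), function(k) {
    win <- strides$start[k]:(strides$end[k] - 1L)
    mag <- abs(fx_total[win])
    in_contact <- if (!is.null(contact)) contact[win] else rep(TRUE, length(win))
    avg <- function(v) if (length(v)) mean(v) else 0
    drf_c <- avg(mag[in_contact]); drf_s <- avg(mag[!in_contact])
    drf <- if (aggregate == "time_average") {
      (sum(mag[in_contact]) + sum(mag[!in_contact])) / length(win)
    } else {
      sum(mag) * dt
    }
    data.frame(stride = strides$stride[k], drf = drf,
               drf_contact = drf_c, drf_swing = drf_s)
  })
  out <- do.call(rbind, rows)
  attr(out, "per_segment") <- per_segment
  attr(out, "reynolds_range") <-
    if (is.finite(re_lo)) c(re_lo, re_hi) else c(NA_real_, NA_real_)
  attr(out, "fx_total") <- fx_total
  class(out) <- c("drag_summary", "data.frame")
  out
}

# Source-frame index for the contralateral leg: half a stride back, folded
# by whole stride periods into [margin, n - margin] where possible.
contralateral_index <- function(n, half, margin = 45L) {
  if (half <= 0) return(seq_len(n))
  period <- 2L * half
  src <- seq_len(n) - half
  lo <- min(margin, n %/% 4L); hi <- n - lo
  for (k in 1:3) src <- ifelse(src < lo, src + period, src)
  for (k in 1:3) src <- ifelse(src > hi, src - period, src)
  pmin(pmax(src, 1L), n)
}

#' Closed-form drag of a frustum in uniform cross-flow
#'
#' Exact diameter integral for a conic frustum moving broadside at uniform
#' speed while fully immersed:
#' `F = 1/2 * rho * Cd * 2 * ((r_p + r_d) / 2) * L * v^2`. Used as the
#' analytic oracle for the strip sum.
#'
#' @param length,proximal_radius,distal_radius Frustum geometry (m).
#' @param speed Uniform normal speed (m/s).
#' @param cd Drag coefficient.
#' @param density Water density (kg/m^3).
#' @return Drag force (N).
#' @export
frustum_drag_uniform <- function(length, proximal_radius, distal_radius,
                                 speed, cd = 1.0, density = 995.7) {
  area <- 2 * (proximal_radius + distal_radius) / 2 * length
  0.5 * density * cd * area * speed * abs(speed)
}
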