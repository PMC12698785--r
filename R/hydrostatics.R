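#' Weight-bearing (apparent weight) table
#'
#' Ordered pairs of immersion depth, as a fraction of stature, and the
#' corresponding weight-bearing fraction (apparent weight over dry weight)
#' during upright immersion. The fraction must decrease strictly with depth
#' and the dry-land endpoint (0, 1) must be present (it is added if absent).
#'
#' @param depth_fraction Numeric vector in `[0, 1]`, increasing.
#' @param weight_bearing Numeric vector in `(0, 1]`, strictly decreasing.
#' @return A `data.frame` of class `"weight_bearing_table"`.
#' @export
weight_bearing_table <- function(depth_fraction, weight_bearing) {
  stopifnot(length(depth_fraction) == length(weight_bearing))
  o <- order(depth_fraction)
  depth_fraction <- depth_fraction[o]; weight_bearing <- weight_bearing[o]
  if (depth_fraction[1] > 0) {
    depth_fraction <- c(0, depth_fraction)
    weight_bearing <- c(1, weight_bearing)
  }
  if (any(diff(depth_fraction) <= 0)) {
    stop("depth_fraction values must be distinct", call. = FALSE)
  }
  if (any(diff(weight_bearing) >= 0)) {
    stop("weight_bearing must decrease strictly with depth", call. = FALSE)
  }
  if (any(weight_bearing <= 0) || any(weight_bearing > 1)) {
    stop("weight_bearing must lie in (0, 1]", call. = FALSE)
  }
  out <- data.frame(depth_fraction = depth_fraction,
                    weight_bearing = weight_bearing)
  class(out) <- c("weight_bearing_table", "data.frame")
  out
}

#' Default weight-bearing table
#'
#' Piecewise-linear nodes at the four anatomical immersion landmarks (knee,
#' hip/greater trochanter, umbilicus, xiphoid) at their mean depth fractions
#' of stature, with the weight-bearing fractions that the corresponding
#' gravity equivalents imply (0.88, 0.58, 0.48, 0.33 g), plus the dry-land
#' endpoint. Literature per-landmark values can be supplied instead via
#' [read_weight_bearing_table()].
#'
#' @return A `"weight_bearing_table"`.
#' @export
default_weight_bearing_table <- function() {
  weight_bearing_table(
    depth_fraction = c(0, 0.28, 0.48, 0.63, 0.73),
    weight_bearing = c(1.00, 0.88, 0.58, 0.48, 0.33)
  )
}

#' Read a weight-bearing table from CSV
#'
#' @param path CSV with columns `depth_fraction`, `weight_bearing`.
#' @return A `"weight_bearing_table"`.
#' @export
read_weight_bearing_table <- function(path) {
  df <- utils::read.csv(path)
  weight_bearing_table(df$depth_fraction, df$weight_bearing)
}

#' Weight-bearing fraction at an immersion depth
#'
#' Piecewise-linear interpolation of the table at `depth / stature`. Depths
#' beyond the last tabulated landmark are extrapolated along the final
#' segment (with a warning), floored just above zero.
#'
#' @param depth Immersion depth (m), in `[0, stature]`.
#' @param stature Participant stature (m).
#' @param table A `"weight_bearing_table"`.
#' @return Weight-bearing fraction `w` in `(0, 1]`.
#' @export
weight_bearing_fraction <- function(depth, stature,
                                    table = default_weight_bearing_table()) {
  if (any(depth < 0) || any(depth > stature)) {
    stop("depth must lie in [0, stature]", call. = FALSE)
  }
  frac <- depth / stature
  top <- max(table$depth_fraction)
  w <- stats::approx(table$depth_fraction, table$weight_bearing,
                     xout = pmin(frac, top))$y
  over <- frac > top
  # a small overshoot (within the study's 2% depth-fraction spread) is
  # extrapolated silently; larger overshoots warn
  if (any(frac > top + 0.015)) {
    warning("depth fraction beyond table range; extrapolating last segment")
    n <- nrow(table)
    slope <- (table$weight_bearing[n] - table$weight_bearing[n - 1]) /
      (table$depth_fraction[n] - table$depth_fraction[n - 1])
    w[over] <- pmax(table$weight_bearing[n] + slope * (frac[over] - top), 1e-6)
  }
  w
}

#' Stride-mean vertical ground reaction force under immersion
#'
#' Over a full stride the mean vertical ground reaction force equals the
#' supported (apparent) body weight, so
#' `GRF_v = w * mass * g`, buoyancy `B = (1 - w) * mass * g`, and the dry
#' gravitational force `Fg = mass * g`, with `B + GRF_v = Fg` exactly.
#'
#' @param mass Body mass (kg).
#' @param w Weight-bearing fraction in `(0, 1]`.
#' @param gravity Gravitational acceleration (m/s^2), default 9.81.
#' @return List with `grf_v`, `buoyancy`, `fg` (N) and `w`.
#' @export
grf_vertical <- function(mass, w, gravity = 9.81) {
  check_positive_scalar(mass, "mass")
  if (any(w <= 0) || any(w > 1)) {
    stop("w must lie in (0, 1]", call. = FALSE)
  }
  fg <- mass * gravity
  list(grf_v = w * fg, buoyancy = (1 - w) * fg, fg = fg, w = w)
}

#' Gravity equivalent of a weight-bearing fraction
#'
#' Immersion reduces the supported weight exactly as hypogravity would, so
#' the weight-bearing fraction maps identically onto an equivalent gravity
#' expressed as a fraction of 1 g.
#'
#' @param w Weight-bearing fraction in `(0, 1]`.
#' @return Equivalent gravity (g-units), numerically equal to `w`.
#' @export
gravity_equivalent <- function(w) {
  if (any(w <= 0) || any(w > 1)) stop("w must lie in (0, 1]", call. = FALSE)
  w
}

#' Immersion depth equivalent to a hypogravity level
#'
#' Inverts the weight-bearing table piecewise-linearly: given a gravity
#' fraction, returns the immersion depth (m) at which upright immersion
#' supports the same fraction of body weight.
#'
#' @param g_frac Gravity fraction in g-units.
#' @param stature Stature (m).
#' @param table A `"weight_bearing_table"`.
#' @return Depth (m).
#' @export
depth_from_gravity <- function(g_frac, stature,
                               table = default_weight_bearing_table()) {
  if (any(g_frac < min(table$weight_bearing)) || any(g_frac > 1)) {
    stop("g_frac outside the table's weight-bearing range", call. = FALSE)
  }
  # weight_bearing decreases with depth_fraction, so flip for approx()
  frac <- stats::approx(rev(table$weight_bearing), rev(table$depth_fraction),
                        xout = g_frac)$y
  frac * stature
}
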