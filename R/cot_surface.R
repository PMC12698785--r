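#' Quadratic cost-of-transport response surface
#'
#' A full second-degree polynomial in walking speed `s` (m/s) and immersion
#' depth `d` (m):
#' `COT = a_ss*s^2 + a_dd*d^2 + a_sd*s*d + a_s*s + a_d*d + a_0` (J/kg/m).
#'
#' @param coefficients Named numeric vector with elements `speed2`,
#'   `depth2`, `speed_depth`, `speed`, `depth`, `intercept`.
#' @param r_squared Coefficient of determination of the fit (optional).
#' @param ci Optional matrix/data.frame of 95% coefficient CIs.
#' @param speed_range,depth_range Fit domain bounds, `c(lo, hi)`.
#' @return An object of class `"cot_surface"`.
#' @export
surface_model <- function(coefficients, r_squared = NA_real_, ci = NULL,
                          speed_range = c(0.2, 0.8),
                          depth_range = c(0.5, 1.3)) {
  needed <- c("speed2", "depth2", "speed_depth", "speed", "depth", "intercept")
  if (!all(needed %in% names(coefficients))) {
    stop("coefficients must be named: ", paste(needed, collapse = ", "),
         call. = FALSE)
  }
  structure(list(coefficients = coefficients[needed], r_squared = r_squared,
                 ci = ci, speed_range = speed_range,
                 depth_range = depth_range),
            class = "cot_surface")
}

#' Published shallow-water walking cost surface
#'
#' The quadratic response surface of net cost of transport over walking
#' speed (0.2-0.8 m/s) and immersion depth (0.5-1.3 m) reported for healthy
#' adults walking in shallow water, with its 95% coefficient CIs and fit
#' R^2 of 0.98. Used as the reference surface for self-selected-speed
#' predictions and for desk evaluations.
#'
#' @return A `"cot_surface"`.
#' @export
study_surface <- function() {
  ci <- rbind(
    speed2      = c(-7.1715, 9.6177),
    depth2      = c(5.3278, 14.5990),
    speed_depth = c(12.7915, 23.0697),
    speed       = c(-18.4388, 2.0991),
    depth       = c(-29.8331, -12.0496),
    intercept   = c(5.6813, 15.3491)
  )
  colnames(ci) <- c("lower", "upper")
  surface_model(
    c(speed2 = 1.22, depth2 = 9.96, speed_depth = 17.93,
      speed = -8.17, depth = -20.95, intercept = 10.52),
    r_squared = 0.98, ci = ci,
    speed_range = c(0.2, 0.8), depth_range = c(0.5, 1.3)
  )
}

#' Study condition-level means
#'
#' Mean measured cost of transport (J/kg/m) and stride drag force (N) for
#' each of the 16 immersion-depth x nominal-speed conditions of the
#' shallow-water walking study, plus the stride-mean vertical ground
#' reaction force (N) per depth. These published group means serve as
#' inputs for surface fitting and desk checks.
#'
#' @return A `data.frame` with columns `depth_label`, `depth` (m), `speed`
#'   (m/s), `cot` (J/kg/m), `drf` (N), `grf_v` (N).
#' @export
study_condition_means <- function() {
  depths <- c(knee = 0.5, hip = 0.85, umbilicus = 1.12, xiphoid = 1.3)
  speeds <- c(0.2, 0.4, 0.6, 0.8)
  cot <- rbind(knee      = c(2.7, 2.8, 3.3, 4.4),
               hip       = c(1.3, 3.3, 4.3, 6.0),
               umbilicus = c(2.8, 4.7, 7.2, 9.6),
               xiphoid   = c(2.7, 5.9, 9.8, 12.1))
  drf <- rbind(knee      = c(8.7, 22.0, 38.6, 58.7),
               hip       = c(13.0, 38.8, 74.0, 111.3),
               umbilicus = c(20.9, 67.1, 115.9, 170.9),
               xiphoid   = c(19.0, 76.0, 126.3, 148.9))
  grf <- c(knee = 666.7, hip = 419.6, umbilicus = 352.7, xiphoid = 244.3)
  out <- expand.grid(speed = speeds, depth_label = names(depths),
                     KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  out$depth <- depths[out$depth_label]
  out$cot <- mapply(function(l, s) cot[l, match(s, speeds)],
                    out$depth_label, out$speed)
  out$drf <- mapply(function(l, s) drf[l, match(s, speeds)],
                    out$depth_label, out$speed)
  out$grf_v <- grf[out$depth_label]
  rownames(out) <- NULL
  out[c("depth_label", "depth", "speed", "cot", "drf", "grf_v")]
}

#' Study mean self-selected walking speeds per immersion depth
#'
#' @return Named numeric vector (m/s) for knee, hip, umbilicus, xiphoid
#'   immersion depths.
#' @export
study_self_selected_speeds <- function() {
  c(knee = 0.62, hip = 0.54, umbilicus = 0.49, xiphoid = 0.43)
}

#' Fit the quadratic cost surface
#'
#' Ordinary least squares on the 6-term full quadratic design in speed and
#' depth. Requires at least 6 points and a full-rank design.
#'
#' @param data `data.frame` with columns `speed`, `depth`, `cot`.
#' @return A `"cot_surface"` with fit R^2 and 95% coefficient CIs.
#' @export
fit_surface <- function(data) {
  stopifnot(all(c("speed", "depth", "cot") %in% names(data)))
  if (nrow(data) < 6) {
    stop("need at least 6 points for the 6-term quadratic surface",
         call. = FALSE)
  }
  fit <- stats::lm(cot ~ I(speed^2) + I(depth^2) + I(speed * depth) +
                     speed + depth, data = data)
  if (any(is.na(stats::coef(fit)))) {
    stop("rank-deficient design: conditions are collinear", call. = FALSE)
  }
  co <- stats::coef(fit)
  map <- c("I(speed^2)" = "speed2", "I(depth^2)" = "depth2",
           "I(speed * depth)" = "speed_depth", "speed" = "speed",
           "depth" = "depth", "(Intercept)" = "intercept")
  coefficients <- stats::setNames(co[names(map)], map)
  # confint warns on zero-residual designs; the CIs are simply degenerate
  ci <- suppressWarnings(stats::confint(fit))[names(map), , drop = FALSE]
  rownames(ci) <- map
  colnames(ci) <- c("lower", "upper")
  r2 <- 1 - sum(stats::residuals(fit)^2) /
    sum((data$cot - mean(data$cot))^2)
  surface_model(coefficients,
                r_squared = r2, ci = ci,
                speed_range = range(data$speed),
                depth_range = range(data$depth))
}

#' Evaluate a cost surface
#'
#' @param model A `"cot_surface"`.
#' @param speed,depth Evaluation points (recycled).
#' @param extrapolate Allow evaluation outside the fit domain without a
#'   warning (default `FALSE`: a warning is emitted).
#' @return Cost of transport (J/kg/m).
#' @export
evaluate_surface <- function(model, speed, depth, extrapolate = FALSE) {
  stopifnot(inherits(model, "cot_surface"))
  if (!extrapolate) {
    tol <- 1e-9
    out_of_domain <- speed < model$speed_range[1] - tol |
      speed > model$speed_range[2] + tol |
      depth < model$depth_range[1] - tol | depth > model$depth_range[2] + tol
    if (any(out_of_domain)) {
      warning("evaluating the surface outside its fit domain")
    }
  }
  a <- model$coefficients
  a[["speed2"]] * speed^2 + a[["depth2"]] * depth^2 +
    a[["speed_depth"]] * speed * depth +
    a[["speed"]] * speed + a[["depth"]] * depth + a[["intercept"]]
}

#' Extrema of the cost surface over a box
#'
#' Global minimum and maximum of the quadratic over
#' `speed_bounds x depth_bounds` by the analytic candidate method: the
#' interior critical point (where the gradient vanishes), the 1-D quadratic
#' vertices along each of the four edges, and the four corners.
#'
#' @param model A `"cot_surface"`.
#' @param speed_bounds,depth_bounds `c(lo, hi)`; default the fit domain.
#' @return List with `minimum` and `maximum`, each holding `cot`, `speed`,
#'   `depth` and `location` (`"interior"`, `"edge"` or `"corner"`).
#' @export
surface_extrema <- function(model, speed_bounds = model$speed_range,
                            depth_bounds = model$depth_range) {
  if (diff(speed_bounds) <= 0 || diff(depth_bounds) <= 0) {
    stop("degenerate bounds", call. = FALSE)
  }
  a <- model$coefficients
  cand <- data.frame(speed = numeric(0), depth = numeric(0),
                     location = character(0))
  add <- function(s, d, loc) {
    if (s >= speed_bounds[1] - 1e-12 && s <= speed_bounds[2] + 1e-12 &&
        d >= depth_bounds[1] - 1e-12 && d <= depth_bounds[2] + 1e-12) {
      cand <<- rbind(cand, data.frame(speed = s, depth = d, location = loc))
    }
  }
  # interior critical point: solve the linear gradient system
  h <- matrix(c(2 * a[["speed2"]], a[["speed_depth"]],
                a[["speed_depth"]], 2 * a[["depth2"]]), 2, 2)
  if (abs(det(h)) > 1e-12) {
    cp <- solve(h, -c(a[["speed"]], a[["depth"]]))
    add(cp[1], cp[2], "interior")
  }
  # edge vertices: 1-D quadratics along each fixed-edge line
  for (d in depth_bounds) {
    if (abs(a[["speed2"]]) > 1e-12) {
      add(-(a[["speed_depth"]] * d + a[["speed"]]) / (2 * a[["speed2"]]),
          d, "edge")
    }
  }
  for (s in speed_bounds) {
    if (abs(a[["depth2"]]) > 1e-12) {
      add(s, -(a[["speed_depth"]] * s + a[["depth"]]) / (2 * a[["depth2"]]),
          "edge")
    }
  }
  for (s in speed_bounds) for (d in depth_bounds) add(s, d, "corner")
  cand$cot <- evaluate_surface(model, cand$speed, cand$depth,
                               extrapolate = TRUE)
  pick <- function(i) list(cot = cand$cot[i], speed = cand$speed[i],
                           depth = cand$depth[i], location = cand$location[i])
  list(minimum = pick(which.min(cand$cot)),
       maximum = pick(which.max(cand$cot)))
}

#' Quadratic cost-speed curve
#'
#' A curve `COT(s) = a2*s^2 + a1*s + a0` over a declared speed range, used
#' both for per-depth fits and for reference curves (swimming, dry-land
#' walking) supplied as coefficient sets.
#'
#' @param coefficients Numeric `c(a2, a1, a0)` (descending powers).
#' @param speed_range Validity range `c(lo, hi)` (m/s).
#' @param name Label.
#' @return An object of class `"cot_curve"`.
#' @export
cot_curve <- function(coefficients, speed_range, name = "curve") {
  stopifnot(length(coefficients) == 3, length(speed_range) == 2)
  structure(list(coefficients = as.numeric(coefficients),
                 speed_range = as.numeric(speed_range), name = name),
            class = "cot_curve")
}

#' Evaluate a cost-speed curve
#'
#' Evaluation outside the declared validity range is permitted but warns
#' (reference equations are extrapolations there).
#'
#' @param curve A `"cot_curve"`.
#' @param speed Speeds (m/s).
#' @param warn_extrapolation Emit the out-of-range warning (default `TRUE`).
#' @return Cost of transport (J/kg/m).
#' @export
evaluate_curve <- function(curve, speed, warn_extrapolation = TRUE) {
  if (warn_extrapolation &&
      (any(speed < curve$speed_range[1] - 1e-9) ||
       any(speed > curve$speed_range[2] + 1e-9))) {
    warning(sprintf("evaluating '%s' outside its validity range", curve$name))
  }
  a <- curve$coefficients
  a[1] * speed^2 + a[2] * speed + a[3]
}

#' Fit a per-depth quadratic cost-speed curve
#'
#' Fits `COT(s)` at one immersion depth and classifies its shape:
#' `"interior_minimum"` (U/J-shape) when the curvature is positive and the
#' vertex lies strictly inside the tested speed range, else `"monotone"`.
#'
#' @param speed,cot Paired observations (>= 3 distinct speeds).
#' @param name Curve label.
#' @return A `"cot_curve"` with extra fields `shape` and `vertex_speed`.
#' @export
per_depth_curve <- function(speed, cot, name = "depth") {
  if (length(speed) < 3) stop("need at least 3 speeds", call. = FALSE)
  fit <- stats::lm(cot ~ I(speed^2) + speed)
  a2 <- stats::coef(fit)[["I(speed^2)"]]
  a1 <- stats::coef(fit)[["speed"]]
  a0 <- stats::coef(fit)[["(Intercept)"]]
  curve <- cot_curve(c(a2, a1, a0), range(speed), name)
  vertex <- if (abs(a2) > 1e-12) -a1 / (2 * a2) else NA_real_
  curve$vertex_speed <- vertex
  curve$shape <- if (!is.na(vertex) && a2 > 0 &&
                     vertex > min(speed) && vertex < max(speed)) {
    "interior_minimum"
  } else {
    "monotone"
  }
  curve
}

#' Iso-cost speeds between two cost-speed curves
#'
#' All real roots of `A(s) - B(s) = 0` inside `speed_range`, by the closed
#' form for the (at most quadratic) polynomial difference. Identical curves
#' are flagged degenerate; an empty result means the curves do not cross.
#'
#' @param curve_a,curve_b `"cot_curve"` objects.
#' @param speed_range Search interval `c(lo, hi)` (m/s).
#' @return A `data.frame` with columns `speed`, `cot` (possibly 0 rows),
#'   with attribute `"degenerate"` `TRUE` for identical curves.
#' @export
iso_cost_speed <- function(curve_a, curve_b, speed_range) {
  d <- curve_a$coefficients - curve_b$coefficients
  empty <- data.frame(speed = numeric(0), cot = numeric(0))
  if (all(abs(d) < 1e-12)) {
    attr(empty, "degenerate") <- TRUE
    return(empty)
  }
  roots <- if (abs(d[1]) > 1e-12) {
    disc <- d[2]^2 - 4 * d[1] * d[3]
    if (disc < 0) numeric(0)
    else (-d[2] + c(-1, 1) * sqrt(disc)) / (2 * d[1])
  } else if (abs(d[2]) > 1e-12) {
    -d[3] / d[2]
  } else {
    numeric(0)
  }
  roots <- sort(unique(roots[roots >= speed_range[1] - 1e-9 &
                               roots <= speed_range[2] + 1e-9]))
  out <- data.frame(
    speed = roots,
    cot = evaluate_curve(curve_a, roots, warn_extrapolation = FALSE)
  )
  attr(out, "degenerate") <- FALSE
  out
}

#' Load reference cost-speed curves from a JSON config
#'
#' Reference equations (front-crawl swimming, dry-land walking, hypogravity
#' walking) are supplied by the user as quadratic coefficient sets with
#' declared validity ranges; a blank template ships in
#' `inst/extdata/reference_curves_template.json`.
#'
#' @param path JSON file: a list of objects with `name`,
#'   `coefficients` (length 3, descending powers) and `speed_range`.
#' @return Named list of `"cot_curve"` objects.
#' @export
read_reference_curves <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
  curves <- lapply(raw, function(r) {
    cot_curve(unlist(r$coefficients), unlist(r$speed_range), r$name)
  })
  stats::setNames(curves, vapply(curves, `[[`, "", "name"))
}

#' Self-selected-speed cost and metabolic power summary
#'
#' Evaluates the cost surface at the self-selected speed of each immersion
#' depth and converts: power (W/kg) = COT (J/kg/m) x speed (m/s); oxygen
#' uptake via the configured energy equivalent of oxygen; calories with
#' 4.186 J/cal; MET as ml O2/kg/min over 3.5.
#'
#' @param model A `"cot_surface"`.
#' @param speeds Named numeric vector of self-selected speeds (m/s).
#' @param depths Named numeric vector of immersion depths (m), same names.
#' @param rer Assumed respiratory exchange ratio for the oxygen conversion,
#'   default 0.85.
#' @param equation Energy-equivalent form, see [energy_equivalent()].
#' @return A `data.frame` with `depth_label`, `depth`, `speed`, `cot`
#'   (J/kg/m), `power` (W/kg), `vo2` (ml O2/kg/min), `cal` (cal/kg/min),
#'   `met`.
#' @export
self_selected_summary <- function(model, speeds, depths, rer = 0.85,
                                  equation = "garby_astrup") {
  if (any(speeds <= 0)) stop("speeds must be positive", call. = FALSE)
  labels <- names(speeds)
  depths <- depths[labels]
  cot <- evaluate_surface(model, speeds, depths)
  power <- cot * speeds                       # W/kg
  j_kg_min <- power * 60
  vo2 <- j_kg_min / energy_equivalent(rer, equation)
  data.frame(depth_label = labels, depth = as.numeric(depths),
             speed = as.numeric(speeds), cot = as.numeric(cot),
             power = as.numeric(power), vo2 = as.numeric(vo2),
             cal = as.numeric(j_kg_min / 4.186),
             met = as.numeric(vo2 / 3.5),
             row.names = NULL)
}
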