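#' Anthropometric description of a participant
#'
#' Bundles the measurements needed to build the segmented body model:
#' total mass, stature, lower-limb length (greater trochanter to floor) and,
#' per segment, length plus proximal and distal circumferences. All units SI.
#'
#' @param participant_id Character label.
#' @param mass Body mass (kg).
#' @param stature Standing height (m).
#' @param leg_length Greater trochanter to floor distance (m); must be less
#'   than stature.
#' @param segments `data.frame` with columns `segment` (one row each of
#'   `"foot"`, `"shank"`, `"thigh"`, `"trunk"`), `length`,
#'   `proximal_circumference`, `distal_circumference` (all m).
#' @return An object of class `"anthropometry"`.
#' @export
anthropometry <- function(participant_id, mass, stature, leg_length, segments) {
  check_positive_scalar(mass, "mass")
  check_positive_scalar(stature, "stature")
  check_positive_scalar(leg_length, "leg_length")
  if (leg_length >= stature) {
    stop("leg_length must be smaller than stature", call. = FALSE)
  }
  required <- c("foot", "shank", "thigh", "trunk")
  cols <- c("segment", "length", "proximal_circumference", "distal_circumference")
  if (!is.data.frame(segments) || !all(cols %in% names(segments))) {
    stop("segments must be a data.frame with columns ",
         paste(cols, collapse = ", "), call. = FALSE)
  }
  missing <- setdiff(required, segments$segment)
  if (length(missing) > 0) {
    stop("missing segment rows: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  for (seg in required) {
    row <- segments[segments$segment == seg, , drop = FALSE][1, ]
    for (field in cols[-1]) {
      value <- row[[field]]
      if (!is.finite(value) || value <= 0) {
        stop(sprintf("non-positive %s for segment '%s'", field, seg),
             call. = FALSE)
      }
    }
  }
  structure(
    list(
      participant_id = as.character(participant_id),
      mass = mass, stature = stature, leg_length = leg_length,
      segments = segments[match(required, segments$segment), cols]
    ),
    class = "anthropometry"
  )
}

#' Read anthropometry from a JSON configuration file
#'
#' The file holds one object per participant with fields `participant_id`,
#' `mass`, `stature`, `leg_length` and a `segments` table; units are SI and
#' validated on construction.
#'
#' @param path Path to a JSON file.
#' @return A list of [anthropometry()] objects.
#' @export
read_anthropometry <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
  lapply(raw, function(p) {
    anthropometry(p$participant_id, p$mass, p$stature, p$leg_length,
                  as.data.frame(p$segments))
  })
}

#' Build the frustum segment model from anthropometry
#'
#' Each lower-limb segment (foot, shank, thigh; both sides) and the trunk
#' (one axial frustum from greater-trochanter level to xiphoid level) is
#' represented as a conic frustum whose end radii come from the measured
#' circumferences assuming circular cross-sections, `r = c / (2 * pi)`.
#' Head and arms are excluded: they stay above the waterline at all
#' immersion depths considered here.
#'
#' @param anthro An [anthropometry()] object.
#' @param include_foot Model the foot as a frustum (default `TRUE`)? Set
#'   `FALSE` to exclude the feet from the drag budget.
#' @return A `data.frame` of class `"segment_model"` with columns `name`,
#'   `segment`, `side` (`"left"`, `"right"`, `"axial"`), `length`,
#'   `proximal_radius`, `distal_radius`.
#' @export
build_segment_model <- function(anthro, include_foot = TRUE) {
  stopifnot(inherits(anthro, "anthropometry"))
  segs <- anthro$segments
  limb <- c(if (include_foot) "foot", "shank", "thigh")
  rows <- list()
  for (seg in limb) {
    row <- segs[segs$segment == seg, ]
    for (side in c("right", "left")) {
      rows[[length(rows) + 1L]] <- data.frame(
        name = paste(seg, side, sep = "_"), segment = seg, side = side,
        length = row$length,
        proximal_radius = row$proximal_circumference / (2 * pi),
        distal_radius = row$distal_circumference / (2 * pi)
      )
    }
  }
  trunk <- segs[segs$segment == "trunk", ]
  rows[[length(rows) + 1L]] <- data.frame(
    name = "trunk", segment = "trunk", side = "axial",
    length = trunk$length,
    proximal_radius = trunk$proximal_circumference / (2 * pi),
    distal_radius = trunk$distal_circumference / (2 * pi)
  )
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("segment_model", "data.frame")
  out
}

#' Discretise a frustum into equal-length strips
#'
#' Splits a conic frustum into `n_strips` transverse strips of equal axial
#' length; the local radius of each strip is the linear interpolation of the
#' proximal and distal radii at the strip midpoint. Because the drag area
#' integrand is linear in the axial coordinate, the midpoint rule makes the
#' strip sum of `2 * r * dl` exact for any number of strips.
#'
#' @param length Frustum length (m).
#' @param proximal_radius,distal_radius End radii (m).
#' @param n_strips Number of strips (>= 1), default 20.
#' @return A `data.frame` of class `"strip_set"` with columns
#'   `axial_position` (strip midpoint, m from the proximal end),
#'   `local_radius` (m) and `strip_length` (m).
#' @export
discretize <- function(length, proximal_radius, distal_radius, n_strips = 20L) {
  if (!is.finite(n_strips) || n_strips < 1) {
    stop("n_strips must be at least 1", call. = FALSE)
  }
  n_strips <- as.integer(n_strips)
  check_positive_scalar(length, "length")
  check_positive_scalar(proximal_radius, "proximal_radius")
  check_positive_scalar(distal_radius, "distal_radius")
  dl <- length / n_strips
  mid <- (seq_len(n_strips) - 0.5) * dl
  r <- proximal_radius + (distal_radius - proximal_radius) * mid / length
  out <- data.frame(axial_position = mid, local_radius = r, strip_length = dl)
  attr(out, "segment_length") <- length
  class(out) <- c("strip_set", "data.frame")
  out
}

#' Discretise every frustum of a segment model
#'
#' @param model A `"segment_model"` from [build_segment_model()].
#' @param n_strips Strips per segment (default 20).
#' @return A named list of `"strip_set"` objects, one per model row.
#' @export
discretize_model <- function(model, n_strips = 20L) {
  sets <- lapply(seq_len(nrow(model)), function(i) {
    discretize(model$length[i], model$proximal_radius[i],
               model$distal_radius[i], n_strips)
  })
  names(sets) <- model$name
  sets
}

check_positive_scalar <- function(x, name) {
  if (length(x) != 1 || !is.finite(x) || x <= 0) {
    stop(sprintf("%s must be a positive finite number", name), call. = FALSE)
  }
  invisible(x)
}
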