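#' @name gait_kinematics
#' @title Sagittal-plane gait kinematics
#' @description Utilities to ingest 60 Hz sagittal marker trajectories,
#'   low-pass filter them, derive segment angular states and detect strides.
#'   Coordinates: `x` horizontal in the walking direction (positive forward),
#'   `y` vertical upward from the pool floor. Angles are measured from the
#'   vertical, positive counterclockwise.
NULL

# landmark order is the digitisation order on the right side of the body
sww_landmarks <- function() {
  c("fifth_metatarsal", "calcaneus", "lateral_malleolus",
    "femoral_epicondyle", "greater_trochanter", "umbilicus", "xiphoid")
}

# segment -> (proximal landmark, distal landmark)
sww_segment_landmarks <- function() {
  list(
    foot  = c("calcaneus", "fifth_metatarsal"),
    shank = c("femoral_epicondyle", "lateral_malleolus"),
    thigh = c("greater_trochanter", "femoral_epicondyle"),
    trunk = c("greater_trochanter", "xiphoid")
  )
}

#' Read a marker trajectory CSV
#'
#' Expects a header column `time` (s) plus `<landmark>_x` and `<landmark>_y`
#' (m) for the seven sagittal landmarks (fifth metatarsal, calcaneus, lateral
#' malleolus, femoral epicondyle, greater trochanter, umbilicus, xiphoid).
#' Time must be strictly increasing and uniformly sampled. Runs of up to 3
#' missing samples per column are linearly interpolated (and reported via a
#' message); longer gaps are rejected.
#'
#' @param path CSV file path.
#' @return An object of class `"marker_set"`: a list with `time`,
#'   `sampling_rate` and a `data.frame` `xy` holding the marker columns.
#' @export
read_markers <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE)
  as_marker_set(df)
}

#' Build a marker set from a data frame
#'
#' Same validation as [read_markers()] but starting from an in-memory
#' `data.frame` (as produced by [generate_gait_trial()]).
#'
#' @param df `data.frame` with a `time` column and `<landmark>_x`/`_y` pairs.
#' @return A `"marker_set"` object.
#' @export
as_marker_set <- function(df) {
  if (!"time" %in% names(df)) stop("missing 'time' column", call. = FALSE)
  needed <- as.vector(t(outer(sww_landmarks(), c("_x", "_y"), paste0)))
  absent <- setdiff(needed, names(df))
  if (length(absent) > 0) {
    stop("missing landmark column(s): ", paste(absent, collapse = ", "),
         call. = FALSE)
  }
  time <- df$time
  dt <- diff(time)
  if (any(dt <= 0)) stop("time must be strictly increasing", call. = FALSE)
  if (max(dt) - min(dt) > 1e-6 * stats::median(dt)) {
    stop("time must be uniformly sampled", call. = FALSE)
  }
  xy <- df[needed]
  n_interp <- 0L
  for (col in needed) {
    v <- xy[[col]]
    if (anyNA(v)) {
      runs <- rle(is.na(v))
      if (any(runs$lengths[runs$values] > 3L)) {
        stop(sprintf("gap longer than 3 samples in '%s'", col), call. = FALSE)
      }
      if (is.na(v[1]) || is.na(v[length(v)])) {
        stop(sprintf("missing samples at series edge in '%s'", col),
             call. = FALSE)
      }
      n_interp <- n_interp + sum(is.na(v))
      xy[[col]] <- stats::approx(time[!is.na(v)], v[!is.na(v)], xout = time)$y
    }
  }
  if (n_interp > 0) {
    message(sprintf("interpolated %d missing marker sample(s)", n_interp))
  }
  structure(
    list(time = time, sampling_rate = 1 / stats::median(dt), xy = xy),
    class = "marker_set"
  )
}

#' Write a marker set to CSV
#' @param markers A `"marker_set"`.
#' @param path Output CSV path.
#' @export
write_markers <- function(markers, path) {
  utils::write.csv(cbind(time = markers$time, markers$xy), path,
                   row.names = FALSE)
  invisible(path)
}

#' Zero-phase low-pass Butterworth filter
#'
#' Applies a 2nd-order (by default) low-pass Butterworth filter forwards and
#' backwards, giving zero phase distortion and an effective 4th-order
#' magnitude response.
#'
#' @param x Numeric series.
#' @param cutoff Cutoff frequency (Hz); must be below the Nyquist frequency.
#' @param sampling_rate Sampling rate (Hz).
#' @param order Filter order per pass (default 2).
#' @return Filtered series, same length as `x`.
#' @export
lowpass_filter <- function(x, cutoff, sampling_rate, order = 2L) {
  if (!is.finite(cutoff) || cutoff <= 0 || cutoff >= sampling_rate / 2) {
    stop("cutoff must lie in (0, Nyquist)", call. = FALSE)
  }
  bf <- signal::butter(order, cutoff / (sampling_rate / 2), type = "low")
  # odd-reflection padding keeps the forward-backward pass transient out of
  # the returned samples (the filter itself starts from zero state)
  n <- length(x)
  pad <- min(n - 1L, as.integer(ceiling(6 * sampling_rate / cutoff)))
  xp <- if (pad > 0) {
    c(2 * x[1] - x[(pad + 1L):2], x, 2 * x[n] - x[(n - 1L):(n - pad)])
  } else {
    x
  }
  y <- as.numeric(signal::filtfilt(bf, xp))
  y[(pad + 1L):(pad + n)]
}

#' Low-pass filter every marker channel
#'
#' @param markers A `"marker_set"`.
#' @param cutoff Cutoff (Hz), default 4.5 — the midpoint of the 4–5 Hz band
#'   conventionally used for slow walking kinematics.
#' @param order Butterworth order per pass, default 2.
#' @return A filtered `"marker_set"`.
#' @export
filter_markers <- function(markers, cutoff = 4.5, order = 2L) {
  markers$xy[] <- lapply(markers$xy, lowpass_filter,
                         cutoff = cutoff,
                         sampling_rate = markers$sampling_rate,
                         order = order)
  markers
}

# central-difference derivative on a uniform grid (one-sided at the edges)
central_diff <- function(x, dt) {
  n <- length(x)
  d <- numeric(n)
  if (n >= 3) d[2:(n - 1)] <- (x[3:n] - x[1:(n - 2)]) / (2 * dt)
  d[1] <- (x[2] - x[1]) / dt
  d[n] <- (x[n] - x[n - 1]) / dt
  d
}

#' Segment angular and linear states from marker trajectories
#'
#' For each modelled segment (foot, shank, thigh, trunk) the bounding
#' landmark pair defines the segment axis. The angle from vertical is
#' `atan2(dx, -dy)` with `d = distal - proximal` (zero when the distal end
#' hangs straight below the proximal end; the trunk, whose distal landmark
#' is above, sits near pi). Angular velocity is the central difference of
#' the unwrapped angle; endpoint linear velocities are central differences
#' of the marker positions.
#'
#' @param markers A (filtered) `"marker_set"`.
#' @return An object of class `"segment_states"`: list with `time`,
#'   `sampling_rate` and per-segment lists holding `prox_x`, `prox_y`,
#'   `dist_x`, `dist_y`, `theta`, `omega`, `vx_prox`, `vy_prox`, `vx_dist`,
#'   `vy_dist`.
#' @export
segment_states <- function(markers) {
  dt <- 1 / markers$sampling_rate
  xy <- markers$xy
  segs <- lapply(sww_segment_landmarks(), function(lm) {
    px <- xy[[paste0(lm[1], "_x")]]; py <- xy[[paste0(lm[1], "_y")]]
    dx <- xy[[paste0(lm[2], "_x")]]; dy <- xy[[paste0(lm[2], "_y")]]
    ax <- dx - px; ay <- dy - py
    len <- sqrt(ax^2 + ay^2)
    if (any(len < 1e-9)) {
      stop("coincident landmarks: zero-length segment", call. = FALSE)
    }
    theta <- unwrap_angle(atan2(ax, -ay))
    list(prox_x = px, prox_y = py, dist_x = dx, dist_y = dy,
         length = len, theta = theta, omega = central_diff(theta, dt),
         vx_prox = central_diff(px, dt), vy_prox = central_diff(py, dt),
         vx_dist = central_diff(dx, dt), vy_dist = central_diff(dy, dt))
  })
  structure(list(time = markers$time, sampling_rate = markers$sampling_rate,
                 segments = segs),
            class = "segment_states")
}

unwrap_angle <- function(theta) {
  d <- diff(theta)
  jumps <- cumsum(c(0, round(d / (2 * pi))))
  theta - 2 * pi * jumps
}

#' Detect strides from calcaneus contact events
#'
#' A foot is "in contact" when the calcaneus is within `height_threshold` of
#' the floor and its horizontal speed is below `speed_threshold` — standard
#' thresholds for slow walking, exposed as arguments. Strides run from one
#' contact onset to the next. Stride length is the horizontal displacement
#' of the greater trochanter over the stride; the walking speed is stride
#' length over stride duration. The contralateral foot's contact pattern is
#' taken as the ipsilateral one shifted by half a stride (only one body side
#' is digitised), and the forward displacement of the trochanter during the
#' ipsilateral single-support window gives `L_sc`.
#'
#' @param markers A filtered `"marker_set"`.
#' @param floor_height Pool-floor height in the marker frame (m), default 0.
#' @param height_threshold Contact height band above the floor (m),
#'   default 0.02.
#' @param speed_threshold Contact horizontal-speed bound (m/s), default 0.05.
#' @return A `data.frame` of class `"stride_metrics"` with columns
#'   `stride`, `start`, `end` (sample indices), `duration` (s), `SL` (m),
#'   `v` (m/s), `L_sc` (m). The logical contact series is attached as
#'   attribute `"contact"` (and `"contact_contra"`).
#' @export
detect_strides <- function(markers, floor_height = 0,
                           height_threshold = 0.02, speed_threshold = 0.05) {
  dt <- 1 / markers$sampling_rate
  heel_y <- markers$xy$calcaneus_y
  heel_vx <- central_diff(markers$xy$calcaneus_x, dt)
  contact <- heel_y < (floor_height + height_threshold) &
    abs(heel_vx) < speed_threshold
  onsets <- which(diff(c(FALSE, contact)) == 1)
  # drop spurious one-sample contacts
  onsets <- onsets[vapply(onsets, function(i) {
    all(contact[i:min(i + 2L, length(contact))])
  }, logical(1))]
  if (length(onsets) >= 2) {
    # noise blips just before true contact create onset clusters; keep the
    # last onset of each cluster (gap below half the median stride spacing)
    med <- stats::median(diff(onsets))
    keep <- c(diff(onsets) >= 0.5 * med, TRUE)
    onsets <- onsets[keep]
  }
  if (length(onsets) < 2) {
    stop("no strides: fewer than 2 contact onsets detected", call. = FALSE)
  }
  hip_x <- markers$xy$greater_trochanter_x
  half <- round(mean(diff(onsets)) / 2)
  contra <- shift_series(contact, half)
  strides <- lapply(seq_len(length(onsets) - 1), function(k) {
    i0 <- onsets[k]; i1 <- onsets[k + 1]
    sl <- hip_x[i1] - hip_x[i0]
    dur <- (i1 - i0) * dt
    # ipsilateral single support: this foot down, contralateral foot up
    win <- i0:(i1 - 1)
    ss <- win[contact[win] & !contra[win]]
    l_sc <- if (length(ss) >= 2) {
      runs <- split(ss, cumsum(c(1, diff(ss) != 1)))
      main <- runs[[which.max(lengths(runs))]]
      hip_x[max(main)] - hip_x[min(main)]
    } else NA_real_
    data.frame(stride = k, start = i0, end = i1, duration = dur,
               SL = sl, v = sl / dur, L_sc = l_sc)
  })
  out <- do.call(rbind, strides)
  if (all(out$SL <= 0)) stop("no strides: no forward progression", call. = FALSE)
  attr(out, "contact") <- contact
  attr(out, "contact_contra") <- contra
  attr(out, "half_stride_samples") <- half
  class(out) <- c("stride_metrics", "data.frame")
  out
}

# circular shift keeps the periodic stance pattern intact at the edges
shift_series <- function(x, by) {
  n <- length(x)
  by <- ((by %% n) + n) %% n
  if (by == 0) return(x)
  c(x[(n - by + 1):n], x[1:(n - by)])
}
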