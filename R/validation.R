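#' Predicted-vs-measured agreement
#'
#' Per-group ratio of means `mean(pred) / mean(meas)` and the overall
#' coefficient of determination of the predictions taken directly as
#' estimates of the measurements, `R^2 = 1 - SS_res / SS_tot` with
#' `SS_res = sum((meas - pred)^2)`.
#'
#' @param pred,meas Paired numeric vectors; `meas` must be positive.
#' @param group Optional grouping factor (e.g. immersion depth) for the
#'   per-group ratios.
#' @return List with `ratios` (named per-group, or a single `overall`
#'   element) and `r_squared`.
#' @export
prediction_agreement <- function(pred, meas, group = NULL) {
  if (length(pred) != length(meas)) {
    stop("pred and meas must have the same length", call. = FALSE)
  }
  if (any(meas <= 0)) stop("measured values must be positive", call. = FALSE)
  ratios <- if (is.null(group)) {
    c(overall = mean(pred) / mean(meas))
  } else {
    r <- tapply(pred, group, mean) / tapply(meas, group, mean)
    stats::setNames(as.vector(r), names(r))
  }
  r2 <- 1 - sum((meas - pred)^2) / sum((meas - mean(meas))^2)
  list(ratios = ratios, r_squared = r2)
}

#' Leave-one-out cross-validated R^2
#'
#' Leaves out one unit (participant) at a time, refits the model's fitted
#' component — by default a linear calibration of measured on predicted
#' cost, `lm(formula)` — on the remaining units, predicts the left-out
#' unit, and pools all out-of-sample predictions into a single
#' `R^2 = 1 - SS_res / SS_tot` against the observed response.
#'
#' @param formula Model formula, e.g. `cot_measured ~ cot_predicted`.
#' @param data `data.frame` holding the variables and the unit column.
#' @param unit Name of the column identifying the leave-out unit.
#' @return Cross-validated R^2 (scalar).
#' @export
loocv_r2 <- function(formula, data, unit) {
  units <- unique(data[[unit]])
  if (length(units) < 3) stop("need at least 3 units", call. = FALSE)
  response <- all.vars(formula)[1]
  pred <- rep(NA_real_, nrow(data))
  for (u in units) {
    hold <- data[[unit]] == u
    fit <- stats::lm(formula, data = data[!hold, , drop = FALSE])
    pred[hold] <- stats::predict(fit, newdata = data[hold, , drop = FALSE])
  }
  obs <- data[[response]]
  1 - sum((obs - pred)^2) / sum((obs - mean(obs))^2)
}

#' Bootstrap confidence interval for the prediction R^2
#'
#' Resamples units (participants) with replacement, recomputes the
#' predicted-vs-measured R^2 of [prediction_agreement()] on each resample,
#' and returns the bootstrap mean with the 2.5/97.5 percentile interval.
#' Deterministic for a fixed seed.
#'
#' @param data `data.frame` with prediction, measurement and unit columns.
#' @param pred,meas,unit Column names.
#' @param n_iter Bootstrap iterations, default 1000.
#' @param seed Integer seed (required, recorded in the output).
#' @return List with `mean`, `ci` (length-2), `n_iter`, `seed`,
#'   `replicates`.
#' @export
bootstrap_r2_ci <- function(data, pred = "cot_predicted",
                            meas = "cot_measured", unit = "participant_id",
                            n_iter = 1000L, seed) {
  if (nrow(data) == 0) stop("empty dataset", call. = FALSE)
  if (missing(seed)) stop("seed is required", call. = FALSE)
  if (n_iter < 1) stop("n_iter must be at least 1", call. = FALSE)
  units <- unique(data[[unit]])
  by_unit <- split(seq_len(nrow(data)), data[[unit]])[as.character(units)]
  p <- data[[pred]]; m <- data[[meas]]
  set.seed(seed)
  reps <- vapply(seq_len(n_iter), function(i) {
    idx <- unlist(by_unit[sample.int(length(units), replace = TRUE)],
                  use.names = FALSE)
    mm <- m[idx]; pp <- p[idx]
    1 - sum((mm - pp)^2) / sum((mm - mean(mm))^2)
  }, numeric(1))
  list(mean = mean(reps),
       ci = unname(stats::quantile(reps, c(0.025, 0.975))),
       n_iter = n_iter, seed = seed, replicates = reps)
}

#' Sensitivity of the predicted cost to input perturbations
#'
#' Recomputes the predicted cost of transport with one input at a time
#' scaled by `1 - delta` and `1 + delta` (default 10%), from a baseline
#' state of mechanical components. Conventions:
#' * `efficiency` — enters only the cost denominator, so the response is
#'   exactly inverse-proportional.
#' * `mass` — by default (`mass_mode = "denominator_only"`) also enters only
#'   the denominator (the apparent weight is held fixed), mirroring the
#'   efficiency response; `"propagate"` additionally rescales `GRF_v`.
#' * `speed` — rescales the drag force by the square of the speed ratio
#'   (pressure drag is quadratic in velocity); stride length held fixed.
#' * `stride_length` — propagates into the drag work (`W_D = DrF * SL`),
#'   into the single-support displacement (`L_sc` proportional to `SL`)
#'   and hence the vertical work, and into the cost denominator.
#'
#' @param state List with `drf` (N), `sl` (m), `l_sc` (m), `l_leg` (m),
#'   `grf_v` (N), `mass` (kg), `efficiency`.
#' @param parameters Which inputs to perturb.
#' @param delta Relative perturbation, default 0.1.
#' @param mass_mode `"denominator_only"` (default) or `"propagate"`.
#' @return A `data.frame` with `parameter`, `change_minus_pct`,
#'   `change_plus_pct`, `mean_abs_pct`; baseline cost as attribute
#'   `"baseline_cot"`.
#' @export
sensitivity <- function(state,
                        parameters = c("efficiency", "mass", "speed",
                                       "stride_length"),
                        delta = 0.1,
                        mass_mode = c("denominator_only", "propagate")) {
  mass_mode <- match.arg(mass_mode)
  known <- c("efficiency", "mass", "speed", "stride_length")
  bad <- setdiff(parameters, known)
  if (length(bad) > 0) {
    stop("unknown parameter(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  cot_of <- function(st) {
    w_d <- horizontal_work(st$drf, st$sl)
    w_v <- vertical_work(st$grf_v,
                         com_vertical_displacement(st$l_leg, st$l_sc))
    cot_predicted(total_work(w_d, w_v), st$sl, st$mass, st$efficiency)
  }
  baseline <- cot_of(state)
  if (baseline <= 0) stop("baseline predicted cost must be positive",
                          call. = FALSE)
  perturb <- function(par, k) {
    st <- state
    if (par == "efficiency") st$efficiency <- st$efficiency * k
    if (par == "mass") {
      st$mass <- st$mass * k
      if (mass_mode == "propagate") st$grf_v <- st$grf_v * k
    }
    if (par == "speed") st$drf <- st$drf * k^2
    if (par == "stride_length") {
      st$sl <- st$sl * k
      st$l_sc <- st$l_sc * k
    }
    (cot_of(st) / baseline - 1) * 100
  }
  rows <- lapply(parameters, function(par) {
    lo <- perturb(par, 1 - delta)
    hi <- perturb(par, 1 + delta)
    data.frame(parameter = par, change_minus_pct = lo, change_plus_pct = hi,
               mean_abs_pct = mean(abs(c(lo, hi))))
  })
  out <- do.call(rbind, rows)
  attr(out, "baseline_cot") <- baseline
  out
}

#' Correlations of cost with the kinetic determinants
#'
#' Pearson correlations (with two-sided p-values) of the measured cost of
#' transport with the stride drag force and with the stride-mean vertical
#' ground reaction force.
#'
#' @param cot,drf,grf_v Numeric vectors of equal length (>= 3).
#' @return A `data.frame` with `variable`, `r`, `p`.
#' @export
cot_correlations <- function(cot, drf, grf_v) {
  if (length(cot) < 3) stop("need at least 3 observations", call. = FALSE)
  one <- function(x, name) {
    if (stats::sd(x) == 0 || stats::sd(cot) == 0) {
      stop("zero variance in ", name, call. = FALSE)
    }
    ct <- stats::cor.test(cot, x)
    data.frame(variable = name, r = unname(ct$estimate), p = ct$p.value)
  }
  rbind(one(drf, "drf"), one(grf_v, "grf_v"))
}
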