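test_that("surface fitting recovers exact coefficients from noiseless data", {
  truth <- study_surface()
  grid <- expand.grid(speed = c(0.2, 0.35, 0.5, 0.65, 0.8),
                      depth = c(0.5, 0.7, 0.9, 1.1, 1.3))
  grid$cot <- evaluate_surface(truth, grid$speed, grid$depth)
  fit <- fit_surface(grid)
  expect_equal(fit$coefficients, truth$coefficients, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)

  expect_error(fit_surface(grid[1:5, ]), "at least 6")
  collinear <- data.frame(speed = seq(0.2, 0.8, length.out = 8),
                          depth = 1, cot = 1:8)
  expect_error(fit_surface(collinear), "rank-deficient")
})

test_that("the reference surface reproduces the study's fit quality", {
  cond <- study_condition_means()
  fit <- fit_surface(data.frame(speed = cond$speed, depth = cond$depth,
                                cot = cond$cot))
  # a fresh least-squares fit to the condition means at nominal speeds can
  # only explain them at least as well as the published coefficients
  expect_gte(fit$r_squared, 0.98)
  # the published coefficients themselves reproduce the published fit quality
  pred <- evaluate_surface(study_surface(), cond$speed, cond$depth)
  r2 <- 1 - sum((cond$cot - pred)^2) / sum((cond$cot - mean(cond$cot))^2)
  expect_equal(round(r2, 2), 0.98)
})

test_that("surface evaluation matches printed spot values", {
  surf <- study_surface()
  expect_equal(round(evaluate_surface(surf, 0.8, 1.3), 1), 13.0)
  expect_equal(round(evaluate_surface(surf, 0.54, 0.85), 1), 4.1)
  expect_equal(evaluate_surface(surf, 0, 0, extrapolate = TRUE), 10.52)
  expect_warning(evaluate_surface(surf, 1.5, 1.0), "outside")
})

test_that("extrema search is exact for saddles and bowls", {
  surf <- study_surface()
  a <- surf$coefficients
  # indefinite Hessian: a saddle, so both extrema must sit on the boundary
  expect_lt(4 * a[["speed2"]] * a[["depth2"]] - a[["speed_depth"]]^2, 0)
  ext <- surface_extrema(surf)
  expect_equal(round(ext$maximum$cot, 1), 13.0)
  expect_equal(ext$maximum$speed, 0.8)
  expect_equal(ext$maximum$depth, 1.3)
  expect_false(ext$minimum$location == "interior")
  expect_false(ext$maximum$location == "interior")

  bowl <- surface_model(c(speed2 = 1, depth2 = 1, speed_depth = 0,
                          speed = 0, depth = 0, intercept = 0),
                        speed_range = c(-1, 1), depth_range = c(-1, 1))
  bext <- surface_extrema(bowl)
  expect_equal(bext$minimum$cot, 0)
  expect_equal(c(bext$minimum$speed, bext$minimum$depth), c(0, 0))
  expect_identical(bext$minimum$location, "interior")
  expect_equal(bext$maximum$cot, 2)

  expect_error(surface_extrema(surf, speed_bounds = c(0.5, 0.5)),
               "degenerate")

  # extrema bound every value on a dense grid
  g <- expand.grid(speed = seq(0.2, 0.8, length.out = 100),
                   depth = seq(0.5, 1.3, length.out = 100))
  v <- evaluate_surface(surf, g$speed, g$depth)
  expect_lte(ext$minimum$cot, min(v) + 1e-9)
  expect_gte(ext$maximum$cot, max(v) - 1e-9)
})

test_that("per-depth curves classify J-shaped vs monotone responses", {
  knee <- per_depth_curve(c(0.2, 0.4, 0.6, 0.8), c(2.7, 2.8, 3.3, 4.4),
                          name = "knee")
  expect_gt(knee$coefficients[1], 0)
  expect_identical(knee$shape, "interior_minimum")
  expect_true(knee$vertex_speed > 0.2 && knee$vertex_speed < 0.8)

  lin <- per_depth_curve(c(0.2, 0.4, 0.6, 0.8), c(1, 2, 3, 4))
  expect_identical(lin$shape, "monotone")
  expect_equal(lin$coefficients[1], 0, tolerance = 1e-9)

  sym <- per_depth_curve(c(0.2, 0.5, 0.8), c(1.09, 1, 1.09))
  expect_equal(sym$vertex_speed, 0.5, tolerance = 1e-6)

  expect_error(per_depth_curve(c(0.2, 0.4), c(1, 2)), "3 speeds")
})

test_that("iso-cost intersection solves the quadratic difference exactly", {
  a <- cot_curve(c(0, 0, 3), c(0, 2), "flat")
  b <- cot_curve(c(1, 0, 2), c(0, 2), "parabola")
  pts <- iso_cost_speed(a, b, c(0, 2))
  expect_equal(pts$speed, 1)
  expect_equal(pts$cot, 3)
  # residual check at the root
  expect_lt(abs(evaluate_curve(a, pts$speed, FALSE) -
                  evaluate_curve(b, pts$speed, FALSE)), 1e-9)

  same <- iso_cost_speed(a, a, c(0, 2))
  expect_true(attr(same, "degenerate"))
  expect_equal(nrow(same), 0)

  offset <- cot_curve(c(0, 0, 4), c(0, 2), "flat+1")
  expect_equal(nrow(iso_cost_speed(a, offset, c(0, 2))), 0)

  # at most two roots for quadratic-quadratic differences
  c1 <- cot_curve(c(2, -3, 2), c(0, 3), "c1")
  c2 <- cot_curve(c(-1, 2, 1), c(0, 3), "c2")
  expect_lte(nrow(iso_cost_speed(c1, c2, c(-10, 10))), 2)
})

test_that("self-selected summary converts units consistently", {
  surf <- study_surface()
  ss <- self_selected_summary(surf, study_self_selected_speeds(),
                              c(knee = 0.5, hip = 0.85,
                                umbilicus = 1.12, xiphoid = 1.3))
  hip <- ss[ss$depth_label == "hip", ]
  expect_equal(round(hip$cot, 1), 4.1)
  expect_equal(round(hip$power, 1), 2.2)
  expect_equal(ss$power / (ss$cot * ss$speed), rep(1, 4))
  expect_equal(ss$met, ss$vo2 / 3.5)
  expect_equal(ss$cal, ss$power * 60 / 4.186)
  expect_error(self_selected_summary(surf, c(hip = -1), c(hip = 0.85)),
               "positive")
})

test_that("reference curves load from JSON with declared ranges", {
  path <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(
    list(list(name = "dryland_walking", coefficients = c(4.4, -8.0, 5.7),
              speed_range = c(0.2, 2.0))),
    path, auto_unbox = TRUE, digits = NA
  )
  curves <- read_reference_curves(path)
  expect_named(curves, "dryland_walking")
  expect_warning(evaluate_curve(curves[[1]], 2.5), "outside")
  expect_silent(evaluate_curve(curves[[1]], 1.0))
})
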