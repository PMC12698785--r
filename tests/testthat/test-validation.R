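test_that("prediction agreement reports ratios and R^2 from first principles", {
  meas <- c(2, 3, 4, 5, 6, 8)
  grp <- c("a", "a", "a", "b", "b", "b")
  perfect <- prediction_agreement(meas, meas, grp)
  expect_equal(unname(perfect$ratios), c(1, 1))
  expect_equal(perfect$r_squared, 1)

  pred <- 0.8 * meas
  ag <- prediction_agreement(pred, meas, grp)
  expect_equal(unname(ag$ratios), c(0.8, 0.8))
  # brute-force sums of squares
  r2_direct <- 1 - sum((meas - pred)^2) / sum((meas - mean(meas))^2)
  expect_equal(ag$r_squared, r2_direct)

  expect_error(prediction_agreement(1:3, 1:4), "length")
  expect_error(prediction_agreement(1:3, c(1, 0, 2)), "positive")
})

test_that("LOOCV is exact on noiseless data and honest on pure noise", {
  df <- data.frame(participant_id = rep(1:5, each = 4),
                   cot_predicted = runif(20, 1, 10))
  df$cot_measured <- df$cot_predicted
  expect_equal(loocv_r2(cot_measured ~ cot_predicted, df, "participant_id"),
               1, tolerance = 1e-6)

  set.seed(17)
  vals <- replicate(300, {
    d <- data.frame(participant_id = rep(1:9, each = 16),
                    p = rnorm(144), m = rnorm(144))
    loocv_r2(m ~ p, d, "participant_id")
  })
  expect_lt(mean(vals), 0)

  two <- df[df$participant_id <= 2, ]
  expect_error(loocv_r2(cot_measured ~ cot_predicted, two, "participant_id"),
               "3 units")
})

test_that("LOOCV does not exceed in-sample fit quality on noisy cohorts", {
  set.seed(29)
  diffs <- replicate(100, {
    d <- data.frame(participant_id = rep(1:8, each = 6))
    d$p <- runif(48, 1, 10)
    d$m <- d$p + rnorm(48, 0, 2)
    fit <- lm(m ~ p, d)
    r2_in <- summary(fit)$r.squared
    r2_in - loocv_r2(m ~ p, d, "participant_id")
  })
  expect_gt(mean(diffs), 0)
})

test_that("bootstrap CI is deterministic and degenerate on replicated data", {
  df <- data.frame(participant_id = rep(1:6, each = 4),
                   cot_predicted = rep(c(1, 2, 3, 4), 6),
                   cot_measured = rep(c(1.1, 1.9, 3.2, 4.1), 6))
  b1 <- bootstrap_r2_ci(df, n_iter = 200, seed = 7)
  b2 <- bootstrap_r2_ci(df, n_iter = 200, seed = 7)
  expect_identical(b1$replicates, b2$replicates)
  # every participant carries identical data: zero-width interval
  expect_equal(diff(b1$ci), 0, tolerance = 1e-12)
  expect_equal(b1$mean, b1$ci[[1]])
  expect_true(b1$ci[1] <= b1$mean && b1$mean <= b1$ci[2])
  expect_error(bootstrap_r2_ci(df[0, ], seed = 1), "empty")
  expect_error(bootstrap_r2_ci(df, n_iter = 100), "seed")
})

test_that("sensitivity identities hold analytically", {
  state <- list(drf = 50, sl = 0.8, l_sc = 0.32, l_leg = 0.9,
                grf_v = 400, mass = 77, efficiency = 0.25)
  s <- sensitivity(state)
  eff <- s[s$parameter == "efficiency", ]
  expect_equal(eff$change_minus_pct, 100 / 0.9 - 100, tolerance = 1e-9)
  expect_equal(eff$change_plus_pct, 100 / 1.1 - 100, tolerance = 1e-9)
  expect_equal(eff$mean_abs_pct, 10.101, tolerance = 1e-3)

  # mass mirrors efficiency when the apparent weight is held fixed
  mass <- s[s$parameter == "mass", ]
  expect_equal(mass$change_minus_pct, eff$change_minus_pct)
  expect_equal(mass$change_plus_pct, eff$change_plus_pct)

  # drag-dominated limit: speed perturbation is purely quadratic
  dragged <- sensitivity(list(drf = 120, sl = 0.8, l_sc = 0, l_leg = 0.9,
                              grf_v = 0, mass = 77, efficiency = 0.25),
                         parameters = "speed")
  expect_equal(dragged$change_minus_pct, -19, tolerance = 1e-9)
  expect_equal(dragged$change_plus_pct, 21, tolerance = 1e-9)
  expect_equal(dragged$mean_abs_pct, 20, tolerance = 1e-9)

  none <- sensitivity(state, parameters = "speed", delta = 0)
  expect_equal(none$mean_abs_pct, 0)

  expect_error(sensitivity(state, parameters = "cadence"), "unknown")
})

test_that("mass propagation mode changes only the vertical-work share", {
  state <- list(drf = 50, sl = 0.8, l_sc = 0.32, l_leg = 0.9,
                grf_v = 400, mass = 77, efficiency = 0.25)
  prop <- sensitivity(state, parameters = "mass", mass_mode = "propagate")
  denom <- sensitivity(state, parameters = "mass")
  # propagating mass into GRF_v damps the inverse response
  expect_lt(prop$mean_abs_pct, denom$mean_abs_pct)
})

test_that("correlations recover exact and null relationships", {
  x <- c(1, 2, 4, 7, 9, 12)
  r <- cot_correlations(2 * x, x, -x + 100)
  expect_equal(r$r[r$variable == "drf"], 1)
  expect_equal(r$r[r$variable == "grf_v"], -1)

  set.seed(5)
  a <- rnorm(100); b <- rnorm(100); c <- rnorm(100)
  rr <- cot_correlations(a, b, c)
  expect_true(all(abs(rr$r) < 0.2))

  expect_error(cot_correlations(c(1, 1, 1), x[1:3], x[1:3]), "zero variance")
  expect_error(cot_correlations(1:2, 1:2, 1:2), "3 observations")
})
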