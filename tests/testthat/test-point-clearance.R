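test_that("exactly linear calibration recovers the response factor with zero residual", {
  ds <- depletion_dataset("DTX-C", rbind(make_cells_rows(), make_cal_rows()))
  cal <- fit_calibration(ds)
  expect_equal(cal$response_factor, 2.0)
  expect_equal(cal$fit_residual_sd, 0)
})

test_that("calibration under known multiplicative noise matches the closed-form zero-intercept OLS", {
  levels <- c(0.1, 0.5, 1)
  noise <- c(1.10, 0.95, 1.02)   # fixed known perturbations
  y <- 2 * levels * noise
  rows <- rbind(make_cells_rows(),
                data.frame(time_min = 0, condition = "calibration",
                           replicate = 1L, response = y,
                           has_internal_standard = TRUE,
                           nominal_conc_uM = levels))
  cal <- fit_calibration(depletion_dataset("DTX-C", rows))
  expect_equal(cal$response_factor, sum(levels * y) / sum(levels^2),
               tolerance = 1e-12)
})

test_that("a single calibration level is a calibration error", {
  rows <- rbind(make_cells_rows(), make_cal_rows(levels = c(1, 1)))
  expect_error(fit_calibration(depletion_dataset("DTX-C", rows)),
               "calibration error")
})

test_that("quantification divides by the response factor and flags censoring", {
  ds <- depletion_dataset("DTX-C", rbind(make_cells_rows(), make_cal_rows()),
                          loq_uM = 0.05)
  cal <- fit_calibration(ds)
  q <- quantify(ds, cal)
  expect_equal(unique(q$conc_uM[q$condition == "cells"]), 0.5)  # 1.0 / 2.0

  ds0 <- depletion_dataset("DTX-C", rbind(
    make_cells_rows(response_fun = function(t) ifelse(t == 240, 0, 1)),
    make_cal_rows()), loq_uM = 0.05)
  q0 <- quantify(ds0, fit_calibration(ds0))
  z <- q0[q0$condition == "cells" & q0$time_min == 240, ]
  expect_true(all(z$conc_uM == 0))
  expect_true(all(z$censored))
})

test_that("quantifying noiseless simulated data recovers the generating C(t) exactly", {
  truth <- simulation_truth("DTX-S", k_bio_true = 0.003, rf_true = 3.7,
                            noise_sd_true = 0, seed = 1)
  ds <- simulate_depletion(truth)$dataset
  q <- quantify(ds, fit_calibration(ds))
  cells <- q[q$condition == "cells", ]
  expect_equal(cells$conc_uM, exp(-0.003 * cells$time_min), tolerance = 1e-10)
})

test_that("a flat concentration series gives slope 0 with p = 1", {
  ds <- depletion_dataset("DTX-F", rbind(make_cells_rows(), make_cal_rows()))
  q <- quantify(ds, fit_calibration(ds))
  fit <- fit_log_linear(q[q$condition == "cells", ])
  expect_equal(fit$slope, 0)
  expect_equal(fit$p_value, 1)
})

test_that("noiseless exponential input recovers the generating rate to 10 significant digits", {
  ds <- make_exact_dataset(k = 0.005)
  q <- quantify(ds, fit_calibration(ds))
  fit <- fit_log_linear(q[q$condition == "cells", ])
  expect_equal(fit$slope, -0.005, tolerance = 1e-10)
  expect_lt(fit$p_value, 1e-6)
})

test_that("the slope estimator is unbiased: empirical mean within 2 MC-SE of truth", {
  k <- 0.004; n_rep <- 400
  slopes <- vapply(seq_len(n_rep), function(i) {
    tr <- simulation_truth("DTX-MC", k_bio_true = k, noise_sd_true = 0.15,
                           seed = 20000 + i)
    ds <- simulate_depletion(tr, include_controls = FALSE)$dataset
    q <- quantify(ds, fit_calibration(ds))
    fit_log_linear(q[q$condition == "cells", ])$slope
  }, numeric(1))
  mc_se <- sd(slopes) / sqrt(n_rep)
  expect_lt(abs(mean(slopes) - (-k)), 2 * mc_se + 1e-6)
})

test_that("the significance gate zeroes clearance above the cutoff and for apparent gains", {
  ds <- make_exact_dataset()
  fit <- list(slope = -0.001, slope_se = 0.002, p_value = 0.2,
              p_depletion = 0.2, n_obs = 15)
  est <- clint_from_fit(fit, ds)
  expect_false(est$significant)
  expect_equal(est$clint, 0)

  gain <- list(slope = 0.002, slope_se = 1e-5, p_value = 1e-8,
               p_depletion = 1, n_obs = 15)
  est2 <- clint_from_fit(gain, ds)
  expect_equal(est2$clint, 0)
  expect_false(est2$significant)
})

test_that("significant depletion converts to half-life and clearance by the rate identities", {
  ds <- make_exact_dataset()
  fit <- list(slope = -0.00347, slope_se = 1e-5, p_value = 1e-10,
              p_depletion = 1e-10, n_obs = 15)
  est <- clint_from_fit(fit, ds)
  expect_true(est$significant)
  expect_equal(est$half_life_min, log(2) / 0.00347, tolerance = 1e-12)
  expect_equal(est$clint, 0.00347 * 2000, tolerance = 1e-12)  # density 0.5
  # identity: half-life x rate = ln 2
  expect_equal(est$half_life_min * (-fit$slope), log(2), tolerance = 1e-12)
})

test_that("clearance is linear in the depletion rate with factor 1000/density", {
  ds <- make_exact_dataset()
  slopes <- -c(0.001, 0.002, 0.004, 0.008)
  clints <- vapply(slopes, function(s) {
    clint_from_fit(list(slope = s, p_value = 1e-9, p_depletion = 1e-9),
                   ds)$clint
  }, numeric(1))
  expect_equal(clints, -slopes * 1000 / ds$cell_density_millions_per_mL,
               tolerance = 1e-12)
  expect_true(all(diff(clints) > 0))  # more negative slope => larger clint
})

test_that("abiotic controls are assessed with the same regression machinery", {
  # flat controls: not significant, rate 0
  tr <- simulation_truth("DTX-AB", k_bio_true = 0.004, k_abio_true = 0,
                         noise_sd_true = 0, seed = 2)
  ds <- simulate_depletion(tr)$dataset
  ab <- assess_abiotic(ds, fit_calibration(ds))
  expect_false(ab$abiotic_significant)
  expect_equal(ab$abiotic_rate, 0)

  # controls decaying at 0.002/min noiselessly: significant, rate recovered
  tr2 <- simulation_truth("DTX-AB2", k_abio_true = 0.002, noise_sd_true = 0,
                          seed = 3)
  ds2 <- simulate_depletion(tr2)$dataset
  ab2 <- assess_abiotic(ds2, fit_calibration(ds2))
  expect_true(ab2$abiotic_significant)
  expect_equal(ab2$abiotic_rate, 0.002, tolerance = 1e-10)
})

test_that("datasets without controls yield an absent abiotic result with a warning", {
  tr <- simulation_truth("DTX-NC", seed = 4)
  ds <- simulate_depletion(tr, include_controls = FALSE)$dataset
  expect_warning(ab <- assess_abiotic(ds, fit_calibration(ds)), "no control")
  expect_null(ab$fit)
  expect_true(is.na(ab$abiotic_rate))
})

test_that("the panel summary counts zeros and takes the median over significant values", {
  s <- summarize_clint(c(0, 0, 0, 4.52))
  expect_equal(s$n_zero, 3)
  expect_equal(s$median_significant, 4.52)

  all_zero <- summarize_clint(c(0, 0))
  expect_true(is.na(all_zero$median_significant))
  expect_error(summarize_clint(numeric(0)), "empty")
})

test_that("full point pipeline recovers a strong signal end to end", {
  tr <- simulation_truth("DTX-E2E", k_bio_true = 0.0075, noise_sd_true = 0.1,
                         seed = 9)
  fit <- clint_point(simulate_depletion(tr)$dataset)
  expect_true(fit$estimate$significant)
  expect_equal(fit$estimate$clint, 15, tolerance = 0.25)
  expect_equal(unname(coef(fit)["clint"]), fit$estimate$clint)
  s <- summary(fit)
  expect_equal(s$chemical_id, "DTX-E2E")
  expect_lt(s$p_value, 1e-6)
  # predicted concentrations decay from ~C_test; residuals centred near 0
  pred <- predict(fit, times = c(0, 240))
  expect_gt(pred[1], pred[2])
  expect_equal(mean(residuals(fit)), 0, tolerance = 1e-10)  # OLS identity
  expect_output(print(fit), "significant depletion")
})
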