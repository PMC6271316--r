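dsc_grid <- seq(278.15, 383.15, by = 0.1)
flank_windows <- list(c(278.15, 303.15), c(368.15, 383.25))

test_that("an exactly cubic trace is zeroed by baseline correction", {
  coeffs <- c(0.8, -4e-3, 5e-5, -2e-7)
  cur <- gen_dsc_thermogram(list(transition(100, 330, dH_cal = 0)),
                            baseline_coeffs = coeffs, grid = dsc_grid)
  out <- fit_baseline(cur, flank_windows)
  expect_lt(max(abs(out$corrected$Cp)), 1e-9)
  expect_equal(out$baseline$coeffs, coeffs, tolerance = 1e-6)
})

test_that("baseline coefficients are recovered under a two-peak curve", {
  # sharp central transitions keep the edge windows signal-free, the way a
  # practitioner chooses baseline windows; broad transitions never reach
  # zero inside the scan and contaminate any window choice
  set.seed(7)
  coeffs <- c(runif(1, 1, 3), runif(1, 0.01, 0.03),
              runif(1, 1e-4, 3e-4), runif(1, 1e-6, 3e-6)) *
    sample(c(-1, 1), 4, replace = TRUE)
  trs <- list(transition(300, 330), transition(350, 336))
  raw <- gen_dsc_thermogram(trs, baseline_coeffs = coeffs, grid = dsc_grid)
  out <- fit_baseline(raw, list(c(278.15, 288.15), c(373.15, 383.25)))
  expect_true(all(rel_err(out$baseline$coeffs, coeffs) < 0.01))
  # corrected curve re-integrates to the clean enthalpy
  clean <- gen_dsc_thermogram(trs, grid = dsc_grid)
  expect_equal(total_enthalpy(out$corrected), total_enthalpy(clean),
               tolerance = 1e-3)
  # mean corrected Cp inside the windows is ~0
  inw <- raw$T < 288.15 | raw$T >= 373.15
  expect_lt(abs(mean(out$corrected$Cp[inw])), 1e-6)
})

test_that("windows overlapping the transition region corrupt the integral", {
  trs <- htel_transitions(htel$mer22)
  raw <- gen_dsc_thermogram(trs, baseline_coeffs = c(0.2, 1e-3, 0, 0),
                            grid = dsc_grid)
  bad <- fit_baseline(raw, list(c(278.15, 303.15), c(330.15, 345.15)))
  clean <- total_enthalpy(gen_dsc_thermogram(trs, grid = dsc_grid))
  expect_gt(rel_err(total_enthalpy(bad$corrected), clean), 0.05)
})

test_that("baseline fitting validates its windows", {
  cur <- gen_dsc_thermogram(list(transition(100, 330)), grid = dsc_grid)
  expect_error(fit_baseline(cur, list(c(278.15, 278.25), c(380, 380.1))),
               "at least 4")
  expect_error(fit_baseline(cur, list(c(250, 300), c(360, 380))), "inside")
  expect_error(fit_baseline(cur, list(c(280, 320), c(310, 330))), "overlap")
})

test_that("noiseless two-transition deconvolution is exact to 0.1%", {
  p <- htel$mer22
  trs <- htel_transitions(p)
  fit <- fit_non2state(gen_dsc_thermogram(trs, grid = dsc_grid), 2)
  expect_true(fit$converged)
  cf <- coef(fit)
  expect_lt(rel_err(cf[1, "dH_vH"], p$dH1), 0.001)
  expect_lt(rel_err(cf[2, "dH_vH"], p$dH2), 0.001)
  expect_lt(rel_err(cf[1, "Tm"], celsius_to_kelvin(p$Tm1)), 0.001)
  expect_lt(rel_err(cf[2, "Tm"], celsius_to_kelvin(p$Tm2)), 0.001)
  # the generating model reproduces its own curve to numerical noise
  expect_lt(fit$residual_rms, 1e-8)
})

test_that("deconvolution tolerates instrument-scale Gaussian noise", {
  p <- htel$mer22
  cur <- gen_dsc_thermogram(htel_transitions(p), grid = dsc_grid,
                            noise_sd = 0.05, seed = 42)
  fit <- fit_non2state(cur, 2)
  cf <- coef(fit)
  expect_true(fit$converged)
  expect_lt(rel_err(cf[1, "dH_vH"], p$dH1), 0.02)
  expect_lt(rel_err(cf[2, "dH_vH"], p$dH2), 0.02)
  expect_lt(rel_err(cf[1, "Tm"], celsius_to_kelvin(p$Tm1)), 0.02)
  expect_lt(rel_err(cf[2, "Tm"], celsius_to_kelvin(p$Tm2)), 0.02)
})

test_that("a single-transition model underfits a two-peak curve", {
  cur <- gen_dsc_thermogram(htel_transitions(htel$mer22), grid = dsc_grid,
                            noise_sd = 0.05, seed = 42)
  f2 <- fit_non2state(cur, 2)
  f1 <- fit_non2state(cur, 1)
  expect_true(f1$converged)
  expect_gt(f1$residual_rms, 5 * f2$residual_rms)
})

test_that("noiseless round trips recover parameters across the model range", {
  set.seed(23)
  for (i in 1:5) {
    dH <- runif(2, 40, 250)
    Tm1 <- runif(1, 310, 345)
    Tm2 <- Tm1 + runif(1, 6, 15)
    trs <- list(transition(dH[1], Tm1), transition(dH[2], Tm2))
    fit <- fit_non2state(gen_dsc_thermogram(trs, grid = dsc_grid), 2)
    cf <- coef(fit)
    expect_lt(rel_err(cf[1, "dH_vH"], dH[1]), 0.005)
    expect_lt(rel_err(cf[2, "dH_vH"], dH[2]), 0.005)
    expect_lt(rel_err(cf[1, "Tm"], Tm1), 0.005)
    expect_lt(rel_err(cf[2, "Tm"], Tm2), 0.005)
  }
})

test_that("amplitude-decoupled fits recover dH_cal independently of dH_vH", {
  p <- htel$mer22
  trs <- htel_transitions(p, scale_amplitudes = TRUE)
  fit <- fit_non2state(gen_dsc_thermogram(trs, grid = dsc_grid), 2,
                       free_amplitude = TRUE)
  cf <- coef(fit)
  expect_lt(rel_err(sum(cf[, "dH_cal"]), p$dH_tot), 0.005)
  expect_lt(rel_err(cf[1, "dH_vH"], p$dH1), 0.005)
})

test_that("the fit is invariant to initial-guess order and sorted by Tm", {
  trs <- htel_transitions(htel$mer22)
  cur <- gen_dsc_thermogram(trs, grid = dsc_grid)
  f_fwd <- fit_non2state(cur, 2, init = trs)
  f_rev <- fit_non2state(cur, 2, init = rev(trs))
  expect_equal(coef(f_fwd), coef(f_rev), tolerance = 1e-6)
  expect_true(all(diff(coef(f_fwd)[, "Tm"]) > 0))
})

test_that("degenerate monotone traces are flagged, not fatal", {
  Tg <- seq(300, 360, by = 0.5)
  cur <- thermogram(Tg, seq(0.01, 0.3, length.out = length(Tg)))
  fit <- fit_non2state(cur, 1)
  expect_true(fit$degenerate)
  expect_s3_class(fit, "non2state")
})

test_that("fit accessors are mutually consistent", {
  cur <- gen_dsc_thermogram(htel_transitions(htel$mer22), grid = dsc_grid,
                            noise_sd = 0.02, seed = 5)
  fit <- fit_non2state(cur, 2)
  expect_equal(fitted(fit) + residuals(fit), cur$Cp, tolerance = 1e-12)
  expect_equal(predict(fit), fitted(fit), tolerance = 1e-12)
  expect_equal(predict(fit, newdata = 340.35),
               excess_heat_capacity(340.35, fit$transitions))
  sims <- simulate(fit, nsim = 2, seed = 9)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "thermogram")
  expect_error(fit_non2state(cur, 0), "positive")
})
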