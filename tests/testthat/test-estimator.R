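test_that("binned drift profile matches brute-force step enumeration bit-exactly", {
  set.seed(17)
  # small input, enumerable by hand: 200 steps of a noisy drifting walk
  x <- cumsum(c(0, rnorm(200, mean = 0.002, sd = 0.05)))
  tr <- trajectory(seq(0, by = 1e-3, length.out = 201), x, 1e-3)
  dp <- suppressMessages(
    estimate_drift_profile(tr, MEDIUM, l = 0.1, n_min = 1L))
  bf <- brute_force_drift(x, 1e-3, MEDIUM$gamma, l = 0.1)
  pop <- dp[dp$n_steps > 0, ]
  expect_identical(pop$bin_center, bf$bin_center)
  expect_identical(pop$n_steps, as.integer(bf$n_steps))
  expect_identical(pop$mean_step, bf$mean_step)
  expect_identical(pop$force, bf$force)
})

test_that("constant drift is recovered exactly and bins below n_min are absent", {
  v <- 1.0                                        # um/s
  x <- v * seq(0, by = 1e-3, length.out = 2001)
  tr <- trajectory(seq(0, by = 1e-3, length.out = 2001), x, 1e-3)
  dp <- estimate_drift_profile(tr, MEDIUM, l = 0.1, n_min = 50L)
  pop <- dp[!is.na(dp$force), ]
  expect_gt(nrow(pop), 10)
  expect_equal(pop$force, rep(MEDIUM$gamma * v, nrow(pop)), tolerance = 1e-10)
  expect_true(all(is.na(dp$force[dp$n_steps < 50])))
  expect_error(estimate_drift_profile(tr, list(D = 3.8)), "medium_params")
})

test_that("free diffusion yields force estimates consistent with zero", {
  trs <- sim_clamp(0, duration = 50, n_traj = 20L, seed = 55L,
                   init = "point")
  frac <- unlist(lapply(trs, function(tr) {
    dp <- estimate_drift_profile(tr, MEDIUM, l = 0.1, n_min = 50L)
    ok <- !is.na(dp$force)
    abs(dp$force[ok]) < 3 * dp$se[ok]
  }))
  expect_gte(mean(frac), 0.99)
})

test_that("binned estimates track the true clamp force along the profile", {
  tr <- sim_clamp(10, duration = 50, n_traj = 1L, seed = 23L)[[1]]
  dp <- estimate_drift_profile(tr, MEDIUM, l = 0.1, n_min = 50L)
  pop <- dp[!is.na(dp$force), ]
  truth <- clamp_force(pop$bin_center, clamp_params(10, 0, 0.3))
  expect_gte(mean(abs(pop$force - truth) <= 3 * pop$se), 0.95)
})

test_that("the clamp-model fit recovers a noiseless profile to machine precision", {
  p <- clamp_params(F0 = 10, x0 = 0.2, h = 0.4)
  bins <- seq(-2.8, 3.2, by = 0.1)
  dp <- structure(data.frame(bin_center = bins, n_steps = 1000L,
                             mean_step = NA_real_,
                             force = clamp_force(bins, p),
                             se = rep(0.01, length(bins))),
                  class = c("drift_profile", "data.frame"),
                  l = 0.1, gamma = MEDIUM$gamma, frame_dt = 1e-3)
  fit <- fit_clamp_model(dp)
  expect_false(fit$flagged)
  expect_equal(fit$F0_hat, 10, tolerance = 1e-6)
  expect_equal(fit$x0_hat, 0.2, tolerance = 1e-6)
  expect_equal(fit$h_hat, 0.4, tolerance = 1e-6)
  expect_true(isSymmetric(fit$cov, tol = 1e-8))
  expect_true(all(eigen(fit$cov, only.values = TRUE)$values > -1e-12))
})

test_that("simulated clamp fits are unbiased with calibrated intervals", {
  trs <- sim_clamp(7.4, duration = 50, n_traj = 20L, seed = 71L,
                   sigma = 0.01)
  fits <- lapply(trs, function(tr)
    fit_clamp_model(estimate_drift_profile(tr, MEDIUM)))
  F0s <- vapply(fits, `[[`, 0, "F0_hat")
  ses <- vapply(fits, function(f) f$se[["F0"]], 0)
  expect_false(any(vapply(fits, `[[`, TRUE, "flagged")))
  expect_lt(abs(mean(F0s) - 7.4) / 7.4, 0.10)
  covered <- abs(F0s - 7.4) <= 1.96 * ses
  expect_gte(sum(covered), 17L)
})

test_that("a free-diffusion profile gives a flagged, non-identifiable fit", {
  tr <- sim_clamp(0, duration = 50, n_traj = 1L, seed = 99L, init = "point")[[1]]
  fit <- fit_clamp_model(estimate_drift_profile(tr, MEDIUM))
  expect_true(fit$flagged)
})

test_that("shifting all positions shifts x0 and nothing else", {
  tr <- sim_clamp(7.4, duration = 50, n_traj = 1L, seed = 31L)[[1]]
  fit1 <- fit_clamp_model(estimate_drift_profile(tr, MEDIUM))
  tr$x <- tr$x + 5.0   # a whole number of bin widths
  fit2 <- fit_clamp_model(estimate_drift_profile(tr, MEDIUM))
  expect_equal(fit2$x0_hat - fit1$x0_hat, 5.0, tolerance = 1e-6)
  expect_lt(abs(fit2$F0_hat - fit1$F0_hat) / fit1$F0_hat, 1e-6)
  expect_lt(abs(fit2$h_hat - fit1$h_hat) / fit1$h_hat, 1e-6)
})

test_that("10 nm localization noise barely moves the recovered force", {
  tr0 <- sim_clamp(7.4, duration = 50, n_traj = 1L, seed = 47L)[[1]]
  fit0 <- fit_clamp_model(estimate_drift_profile(tr0, MEDIUM))
  trn <- add_localization_noise(tr0, 0.01, seed = 48L)
  fitn <- fit_clamp_model(estimate_drift_profile(trn, MEDIUM))
  expect_lt(abs(fitn$F0_hat - fit0$F0_hat) / fit0$F0_hat, 0.05)
})

test_that("rescaling one profile returns its own dimensionless curve", {
  p <- clamp_params(F0 = 12, x0 = -0.3, h = 0.5)
  bins <- seq(-3.3, 2.7, by = 0.125)
  dp <- structure(data.frame(bin_center = bins, n_steps = 1000L,
                             mean_step = NA_real_,
                             force = clamp_force(bins, p),
                             se = rep(0.01, length(bins))),
                  class = c("drift_profile", "data.frame"),
                  l = 0.125, gamma = MEDIUM$gamma, frame_dt = 1e-3)
  fit <- fit_clamp_model(dp)
  pooled <- rescale_and_pool(list(list(fit = fit, profile = dp)), pitch = 0.25)
  expect_identical(attr(pooled, "n_trajectories"), 1L)
  # the pooled curve reproduces the master curve exactly (noiseless input)
  expect_equal(pooled$Ft, dimensionless_force(pooled$xt), tolerance = 1e-3)
  expect_error(rescale_and_pool(list()), "no profiles")
})

test_that("pooling across heterogeneous noiseless particles collapses onto one curve", {
  entries <- lapply(c(2, 5.5, 11, 20), function(F0) {
    p <- clamp_params(F0 = F0, x0 = 0.1 * F0 - 0.5, h = 0.2 + F0 / 50)
    bins <- seq(p$x0 - 3, p$x0 + 3, by = 0.1)
    dp <- structure(data.frame(bin_center = bins, n_steps = 1000L,
                               mean_step = NA_real_,
                               force = clamp_force(bins, p),
                               se = rep(0.01, length(bins))),
                    class = c("drift_profile", "data.frame"),
                    l = 0.1, gamma = MEDIUM$gamma, frame_dt = 1e-3)
    list(fit = fit_clamp_model(dp), profile = dp)
  })
  pooled <- rescale_and_pool(entries, pitch = 0.25, xt_max = 6)
  expect_identical(attr(pooled, "n_trajectories"), 4L)
  # within-bin discretization (bins of pitch 0.25 on a curve of unit slope)
  # bounds the collapse error; no particle deviates beyond it
  expect_lt(max(abs(pooled$Ft - dimensionless_force(pooled$xt))), 0.05)
  # antisymmetry: the bin at the origin carries no net force
  at0 <- pooled$Ft[abs(pooled$xt) < 1e-9]
  expect_lt(abs(at0), 0.05)
})

test_that("the force-voltage fit recovers exact lines and rejects short series", {
  v <- seq(4.3, 4.8, by = 0.1)
  exact <- data.frame(voltage = v, F0_hat = 30 * (v - 4.0))
  lf <- suppressWarnings(force_voltage_fit(exact))   # zero-residual input
  expect_equal(lf$slope, 30, tolerance = 1e-12)
  expect_equal(lf$intercept, -120, tolerance = 1e-10)
  expect_equal(lf$r_squared, 1)
  flat <- data.frame(voltage = v, F0_hat = rep(9, 6))
  expect_equal(suppressWarnings(force_voltage_fit(flat))$slope, 0,
               tolerance = 1e-12)
  expect_error(force_voltage_fit(exact[1:2, ]), "at least 3")
})
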