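#' Full run configuration
#'
#' A single serializable record tying together the physical constants, clamp
#' parameters or study design, acquisition settings, and estimator/MSD
#' settings of one analysis run. Defaults mirror the standard acquisition:
#' 1 kHz frame rate, 50 s trajectories, D = 3.8 um^2/s, 10 nm localization
#' noise.
#'
#' @param medium a [medium_params].
#' @param study a [study_config] (multi-particle designs) or `NULL`.
#' @param clamp a [clamp_params] (single-condition runs) or `NULL`.
#' @param sim a [sim_config] or `NULL` (derived from `study` when absent).
#' @param estimator list: `l` (bin width, um), `n_min`, `pool_pitch`,
#'   `pool_xt_max`.
#' @param msd list: `n_lags_short` (short-time fit), `per_decade`.
#' @param seed integer master seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(medium = medium_params(), study = NULL, clamp = NULL,
                       sim = NULL,
                       estimator = list(l = 0.1, n_min = 50L,
                                        pool_pitch = 0.25, pool_xt_max = 6),
                       msd = list(n_lags_short = 4L, per_decade = 25),
                       seed = 1L) {
  structure(list(medium = medium, study = study, clamp = clamp, sim = sim,
                 estimator = estimator, msd = msd, seed = as.integer(seed)),
            class = "run_config")
}

#' Serialize / restore a run configuration
#'
#' Written as JSON at full double precision so that a reloaded configuration
#' reproduces the run bit-identically.
#'
#' @param cfg a [run_config].
#' @param path file path.
#' @return `path` / the restored [run_config].
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  ser <- lapply(cfg, function(el) if (is.list(el)) unclass(el) else el)
  ser$.classes <- lapply(cfg, function(el) class(el)[1])
  jsonlite::write_json(ser, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  ser <- jsonlite::read_json(path, simplifyVector = TRUE)
  cls <- ser$.classes
  ser$.classes <- NULL
  for (nm in names(ser)) {
    if (is.null(ser[[nm]]) || !is.list(ser[[nm]])) next
    ser[[nm]] <- lapply(ser[[nm]], function(v)
      if (is.list(v) && length(v) == 0L) NULL else v)
    if (!is.null(cls[[nm]]) && cls[[nm]] != "list")
      class(ser[[nm]]) <- cls[[nm]]
  }
  out <- structure(ser, class = "run_config")
  for (f in c("seed")) out[[f]] <- as.integer(out[[f]])
  out
}

#' Calibrate the clamp from a single trajectory
#'
#' The full per-trajectory inference chain: estimate the diffusion
#' coefficient from the trajectory's own short-time MSD (so the damping
#' constant \eqn{\gamma = kT/\hat D} is measured, not assumed), run the
#' binned drift estimator, and fit the clamp model.
#'
#' Conditioning on measured (noisy) positions inflates the apparent drift:
#' for localization noise of standard deviation sigma the binned estimate
#' picks up a factor `1 + sigma^2/(D dt)` (the Tweedie posterior-mean shift
#' of the true position given the measured one). With sigma known the factor
#' is divided out of the fitted force.
#'
#' @param traj a [trajectory].
#' @param kT thermal energy, fN um.
#' @param l drift-estimator bin width, um.
#' @param n_min minimum steps per bin.
#' @param n_lags_short number of MSD lags for the diffusion fit.
#' @param loc_noise_sigma localization noise (um) used for the drift
#'   correction; defaults to the value recorded in the trajectory metadata,
#'   or 0 when absent.
#' @return List with `profile` (drift profile), `fit` (clamp fit, force
#'   corrected for localization noise), `D_hat` (um^2/s) and `medium` (the
#'   [medium_params] used).
#' @export
calibrate_trajectory <- function(traj, kT = 4.11, l = 0.1, n_min = 50L,
                                 n_lags_short = 4L, loc_noise_sigma = NULL) {
  if (is.null(loc_noise_sigma))
    loc_noise_sigma <- if (!is.null(traj$meta$loc_noise_sigma))
      traj$meta$loc_noise_sigma else 0
  msd <- compute_msd(traj, mode = "time_averaged",
                     lags = traj$frame_dt * seq_len(n_lags_short))
  Dhat <- fit_diffusion_short_time(msd, n_lags = n_lags_short)$D_hat
  # self-consistent refinement: in a strong clamp even the first few lags
  # bend below 2*D*tau (relaxation times reach tens of ms), biasing the
  # short-time slope low and hence gamma and the force high. Correct the
  # measured short-time MSD by the confinement factor of an
  # Ornstein-Uhlenbeck process matched to the fitted clamp's stationary
  # variance, and iterate once more.
  for (iter in 1:2) {
    m <- medium_params(D = Dhat, kT = kT)
    dp <- estimate_drift_profile(traj, m, l = l, n_min = n_min)
    fit <- fit_clamp_model(dp)
    if (iter == 2L || fit$flagged || !is.finite(fit$h_hat) ||
        fit$h_hat >= 4.9) break
    V <- stationary_variance(clamp_params(fit$F0_hat, fit$x0_hat,
                                          max(fit$h_hat, 0.01)), m)
    tau <- msd$lag[seq_len(n_lags_short)]
    conf <- V * (1 - exp(-Dhat * tau / V)) / (Dhat * tau)
    adj <- msd
    adj$msd <- (adj$msd - 2 * loc_noise_sigma^2) / conf +
      2 * loc_noise_sigma^2
    Dnew <- fit_diffusion_short_time(adj, n_lags = n_lags_short)$D_hat
    if (!is.finite(Dnew) || Dnew <= 0 ||
        abs(Dnew - Dhat) / Dhat < 1e-3) break
    Dhat <- Dnew
  }
  infl <- 1 + loc_noise_sigma^2 / (Dhat * traj$frame_dt)
  if (is.finite(fit$F0_hat)) {
    fit$F0_hat <- fit$F0_hat / infl
    fit$se[["F0"]] <- fit$se[["F0"]] / infl
  }
  list(profile = dp, fit = fit, D_hat = Dhat, medium = m)
}

analyze_one <- function(traj, kT, est, n_lags_short = 4L) {
  calibrate_trajectory(traj, kT = kT, l = est$l, n_min = est$n_min,
                       n_lags_short = n_lags_short)
}

#' Pooling experiment: heterogeneous particles onto one master curve
#'
#' Simulates a heterogeneous-charge ensemble, runs the drift estimator and
#' clamp-model fit per particle (with the damping constant taken from each
#' trajectory's own short-time diffusion estimate), rescales every profile to
#' dimensionless form, pools, and compares the pooled curve against the
#' master curve \eqn{\tilde x/\sqrt{\tilde x^2 + 1}}.
#'
#' @param cfg a [run_config] with a `study` design.
#' @return List with `pooled` (a `rescaled_profile`), `fits` (per-particle
#'   data.frame), `comparison` (per-bin model deviation in units of pooled
#'   SE), `frac_within_3se`, `n_flagged` and `log`.
#' @export
run_pooling_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$study)) stop("run_pooling_experiment needs cfg$study")
  t0 <- proc.time()[["elapsed"]]
  ds <- synthetic_experiment(cfg$study, cfg$medium)
  entries <- lapply(ds$trajectories, function(tr)
    analyze_one(tr, cfg$medium$kT, cfg$estimator, cfg$msd$n_lags_short))
  fits <- data.frame(
    particle = vapply(ds$trajectories, function(tr) tr$meta$particle, 0L),
    F0_true = ds$truth$F0,
    F0_hat = vapply(entries, function(e) e$fit$F0_hat, 0),
    x0_hat = vapply(entries, function(e) e$fit$x0_hat, 0),
    h_hat = vapply(entries, function(e) e$fit$h_hat, 0),
    D_hat = vapply(entries, function(e) e$D_hat, 0),
    flagged = vapply(entries, function(e) e$fit$flagged, TRUE))
  pooled <- rescale_and_pool(entries, pitch = cfg$estimator$pool_pitch,
                             xt_max = cfg$estimator$pool_xt_max)
  dev_se <- (pooled$Ft - dimensionless_force(pooled$xt)) / pooled$se
  ok <- is.finite(dev_se)
  list(pooled = pooled, fits = fits,
       comparison = data.frame(xt = pooled$xt, deviation_se = dev_se),
       frac_within_3se = mean(abs(dev_se[ok]) <= 3),
       n_flagged = sum(fits$flagged),
       log = list(n_particles = nrow(fits),
                  elapsed_s = proc.time()[["elapsed"]] - t0))
}

#' Voltage-series experiment: force-voltage linearity
#'
#' Simulates one particle recorded at several voltages (its true force
#' exactly linear in voltage), recovers the force at each voltage with the
#' drift estimator and clamp fit, and fits a line to force versus voltage.
#'
#' @param cfg a [run_config] whose `study` has a `voltages` vector (>= 3
#'   voltages).
#' @return List with `series` (voltage, true and recovered F0), `linfit`
#'   (from [force_voltage_fit]), `slope_true`, `covers_truth` (does the 95%
#'   slope CI cover the ground-truth slope) and `log`.
#' @export
run_voltage_experiment <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  if (is.null(cfg$study) || is.null(cfg$study$voltages))
    stop("run_voltage_experiment needs cfg$study with voltages")
  if (length(unique(cfg$study$voltages)) < 3L)
    stop("need at least 3 voltages")
  t0 <- proc.time()[["elapsed"]]
  ds <- synthetic_experiment(cfg$study, cfg$medium)
  entries <- lapply(ds$trajectories, function(tr)
    analyze_one(tr, cfg$medium$kT, cfg$estimator, cfg$msd$n_lags_short))
  series <- data.frame(voltage = ds$truth$voltage, F0_true = ds$truth$F0,
                       F0_hat = vapply(entries, function(e) e$fit$F0_hat, 0),
                       flagged = vapply(entries, function(e) e$fit$flagged, TRUE))
  lf <- force_voltage_fit(series[!series$flagged, ])
  slope_true <- unname(stats::coef(stats::lm(F0 ~ voltage, data = ds$truth))[2])
  ci <- lf$slope + c(-1, 1) * stats::qt(0.975, df = sum(!series$flagged) - 2) * lf$slope_se
  list(series = series, linfit = lf, slope_true = slope_true,
       covers_truth = slope_true >= ci[1] && slope_true <= ci[2],
       log = list(n_flagged = sum(series$flagged),
                  elapsed_s = proc.time()[["elapsed"]] - t0))
}

#' MSD experiment: measured vs numerical vs asymptotic curves
#'
#' For each requested force, simulates one long trajectory, computes its
#' time-averaged MSD, overlays the numerical ensemble prediction (matched
#' parameters, independent seed) and the short/long-time asymptotics, and
#' extracts relaxation times.
#'
#' @param cfg a [run_config] with `clamp` giving the shared `x0`/`h`.
#' @param F0_values vector of clamp forces, fN.
#' @param duration trajectory length, s.
#' @param n_traj_numerical ensemble size of the numerical prediction.
#' @return List (one element per force) with `msd`, `prediction`,
#'   `asymptotics`, `relaxation`, `agreement` (fraction of lags where the
#'   measured and numerical curves agree within 3 combined SE), plus a
#'   top-level `log`.
#' @export
run_msd_experiment <- function(cfg, F0_values = c(1.8, 7.4, 18.3),
                               duration = 50, n_traj_numerical = 200L) {
  stopifnot(inherits(cfg, "run_config"))
  h <- if (!is.null(cfg$clamp)) cfg$clamp$h else 0.3
  x0 <- if (!is.null(cfg$clamp)) cfg$clamp$x0 else 0
  t0 <- proc.time()[["elapsed"]]
  out <- lapply(seq_along(F0_values), function(i) {
    p <- clamp_params(F0 = F0_values[i], x0 = x0, h = h)
    sc <- sim_config(duration = duration, n_traj = 1L,
                     seed = cfg$seed + i, init = "stationary",
                     loc_noise_sigma = 0.01)
    tr <- simulate_trajectories(sc, p, cfg$medium)[[1]]
    # lags reach 0.45*duration so weak clamps still show their plateau
    msd <- compute_msd(tr, mode = "time_averaged", max_lag = 0.45 * duration)
    pred <- predict_msd_numerical(p, cfg$medium, lags = msd$lag,
                                  n_traj = n_traj_numerical,
                                  seed = cfg$seed + 1000L + i,
                                  frame_dt = tr$frame_dt,
                                  duration = min(duration, 8 * max(msd$lag)),
                                  loc_noise_sigma = 0.01)
    asy <- msd_asymptotics(p, cfg$medium, loc_noise_sigma = 0.01)
    comb_se <- sqrt(msd$se^2 + pred$se^2)
    agree <- abs(msd$msd - pred$msd) <= 3 * comb_se
    list(F0 = F0_values[i], msd = msd, prediction = pred, asymptotics = asy,
         relaxation = relaxation_time(msd),
         agreement = mean(agree, na.rm = TRUE))
  })
  names(out) <- paste0("F0_", F0_values)
  out$log <- list(elapsed_s = proc.time()[["elapsed"]] - t0)
  out
}
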