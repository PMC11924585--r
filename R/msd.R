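#' Default logarithmic lag grid
#'
#' Log-spaced lag times, 25 points per decade from the frame interval to
#' `duration/5`, snapped to integer frame multiples (duplicates removed).
#'
#' @param frame_dt frame interval, s.
#' @param duration trajectory duration, s.
#' @param per_decade lag density.
#' @return Numeric vector of lag times, s.
#' @export
msd_lag_grid <- function(frame_dt, duration, per_decade = 25) {
  lo <- log10(frame_dt); hi <- log10(duration / 5)
  lags <- 10^seq(lo, hi, by = 1 / per_decade)
  unique(round(lags / frame_dt)) * frame_dt
}

msd_curve <- function(lags, msd, n_pairs, se, mode) {
  structure(data.frame(lag = lags, msd = msd, n_pairs = n_pairs, se = se),
            class = c("msd_curve", "data.frame"), mode = mode)
}

msd_one_traj <- function(x, frame_dt, lag_frames) {
  n <- length(x)
  vapply(lag_frames, function(k) {
    if (k >= n) return(c(NA_real_, 0, NA_real_))
    d2 <- (x[(k + 1L):n] - x[1L:(n - k)])^2
    c(sum(d2) / length(d2), length(d2), stats::sd(d2))
  }, numeric(3))
}

#' Mean squared displacement of one or more trajectories
#'
#' Time-averaged mode uses all overlapping pairs within each trajectory
#' (standard single-particle-tracking practice; pair counts are recorded, and
#' standard errors are computed from the spread of squared displacements, so
#' they understate the true uncertainty of strongly overlapping pairs).
#' Ensemble mode averages \eqn{(x(\tau) - x(0))^2} across trajectories.
#'
#' @param t a [trajectory] or a list of them.
#' @param mode `"time_averaged"` or `"ensemble"`.
#' @param max_lag largest lag, s. For time-averaged curves a `max_lag`
#'   beyond `duration/2` is computed but a warning attribute is recorded
#'   (poor statistics).
#' @param lags optional explicit lag vector, s (overrides `max_lag` grid).
#' @return An `msd_curve`: data.frame with `lag` (s), `msd` (um^2),
#'   `n_pairs`, `se`, and attribute `mode`.
#' @export
compute_msd <- function(t, mode = c("time_averaged", "ensemble"),
                        max_lag = NULL, lags = NULL) {
  mode <- match.arg(mode)
  trajs <- if (inherits(t, "trajectory")) list(t) else t
  stopifnot(length(trajs) >= 1L, inherits(trajs[[1]], "trajectory"))
  frame_dt <- trajs[[1]]$frame_dt
  duration <- (length(trajs[[1]]$x) - 1L) * frame_dt
  if (is.null(lags)) {
    if (is.null(max_lag)) max_lag <- duration / 5
    lags <- msd_lag_grid(frame_dt, 5 * min(max_lag, duration))
    lags <- lags[lags <= max_lag + 1e-12]
  }
  warn <- NULL
  if (mode == "time_averaged" && max(lags) > duration / 2 + 1e-12)
    warn <- "max lag exceeds duration/2: time-averaged MSD has poor statistics there"
  lag_frames <- as.integer(round(lags / frame_dt))
  keep <- lag_frames >= 1L
  lag_frames <- lag_frames[keep]; lags <- lags[keep]

  if (mode == "time_averaged") {
    per <- lapply(trajs, function(tr) msd_one_traj(tr$x, frame_dt, lag_frames))
    if (length(per) == 1L) {
      m <- per[[1]]
      # overlapping pairs at lag k are strongly correlated; the effective
      # sample size is the number of non-overlapping windows, n_pairs/k
      n_eff <- pmax(floor(m[2, ] / lag_frames), 1)
      out <- msd_curve(lags, m[1, ], m[2, ], m[3, ] / sqrt(n_eff), mode)
    } else {
      M <- vapply(per, function(m) m[1, ], numeric(length(lag_frames)))
      W <- vapply(per, function(m) m[2, ], numeric(length(lag_frames)))
      msd <- rowSums(M * W, na.rm = TRUE) / rowSums(W, na.rm = TRUE)
      se <- apply(M, 1, stats::sd, na.rm = TRUE) / sqrt(rowSums(!is.na(M)))
      out <- msd_curve(lags, msd, rowSums(W), se, mode)
    }
  } else {
    X <- vapply(trajs, function(tr) tr$x, numeric(length(trajs[[1]]$x)))
    d2 <- (X[lag_frames + 1L, , drop = FALSE] - rep(X[1L, ], each = length(lag_frames)))^2
    out <- msd_curve(lags, rowMeans(d2), ncol(d2),
                     apply(d2, 1, stats::sd) / sqrt(ncol(d2)), mode)
  }
  attr(out, "warning") <- warn
  out
}

#' Numerical MSD prediction in the clamp potential
#'
#' The nonlinear clamp force admits no closed-form MSD at arbitrary times, so
#' the prediction is computed numerically: an ensemble of stationary-start
#' Langevin trajectories is simulated and its MSD evaluated. Because the
#' stationary process is ergodic, the default time-averaged mode equals the
#' ensemble MSD in expectation while using far more pairs.
#'
#' @param p a [clamp_params] with `F0 > 0`.
#' @param m a [medium_params].
#' @param lags lag times, s.
#' @param n_traj ensemble size (>= 100).
#' @param seed integer seed.
#' @param frame_dt recording interval, s.
#' @param dt_int integration step, s.
#' @param duration simulated duration, s; defaults to 4 times the largest lag.
#' @param loc_noise_sigma localization noise applied to the simulated
#'   ensemble, um; match the measurement being predicted.
#' @param mode passed to [compute_msd].
#' @return An `msd_curve` with per-lag standard errors.
#' @export
predict_msd_numerical <- function(p, m, lags, n_traj = 200L, seed = 1L,
                                  frame_dt = NULL, dt_int = NULL,
                                  duration = NULL, loc_noise_sigma = 0,
                                  mode = c("time_averaged", "ensemble")) {
  mode <- match.arg(mode)
  stopifnot(n_traj >= 100L)
  if (is.null(frame_dt)) frame_dt <- max(min(lags), 1e-3)
  if (is.null(duration)) duration <- 4 * max(lags)
  if (is.null(dt_int)) {
    # resolve the well-curvature time gamma*h/F0 and respect the simulator's
    # drift-step << noise-step criterion F0*dt/gamma <= 0.1*sqrt(2*D*dt)
    dt_int <- min(frame_dt, 1e-3,
                  if (p$F0 > 0) 0.02 * m$gamma * p$h / p$F0 else Inf,
                  if (p$F0 > 0) 0.9 * 0.01 * 2 * m$D * (m$gamma / p$F0)^2 else Inf)
    dt_int <- frame_dt / ceiling(frame_dt / dt_int)
  }
  # the unconfined limit has no stationary density; start at the minimum
  init <- if (p$F0 > 0) "stationary" else "point"
  cfg <- sim_config(dt_int = dt_int, frame_dt = frame_dt, duration = duration,
                    n_traj = n_traj, seed = seed, init = init,
                    boundary = if (p$F0 > 0) "reflecting" else "none",
                    loc_noise_sigma = loc_noise_sigma)
  trajs <- simulate_trajectories(cfg, p, m)
  compute_msd(trajs, mode = mode, lags = lags)
}

#' Short- and long-time MSD asymptotics in the clamp
#'
#' At short lags the particle diffuses freely, \eqn{\mathrm{MSD} = 2 D \tau}
#' (plus a \eqn{2\sigma^2} localization-noise offset when declared); at long
#' lags it thermalizes in the confining potential and the MSD saturates at
#' twice the Boltzmann position variance.
#'
#' @param p a [clamp_params] with `F0 > 0`.
#' @param m a [medium_params].
#' @param loc_noise_sigma localization noise, um (adds `2 sigma^2` to the
#'   short-time law).
#' @return List with `short_time` (function of lag, um^2), `plateau` (um^2)
#'   and `relaxation_scale` (s).
#' @export
msd_asymptotics <- function(p, m, loc_noise_sigma = 0) {
  stopifnot(p$F0 > 0)
  plateau <- 2 * stationary_variance(p, m)
  list(short_time = function(tau) 2 * m$D * tau + 2 * loc_noise_sigma^2,
       plateau = plateau,
       relaxation_scale = relaxation_scale(p, m))
}

#' Diffusion coefficient from the short-time MSD
#'
#' Weighted (pair-count) linear fit of the first `n_lags` points of an MSD
#' curve with a free intercept; the slope over 2 estimates D. The intercept
#' absorbs the localization-noise offset \eqn{2\sigma^2}; when the noise is
#' known the remaining (dynamic-error) part of the intercept is reported.
#'
#' @param c an `msd_curve`.
#' @param n_lags number of initial lags to fit (>= 2).
#' @param loc_noise_sigma known localization noise, um, or `NULL` if unknown.
#' @return List with `D_hat` (um^2/s), `D_se`, `intercept` (um^2) and
#'   `intercept_excess` (intercept minus `2 sigma^2` when sigma known).
#' @export
fit_diffusion_short_time <- function(c, n_lags = 4L, loc_noise_sigma = NULL) {
  stopifnot(inherits(c, "msd_curve"), n_lags >= 2L)
  d <- utils::head(c[!is.na(c$msd), , drop = FALSE], n_lags)
  fit <- stats::lm(msd ~ lag, data = d, weights = d$n_pairs)
  s <- summary(fit)$coefficients
  icpt <- unname(stats::coef(fit)[1])
  list(D_hat = unname(stats::coef(fit)[2]) / 2,
       D_se = s["lag", "Std. Error"] / 2,
       intercept = icpt,
       intercept_excess = if (is.null(loc_noise_sigma)) NA_real_
                          else icpt - 2 * loc_noise_sigma^2)
}

#' Relaxation (thermalization) time from an MSD curve
#'
#' The plateau is the mean MSD over the last decade of lags; the relaxation
#' time is the first lag at which the MSD reaches \eqn{(1 - 1/e)} of the
#' plateau, linearly interpolated between lag points. A curve that has not
#' plateaued (slope over the last decade above 5% of the initial slope)
#' yields `NA` with a diagnostic.
#'
#' @param c an `msd_curve`.
#' @return List with `tau_relax` (s, `NA` if no plateau), `plateau` (um^2)
#'   and `diagnostic` (character).
#' @export
relaxation_time <- function(c) {
  stopifnot(inherits(c, "msd_curve"))
  d <- c[!is.na(c$msd), , drop = FALSE]
  if (nrow(d) < 5L) return(list(tau_relax = NA_real_, plateau = NA_real_,
                                diagnostic = "too few lags"))
  last <- d[d$lag >= max(d$lag) / 10, , drop = FALSE]
  plateau <- mean(last$msd)
  slope_last <- stats::coef(stats::lm(msd ~ lag, data = last))[2]
  slope_init <- (d$msd[2] - d$msd[1]) / (d$lag[2] - d$lag[1])
  if (!is.finite(slope_init) || slope_init <= 0)
    return(list(tau_relax = NA_real_, plateau = NA_real_,
                diagnostic = "degenerate initial slope"))
  if (abs(slope_last) > 0.05 * slope_init)
    return(list(tau_relax = NA_real_, plateau = NA_real_,
                diagnostic = "no plateau reached within the computed lags"))
  target <- (1 - exp(-1)) * plateau
  above <- which(d$msd >= target)
  if (!length(above)) return(list(tau_relax = NA_real_, plateau = plateau,
                                  diagnostic = "plateau target never reached"))
  i <- above[1]
  tau <- if (i == 1L) d$lag[1] else {
    d$lag[i - 1] + (target - d$msd[i - 1]) *
      (d$lag[i] - d$lag[i - 1]) / (d$msd[i] - d$msd[i - 1])
  }
  list(tau_relax = unname(tau), plateau = plateau, diagnostic = "ok")
}

#' Write an MSD curve as delimited text
#' @param c an `msd_curve`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_msd <- function(c, path) {
  d <- as.data.frame(c)
  names(d) <- c("lag_s", "msd_um2", "n_pairs", "se")
  utils::write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
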