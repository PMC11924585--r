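#' Simulation configuration
#'
#' Settings for the overdamped Langevin simulator. Integration is
#' Euler-Maruyama at step `dt_int`, recorded every `frame_dt` (the camera
#' frame interval; defaults mirror a 1 kHz acquisition of 50 s trajectories).
#'
#' The step must satisfy a drift-step << noise-step criterion,
#' \eqn{F_0 \, dt / \gamma \le 0.1 \sqrt{2 D \, dt}}; the simulator refuses to
#' run otherwise rather than integrate with a too-coarse step.
#'
#' @param dt_int integration step, s; `frame_dt/dt_int` must be a positive
#'   integer.
#' @param frame_dt frame (sampling) interval, s.
#' @param duration trajectory length, s.
#' @param n_traj number of trajectories.
#' @param seed integer RNG seed; identical configurations and seeds give
#'   bit-identical output.
#' @param init `"stationary"` (draw x(0) from the Boltzmann density by
#'   inverse-CDF on the quadrature grid) or `"point"` (start at `x_init`).
#' @param x_init starting position for `init = "point"`, um; defaults to the
#'   potential minimum.
#' @param domain_halfwidth reflecting-wall position, um. Default 17.5 um,
#'   half the electrode spacing; far enough not to affect the statistics.
#' @param boundary `"reflecting"` or `"none"`.
#' @param loc_noise_sigma localization noise added to recorded positions, um
#'   (0 = noiseless).
#' @param with_y also record a free-diffusion y coordinate (visual fidelity
#'   only; all quantitative analysis is along x).
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(dt_int = 1e-4, frame_dt = 1e-3, duration = 50,
                       n_traj = 1L, seed = 1L, init = c("stationary", "point"),
                       x_init = NULL, domain_halfwidth = 17.5,
                       boundary = c("reflecting", "none"),
                       loc_noise_sigma = 0, with_y = FALSE) {
  init <- match.arg(init)
  boundary <- match.arg(boundary)
  stopifnot(dt_int > 0, frame_dt > 0, dt_int <= frame_dt,
            duration > 0, n_traj >= 1, domain_halfwidth > 0,
            loc_noise_sigma >= 0)
  nsub <- frame_dt / dt_int
  if (abs(nsub - round(nsub)) > 1e-9)
    stop("frame_dt/dt_int must be a positive integer")
  structure(list(dt_int = dt_int, frame_dt = frame_dt, duration = duration,
                 n_traj = as.integer(n_traj), seed = as.integer(seed),
                 init = init, x_init = x_init,
                 domain_halfwidth = domain_halfwidth, boundary = boundary,
                 loc_noise_sigma = loc_noise_sigma, with_y = isTRUE(with_y)),
            class = "sim_config")
}

#' Single-particle trajectory
#'
#' Uniformly sampled positions with frame interval and provenance metadata
#' (true parameters and seeds when synthetic).
#'
#' @param times sample times, s; strictly increasing with constant spacing.
#' @param x positions, um.
#' @param frame_dt frame interval, s.
#' @param y optional second coordinate, um.
#' @param meta named list of provenance metadata.
#' @return An object of class `trajectory`.
#' @export
trajectory <- function(times, x, frame_dt, y = NULL, meta = list()) {
  stopifnot(length(times) == length(x), length(times) >= 2L)
  dts <- diff(times)
  if (any(dts <= 0) || any(abs(dts - frame_dt) > 1e-9))
    stop("times must be strictly increasing with constant spacing frame_dt")
  if (!is.null(y)) stopifnot(length(y) == length(x))
  structure(list(times = times, x = x, y = y, frame_dt = frame_dt,
                 meta = meta), class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d frames, frame_dt = %.3g s, duration = %.3g s\n",
              length(x$x), x$frame_dt, max(x$times) - min(x$times)))
  invisible(x)
}

# Vectorized Euler-Maruyama core: integrates n = length(x) particles in
# parallel, each with its own clamp parameters (F0, x0, h recycled to n).
# Returns an (n_frames + 1) x n matrix of recorded positions.
em_core <- function(x, F0, x0, h, gamma, D, dt, nsub, n_frames, L = Inf) {
  n <- length(x)
  F0 <- rep_len(F0, n); x0 <- rep_len(x0, n); h <- rep_len(h, n)
  mob_dt <- dt / gamma
  sd_step <- sqrt(2 * D * dt)
  X <- matrix(NA_real_, n_frames + 1L, n)
  X[1L, ] <- x
  reflect <- is.finite(L)
  h2 <- h * h
  for (f in seq_len(n_frames)) {
    z <- matrix(stats::rnorm(nsub * n), nsub, n)
    for (s in seq_len(nsub)) {
      d <- x - x0
      x <- x - F0 * d / sqrt(d * d + h2) * mob_dt + sd_step * z[s, ]
      if (reflect) {
        x <- abs(x + L) - L   # reflect at -L
        x <- L - abs(L - x)   # reflect at +L
      }
    }
    X[f + 1L, ] <- x
  }
  X
}

# inverse-CDF draw of n stationary positions from the Boltzmann density
draw_stationary <- function(n, p, m) {
  bd <- boltzmann_density(p, m)
  dx <- diff(bd$x)
  cdf <- c(0, cumsum((bd$density[-1] + bd$density[-nrow(bd)]) * dx / 2))
  cdf <- cdf / cdf[length(cdf)]
  u <- stats::runif(n)
  stats::approx(cdf, bd$x, xout = u, ties = "ordered")$y
}

check_em_stability <- function(F0max, m, dt) {
  if (F0max * dt / m$gamma > 0.1 * sqrt(2 * m$D * dt))
    stop("integration step too coarse: drift step exceeds 10% of the ",
         "diffusive step at the domain edge; reduce dt_int")
  invisible(TRUE)
}

#' Simulate clamped Brownian trajectories
#'
#' Overdamped Langevin dynamics \eqn{dx = (F(x)/\gamma)\,dt +
#' \sqrt{2 D\, dt}\, \mathcal{N}(0,1)} in the clamp potential, integrated by
#' Euler-Maruyama at `cfg$dt_int` and recorded every `cfg$frame_dt`.
#' The damping constant is \eqn{\gamma = kT/D}; the simulator has no
#' independent mobility parameter. Localization noise (if
#' `cfg$loc_noise_sigma > 0`) is added to the recorded positions.
#'
#' @param cfg a [sim_config].
#' @param p a [clamp_params]. `p$F0` may also be a vector of length
#'   `cfg$n_traj` to give each trajectory its own force (used for
#'   heterogeneous synthetic experiments).
#' @param m a [medium_params].
#' @return A list of [trajectory] objects; each `meta` records the true
#'   parameters, seed and noise sigma.
#' @export
simulate_trajectories <- function(cfg, p, m) {
  stopifnot(inherits(cfg, "sim_config"), inherits(m, "medium_params"))
  if (inherits(p, "clamp_params")) {
    F0 <- p$F0; x0 <- p$x0; h <- p$h
  } else stop("p must be a clamp_params object")
  stopifnot(length(F0) == 1L || length(F0) == cfg$n_traj)
  check_em_stability(max(F0), m, cfg$dt_int)
  set.seed(cfg$seed)
  n <- cfg$n_traj
  n_frames <- round(cfg$duration / cfg$frame_dt)
  nsub <- as.integer(round(cfg$frame_dt / cfg$dt_int))
  L <- if (cfg$boundary == "reflecting") cfg$domain_halfwidth else Inf

  if (cfg$init == "stationary") {
    if (any(F0 <= 0)) stop("stationary initialization requires F0 > 0")
    F0v <- rep_len(F0, n)
    xinit <- numeric(n)
    for (i in seq_len(n))
      xinit[i] <- draw_stationary(1L, clamp_params(F0v[i], x0, h), m)
  } else {
    xinit <- rep_len(if (is.null(cfg$x_init)) x0 else cfg$x_init, n)
  }

  X <- em_core(xinit, F0, x0, h, m$gamma, m$D, cfg$dt_int, nsub, n_frames, L)
  if (cfg$with_y) {
    Y <- apply(matrix(stats::rnorm((n_frames) * n, sd = sqrt(2 * m$D * cfg$frame_dt)),
                      n_frames, n), 2, cumsum)
    Y <- rbind(0, Y)
  }
  if (cfg$loc_noise_sigma > 0)
    X <- X + stats::rnorm(length(X), sd = cfg$loc_noise_sigma)

  times <- seq(0, by = cfg$frame_dt, length.out = n_frames + 1L)
  F0v <- rep_len(F0, n)
  lapply(seq_len(n), function(i) {
    trajectory(times, X[, i], cfg$frame_dt,
               y = if (cfg$with_y) Y[, i] else NULL,
               meta = list(F0 = F0v[i], x0 = x0, h = h, D = m$D, kT = m$kT,
                           seed = cfg$seed, traj_index = i,
                           loc_noise_sigma = cfg$loc_noise_sigma))
  })
}

#' Add localization noise to a trajectory
#'
#' Adds i.i.d. Gaussian offsets (standard deviation `sigma`) to every
#' recorded position, emulating the sub-pixel localization error of the
#' imaging stage. `sigma = 0` returns the positions unchanged.
#'
#' @param t a [trajectory].
#' @param sigma localization noise standard deviation, um.
#' @param seed optional integer seed.
#' @return A [trajectory] with noisy positions; `meta$loc_noise_sigma`
#'   records the total added sigma.
#' @export
add_localization_noise <- function(t, sigma, seed = NULL) {
  stopifnot(inherits(t, "trajectory"), sigma >= 0)
  if (!is.null(seed)) set.seed(seed)
  if (sigma > 0) {
    t$x <- t$x + stats::rnorm(length(t$x), sd = sigma)
    if (!is.null(t$y)) t$y <- t$y + stats::rnorm(length(t$y), sd = sigma)
  }
  prev <- t$meta$loc_noise_sigma
  t$meta$loc_noise_sigma <- sqrt(sum(c(prev, sigma)^2))
  t
}

#' Design of a synthetic clamp experiment
#'
#' Describes a multi-particle study: either a heterogeneous-charge ensemble
#' (per-particle `F0` drawn log-normal, keeping forces positive) for the
#' pooling analysis, or a voltage series in which a single particle's force
#' is exactly linear in the applied voltage,
#' \eqn{F_{0,i}(V) = c_i (V - V_\mathrm{off})} with per-particle charge
#' factor \eqn{c_i}.
#'
#' @param n_particles number of particles.
#' @param F0_median median asymptotic force across particles, fN.
#' @param F0_gsd geometric standard deviation of the per-particle force
#'   (log-normal heterogeneity; > 1 spreads, 1 = identical particles).
#' @param h,x0 clamp geometry shared by all particles (um).
#' @param voltages optional vector of applied voltages, V. When given, each
#'   particle is recorded once per voltage with
#'   `F0 = charge_factor * (V - v_off)`.
#' @param v_off voltage offset at which the force vanishes, V.
#' @param charge_factor per-particle charge-to-force factor, fN/V; recycled
#'   to `n_particles`. Only used with `voltages`.
#' @param duration,frame_dt,dt_int,loc_noise_sigma acquisition settings (s,
#'   s, s, um); defaults mirror 50 s at 1 kHz with 10 nm noise.
#' @param seed integer seed; the whole experiment is deterministic given it.
#' @return An object of class `study_config`.
#' @export
study_config <- function(n_particles = 107L, F0_median = 8, F0_gsd = 1.8,
                         h = 0.3, x0 = 0, voltages = NULL, v_off = 4.0,
                         charge_factor = 30, duration = 50, frame_dt = 1e-3,
                         dt_int = 1e-4, loc_noise_sigma = 0.01, seed = 1L) {
  stopifnot(n_particles >= 1, F0_median > 0, F0_gsd >= 1, h > 0)
  if (!is.null(voltages) && any(charge_factor * (voltages - v_off) <= 0))
    stop("requested voltages yield non-positive forces; the clamp is attractive only")
  structure(list(n_particles = as.integer(n_particles), F0_median = F0_median,
                 F0_gsd = F0_gsd, h = h, x0 = x0, voltages = voltages,
                 v_off = v_off, charge_factor = charge_factor,
                 duration = duration, frame_dt = frame_dt, dt_int = dt_int,
                 loc_noise_sigma = loc_noise_sigma, seed = as.integer(seed)),
            class = "study_config")
}

#' Generate a synthetic multi-particle experiment
#'
#' Simulates every (particle, voltage) combination of a [study_config] with
#' the Langevin simulator, tagging each trajectory with its particle id,
#' voltage and ground-truth parameters. With one particle and no voltage
#' series this reduces to [simulate_trajectories] plus localization noise.
#'
#' @param study a [study_config].
#' @param m a [medium_params].
#' @return A list with `trajectories` (list of [trajectory]) and `truth`
#'   (data.frame: particle, voltage, F0, x0, h).
#' @export
synthetic_experiment <- function(study, m = medium_params()) {
  stopifnot(inherits(study, "study_config"))
  set.seed(study$seed)
  np <- study$n_particles
  if (is.null(study$voltages)) {
    F0 <- stats::rlnorm(np, meanlog = log(study$F0_median),
                        sdlog = log(study$F0_gsd))
    truth <- data.frame(particle = seq_len(np), voltage = NA_real_, F0 = F0,
                        x0 = study$x0, h = study$h)
  } else {
    cf <- rep_len(study$charge_factor, np)
    truth <- expand.grid(particle = seq_len(np), voltage = study$voltages)
    truth$F0 <- cf[truth$particle] * (truth$voltage - study$v_off)
    truth$x0 <- study$x0; truth$h <- study$h
    if (any(truth$F0 <= 0)) stop("non-positive force requested")
  }
  # the strongest drawn particle sets the integration step (drift-step <<
  # noise-step criterion); sub-divide the frame interval as needed
  dt_stab <- 0.9 * 0.02 * m$D * (m$gamma / max(truth$F0))^2
  dt_int <- study$frame_dt / ceiling(study$frame_dt /
                                       min(study$dt_int, dt_stab))
  cfg <- sim_config(dt_int = dt_int, frame_dt = study$frame_dt,
                    duration = study$duration, n_traj = nrow(truth),
                    seed = study$seed + 1L, init = "stationary",
                    loc_noise_sigma = study$loc_noise_sigma)
  p <- clamp_params(F0 = 1, x0 = study$x0, h = study$h)
  p$F0 <- truth$F0  # vectorized per-trajectory force
  trajs <- simulate_trajectories(cfg, p, m)
  for (i in seq_along(trajs)) {
    trajs[[i]]$meta$particle <- truth$particle[i]
    trajs[[i]]$meta$voltage <- truth$voltage[i]
  }
  list(trajectories = trajs, truth = truth)
}

#' Write trajectories to a delimited text table
#'
#' Tab-separated columns `particle_id, frame, t_s, x_um` (plus `y_um` when
#' present), with a JSON sidecar `<path>.meta.json` carrying per-trajectory
#' metadata (ground truth, seeds, noise sigma).
#'
#' @param trajs list of [trajectory] objects.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_trajectories <- function(trajs, path) {
  if (inherits(trajs, "trajectory")) trajs <- list(trajs)
  has_y <- !is.null(trajs[[1]]$y)
  tabs <- lapply(seq_along(trajs), function(i) {
    t <- trajs[[i]]
    d <- data.frame(particle_id = i, frame = seq_along(t$x) - 1L,
                    t_s = t$times, x_um = t$x)
    if (has_y) d$y_um <- t$y
    d
  })
  tab <- do.call(rbind, tabs)
  utils::write.table(tab, path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- lapply(trajs, function(t) c(list(frame_dt = t$frame_dt), t$meta))
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read trajectories written by [write_trajectories]
#'
#' @param path file path; the `<path>.meta.json` sidecar is read when present.
#' @return A list of [trajectory] objects.
#' @export
read_trajectories <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t")
  metas <- NULL
  mp <- paste0(path, ".meta.json")
  if (file.exists(mp)) metas <- jsonlite::read_json(mp, simplifyVector = FALSE)
  ids <- unique(tab$particle_id)
  lapply(seq_along(ids), function(i) {
    d <- tab[tab$particle_id == ids[i], ]
    frame_dt <- if (!is.null(metas)) metas[[i]]$frame_dt else stats::median(diff(d$t_s))
    meta <- if (!is.null(metas)) metas[[i]][names(metas[[i]]) != "frame_dt"] else list()
    trajectory(d$t_s, d$x_um, frame_dt,
               y = if ("y_um" %in% names(d)) d$y_um else NULL, meta = meta)
  })
}
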