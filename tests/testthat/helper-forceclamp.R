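# shared fixtures and independent oracles used across test files

MEDIUM <- medium_params(D = 3.8, kT = 4.11)

# independent brute-force drift estimator: explicit loop over bin centers,
# enumerating every step that begins inside the half-open interval
# [c - l/2, c + l/2); deliberately naive, no shared code with the package
brute_force_drift <- function(x, frame_dt, gamma, l) {
  v <- x[-1] - x[-length(x)]
  starts <- x[-length(x)]
  ks <- sort(unique(as.integer(floor(starts / l + 0.5))))
  res <- data.frame(bin_center = numeric(0), n_steps = integer(0),
                    mean_step = numeric(0), force = numeric(0))
  for (k in ks) {
    ctr <- k * l
    inbin <- starts >= ctr - l / 2 & starts < ctr + l / 2
    if (!any(inbin)) next
    vv <- v[inbin]
    ms <- sum(vv) / length(vv)
    res <- rbind(res, data.frame(bin_center = ctr, n_steps = length(vv),
                                 mean_step = ms,
                                 force = gamma * ms / frame_dt))
  }
  res
}

# quick single-condition simulation used by several tests
sim_clamp <- function(F0, h = 0.3, duration = 50, n_traj = 1L, seed = 1L,
                      sigma = 0, init = "stationary", dt_int = 1e-4) {
  cfg <- sim_config(dt_int = dt_int, frame_dt = 1e-3, duration = duration,
                    n_traj = n_traj, seed = seed, init = init,
                    loc_noise_sigma = sigma)
  simulate_trajectories(cfg, clamp_params(F0 = F0, x0 = 0, h = h), MEDIUM)
}
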