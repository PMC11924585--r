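#' Binned drift estimate of the force field
#'
#' The statistical force estimator: around each position x on a regular grid
#' of pitch `l`, all recorded steps that *begin* inside the half-open
#' interval \eqn{I(x) = [x - l/2, x + l/2)} are pooled, and the local force
#' is the damping constant times the mean drift per frame,
#' \eqn{\hat F(x) = \gamma \langle v_i \rangle / \Delta t}, where
#' \eqn{v_i = x_{i+1} - x_i} is the size of the i-th step. The per-bin
#' standard error is \eqn{\gamma\, \mathrm{sd}(v_i) / (\sqrt{n}\, \Delta t)}.
#'
#' Bins with fewer than `n_min` steps carry no estimate (`NA`, flagged
#' absent), never a zero.
#'
#' @param t a [trajectory].
#' @param m a [medium_params]; supplies \eqn{\gamma = kT/D}. The estimator is
#'   meaningless without a damping constant.
#' @param l bin width, um. Default 0.1 um keeps the potential variation per
#'   bin well below kT while still populating bins over a 50 s trajectory.
#' @param n_min minimum steps per bin for an estimate.
#' @return An object of class `drift_profile`: a data.frame with columns
#'   `bin_center` (um), `n_steps`, `mean_step` (um), `force` (fN) and `se`
#'   (fN), with attributes `l`, `gamma` and `frame_dt`.
#' @export
estimate_drift_profile <- function(t, m, l = 0.1, n_min = 50L) {
  stopifnot(inherits(t, "trajectory"), l > 0)
  if (!inherits(m, "medium_params"))
    stop("medium_params required: the drift estimator needs gamma = kT/D")
  n <- length(t$x)
  if (n < 3L) stop("trajectory too short")
  if (n < 1001L)
    message("fewer than 1000 steps: drift estimates will be very noisy")
  xs <- t$x[-n]
  v <- t$x[-1L] - t$x[-n]
  # regular grid of pitch l, centers at integer multiples of l
  k <- as.integer(floor(xs / l + 0.5))   # index of bin [k*l - l/2, k*l + l/2)
  kr <- range(k)
  idx <- k - kr[1L] + 1L
  groups <- split(v, factor(idx, levels = seq_len(kr[2L] - kr[1L] + 1L)))
  n_steps <- lengths(groups)
  mean_step <- vapply(groups, function(g)
    if (length(g)) sum(g) / length(g) else NA_real_, 0)
  sd_step <- vapply(groups, function(g) {
    if (length(g) < 2L) return(NA_real_)
    mu <- sum(g) / length(g)
    sqrt(sum((g - mu)^2) / (length(g) - 1L))
  }, 0)
  gamma <- m$gamma
  force <- gamma * mean_step / t$frame_dt
  se <- gamma * sd_step / (sqrt(n_steps) * t$frame_dt)
  keep <- n_steps > 0L
  out <- data.frame(bin_center = (seq(kr[1L], kr[2L]))[keep] * l,
                    n_steps = n_steps[keep], mean_step = mean_step[keep],
                    force = force[keep], se = se[keep])
  sparse <- out$n_steps < n_min
  out$force[sparse] <- NA_real_
  out$se[sparse] <- NA_real_
  rownames(out) <- NULL
  structure(out, class = c("drift_profile", "data.frame"),
            l = l, gamma = gamma, frame_dt = t$frame_dt)
}

# data-driven initial guesses for the clamp-model fit
clamp_fit_start <- function(x, f) {
  ord <- order(x)
  x <- x[ord]; f <- f[ord]
  fs <- stats::filter(f, rep(1 / 3, 3), sides = 2)  # light smoothing
  fs[is.na(fs)] <- f[is.na(fs)]
  fs <- as.numeric(fs)
  # x0: zero crossing of the smoothed (decreasing) profile
  sgn <- sign(fs)
  cross <- which(sgn[-1] * sgn[-length(sgn)] < 0)
  x0 <- if (length(cross)) {
    # with noise there can be several sign changes; take the one nearest the
    # bulk of the data (bins concentrate around the potential minimum)
    i <- cross[which.min(abs(x[cross] - stats::median(x)))]
    x[i] - fs[i] * (x[i + 1] - x[i]) / (fs[i + 1] - fs[i])
  } else stats::median(x)
  # F0: mean |force| over the outer thirds
  nb <- length(x)
  outer3 <- c(seq_len(ceiling(nb / 3)), seq(nb - ceiling(nb / 3) + 1L, nb))
  F0 <- mean(abs(f[unique(outer3)]))
  # h: half the distance between the +/- 50% F0 crossings of |f|
  lo <- x[x < x0][which.min(abs(abs(fs[x < x0]) - 0.5 * F0))]
  hi <- x[x > x0][which.min(abs(abs(fs[x > x0]) - 0.5 * F0))]
  h <- if (length(lo) && length(hi)) (hi - lo) / 2 else diff(range(x)) / 4
  h <- min(max(h, 0.02), 4.9)
  list(F0 = max(F0, 1e-3), x0 = x0, h = h)
}

#' Fit the clamp model to a drift profile
#'
#' Weighted (1/SE^2) Levenberg-Marquardt least squares of the clamp force
#' \eqn{F(x) = -F_0 (x - x_0) / \sqrt{(x - x_0)^2 + h^2}} to the binned force
#' estimates. Initial guesses are data-driven (zero crossing, outer-third
#' plateau, half-maximum width); box bounds are \eqn{F_0 \in (0, 10^3]} fN,
#' \eqn{h \in [0.01, 5]} um. The covariance comes from the weighted Jacobian.
#'
#' When `h` is not identified (its 95% interval reaches the box bounds -- the
#' common case for weak clamps, where the crossover region is buried in step
#' noise) the saturating model is degenerate and the fit falls back to its
#' sharp-clamp limit \eqn{F(x) = -F_0\,\mathrm{sign}(x - x_0)}, in which
#' `F0` remains fully identified as the plateau force while `h` is reported
#' as `NA`. Such fits are flagged (no dimensionless rescaling is possible
#' without `h`) and excluded from pooling, but their `F0` is a valid force
#' estimate. Fits that do not converge or whose `F0` is not resolved above
#' twice its standard error are likewise flagged.
#'
#' @param dp a `drift_profile` from [estimate_drift_profile].
#' @return An object of class `clamp_fit`: list with `F0_hat`, `x0_hat`,
#'   `h_hat`, `se` (named vector), `cov` (3x3), `model` ("saturating" or
#'   "sharp"), `h_identified`, `flagged`, `flag_reason`, `residual_df` and
#'   `profile` (the populated bins used).
#' @export
fit_clamp_model <- function(dp) {
  stopifnot(inherits(dp, "drift_profile"))
  d <- dp[!is.na(dp$force) & !is.na(dp$se) & dp$se > 0, , drop = FALSE]
  flagged <- function(reason) {
    structure(list(F0_hat = NA_real_, x0_hat = NA_real_, h_hat = NA_real_,
                   se = c(F0 = NA_real_, x0 = NA_real_, h = NA_real_),
                   cov = matrix(NA_real_, 3, 3), model = "none",
                   h_identified = FALSE, flagged = TRUE,
                   flag_reason = reason, residual_df = NA_integer_,
                   profile = d), class = "clamp_fit")
  }
  if (nrow(d) < 8L) return(flagged("fewer than 8 populated bins"))
  st <- clamp_fit_start(d$bin_center, d$force)
  if (sum(d$bin_center < st$x0) < 2L || sum(d$bin_center > st$x0) < 2L)
    return(flagged("bins do not span the zero crossing"))
  xr <- range(d$bin_center)
  # the weighted-SSR surface can be nearly flat in h on noisy profiles, with
  # local minima at the h bounds; a small multi-start over h guards against
  # the optimizer stalling there
  h_starts <- unique(pmin(pmax(c(st$h, 0.1, 0.3, 1.0), 0.02), 4.5))
  w <- 1 / d$se^2
  best <- NULL; best_ssr <- Inf
  for (h0 in h_starts) {
    fit <- tryCatch(
      minpack.lm::nlsLM(
        force ~ -F0 * (bin_center - x0) / sqrt((bin_center - x0)^2 + h^2),
        data = d, weights = w,
        start = list(F0 = st$F0, x0 = st$x0, h = h0),
        lower = c(F0 = 1e-6, x0 = xr[1], h = 0.01),
        upper = c(F0 = 1e3, x0 = xr[2], h = 5),
        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) next
    co0 <- stats::coef(fit)
    pred <- -co0[["F0"]] * (d$bin_center - co0[["x0"]]) /
      sqrt((d$bin_center - co0[["x0"]])^2 + co0[["h"]]^2)
    ssr <- sum(w * (d$force - pred)^2)
    if (ssr < best_ssr) { best <- fit; best_ssr <- ssr }
  }
  fit <- best
  if (is.null(fit)) return(flagged("fit did not converge"))
  co <- stats::coef(fit)
  vc <- tryCatch(stats::vcov(fit), error = function(e) matrix(NA_real_, 3, 3))
  se <- sqrt(pmax(diag(vc), 0))
  names(se) <- names(co)
  # h is treated as unidentified when it collapses onto the lower bound or
  # when its 95% upper limit reaches the upper bound. In either case the
  # saturating model is degenerate -- h -> 0 reduces it to a sharp clamp
  # where F0 is still the plateau force, h -> large to a straight line where
  # only F0/h is constrained -- and the fit is replaced by the sharp-limit
  # model F(x) = -F0 * sign(x - x0).
  h_identified <- is.finite(co[["h"]]) && is.finite(se[["h"]]) &&
    co[["h"]] > 0.0101 && co[["h"]] + 2 * se[["h"]] < 4.99
  model <- "saturating"
  if (!h_identified) {
    sf <- sharp_clamp_fit(d)
    co <- c(F0 = sf$F0, x0 = sf$x0, h = NA_real_)
    se <- c(F0 = sf$se_F0, x0 = NA_real_, h = NA_real_)
    vc <- matrix(NA_real_, 3, 3)
    model <- "sharp"
  }
  reasons <- character()
  if (!h_identified)
    reasons <- c(reasons,
                 "h not identified (sharp-limit force fit used for F0)")
  if (!is.finite(se[["F0"]]) || !is.finite(co[["F0"]]) ||
      co[["F0"]] < 2 * se[["F0"]])
    reasons <- c(reasons, "F0 not resolved above 2 SE (consistent with free diffusion)")
  structure(list(F0_hat = unname(co[["F0"]]), x0_hat = unname(co[["x0"]]),
                 h_hat = unname(co[["h"]]), se = se, cov = vc,
                 model = model, h_identified = h_identified,
                 flagged = length(reasons) > 0L,
                 flag_reason = if (length(reasons)) paste(reasons, collapse = "; ") else NA_character_,
                 residual_df = nrow(d) - 3L, profile = d),
            class = "clamp_fit")
}

# weighted LS of the sharp-clamp (Laplace-limit) force -F0*sign(x - x0):
# closed-form F0 for each candidate x0 (bin edges), best SSR wins
sharp_clamp_fit <- function(d) {
  w <- 1 / d$se^2
  l <- stats::median(diff(sort(unique(d$bin_center))))
  qs <- stats::quantile(d$bin_center, c(0.1, 0.9))
  cand <- sort(unique(c(d$bin_center - l / 2, d$bin_center + l / 2)))
  cand <- cand[cand >= qs[1] & cand <= qs[2]]
  if (!length(cand)) cand <- stats::median(d$bin_center)
  best <- list(ssr = Inf, F0 = NA_real_, x0 = NA_real_)
  for (x0 in cand) {
    s <- sign(d$bin_center - x0); s[s == 0] <- 1
    F0 <- -sum(w * d$force * s) / sum(w)
    ssr <- sum(w * (d$force + F0 * s)^2)
    if (ssr < best$ssr) best <- list(ssr = ssr, F0 = F0, x0 = x0)
  }
  best$se_F0 <- sqrt(1 / sum(w))
  best
}

#' @export
print.clamp_fit <- function(x, ...) {
  if (x$flagged) {
    cat("Clamp fit: FLAGGED (", x$flag_reason, ")\n", sep = "")
  } else {
    cat(sprintf("Clamp fit: F0 = %.3f +/- %.3f fN, x0 = %.4f um, h = %.3f um\n",
                x$F0_hat, x$se[["F0"]], x$x0_hat, x$h_hat))
  }
  invisible(x)
}

#' Rescale drift profiles to dimensionless form and pool
#'
#' Maps each particle's binned force estimate onto the common dimensionless
#' scale using its own fitted parameters,
#' \eqn{\tilde x = (x - \hat x_0)/\hat h}, \eqn{\tilde F = -\hat F / \hat F_0}
#' (sign chosen so the master curve is \eqn{+\tilde x/\sqrt{\tilde x^2+1}}),
#' then averages within half-open \eqn{\tilde x} bins. This collapses
#' particles of different, unknown charge onto one curve.
#'
#' @param entries list, each element a list with components `fit` (a
#'   [fit_clamp_model] result) and `profile` (the matching
#'   [estimate_drift_profile]). Flagged fits are skipped.
#' @param pitch pooling bin width in dimensionless units.
#' @param xt_max pooled range \eqn{|\tilde x| \le} `xt_max`.
#' @return An object of class `rescaled_profile`: data.frame with
#'   `xt` (bin centers), `Ft` (pooled mean), `se`, `n_points`, plus attribute
#'   `n_trajectories` (number of unflagged particles pooled).
#' @export
rescale_and_pool <- function(entries, pitch = 0.25, xt_max = 6) {
  if (length(entries) == 0L) stop("no profiles to pool")
  xt_all <- numeric(); Ft_all <- numeric()
  n_used <- 0L
  for (e in entries) {
    fit <- e$fit; dp <- e$profile
    if (is.null(fit) || fit$flagged) next
    d <- dp[!is.na(dp$force), , drop = FALSE]
    xt <- (d$bin_center - fit$x0_hat) / fit$h_hat
    Ft <- -d$force / fit$F0_hat
    keep <- abs(xt) <= xt_max
    xt_all <- c(xt_all, xt[keep]); Ft_all <- c(Ft_all, Ft[keep])
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("all fits flagged; nothing to pool")
  k <- floor(xt_all / pitch + 0.5)            # half-open bins [lo, hi)
  centers <- sort(unique(k)) * pitch
  groups <- split(Ft_all, factor(k, levels = sort(unique(k))))
  out <- data.frame(
    xt = centers,
    Ft = vapply(groups, mean, 0),
    se = vapply(groups, function(g)
      if (length(g) > 1L) stats::sd(g) / sqrt(length(g)) else NA_real_, 0),
    n_points = lengths(groups))
  rownames(out) <- NULL
  structure(out, class = c("rescaled_profile", "data.frame"),
            n_trajectories = n_used)
}

#' Force-voltage linearity fit
#'
#' Ordinary least squares of recovered clamp forces against applied voltage.
#' A linear relation with voltage is the signature that the clamp force is
#' set by the electrode charge and the (fixed) particle charge.
#'
#' @param series data.frame with columns `voltage` (V) and `F0_hat` (fN);
#'   at least 3 voltages.
#' @return List with `slope` (fN/V), `intercept` (fN), `slope_se`,
#'   `intercept_se`, `r_squared` and the underlying `lm` fit.
#' @export
force_voltage_fit <- function(series) {
  stopifnot(is.data.frame(series), all(c("voltage", "F0_hat") %in% names(series)))
  if (length(unique(series$voltage)) < 3L)
    stop("need at least 3 distinct voltages for a linearity fit")
  fit <- stats::lm(F0_hat ~ voltage, data = series)
  s <- summary(fit)
  list(slope = unname(stats::coef(fit)[2]),
       intercept = unname(stats::coef(fit)[1]),
       slope_se = s$coefficients["voltage", "Std. Error"],
       intercept_se = s$coefficients["(Intercept)", "Std. Error"],
       r_squared = s$r.squared,
       fit = fit)
}

#' Write a drift profile or pooled profile to delimited text
#' @param x a `drift_profile` or `rescaled_profile`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a clamp fit (parameters, covariance, flags) as JSON
#' @param fit a `clamp_fit`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clamp_fit <- function(fit, path) {
  rec <- list(F0_hat = fit$F0_hat, x0_hat = fit$x0_hat, h_hat = fit$h_hat,
              se = as.list(fit$se), cov = fit$cov, flagged = fit$flagged,
              flag_reason = fit$flag_reason, residual_df = fit$residual_df)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
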