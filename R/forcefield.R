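#' Clamp model parameters
#'
#' Parameters of the closed-form electrostatic clamp potential
#' \eqn{U(x) = F_0 \sqrt{(x - x_0)^2 + h^2}}: the asymptotic force magnitude
#' `F0` (fN), the potential-minimum position `x0` (um) and the crossover
#' length `h` (um, of the order of the channel height) beyond which the force
#' is effectively constant.
#'
#' Units throughout the package: um, s, fN and fN um (1 fN um = 1e-21 J), so
#' that all quantities are O(1)-O(10).
#'
#' @param F0 asymptotic force magnitude, fN; must be >= 0.
#' @param x0 position of the potential minimum, um.
#' @param h crossover length, um; must be > 0.
#' @return An object of class `clamp_params`.
#' @examples
#' clamp_params(F0 = 18.3, x0 = 0, h = 0.3)
#' @export
clamp_params <- function(F0, x0 = 0, h = 0.3) {
  stopifnot(is.numeric(F0), length(F0) == 1L, is.finite(F0), F0 >= 0,
            is.numeric(x0), length(x0) == 1L, is.finite(x0),
            is.numeric(h), length(h) == 1L, is.finite(h), h > 0)
  structure(list(F0 = F0, x0 = x0, h = h), class = "clamp_params")
}

#' @export
print.clamp_params <- function(x, ...) {
  cat(sprintf("Clamp parameters: F0 = %.4g fN, x0 = %.4g um, h = %.4g um\n",
              x$F0, x$x0, x$h))
  invisible(x)
}

#' Medium (thermal bath) parameters
#'
#' Diffusion coefficient and thermal energy of the suspending medium. The
#' damping constant is derived, never supplied: `gamma = kT / D`
#' (fluctuation-dissipation), so the simulator and the drift estimator share
#' a single mobility.
#'
#' @param D diffusion coefficient, um^2/s; > 0.
#' @param kT thermal energy, fN um. Default 4.11 fN um (298 K).
#' @return An object of class `medium_params` with fields `D`, `kT` and the
#'   derived `gamma` (fN s/um).
#' @examples
#' medium_params(D = 3.8)
#' @export
medium_params <- function(D = 3.8, kT = 4.11) {
  stopifnot(is.numeric(D), length(D) == 1L, is.finite(D), D > 0,
            is.numeric(kT), length(kT) == 1L, is.finite(kT), kT > 0)
  structure(list(D = D, kT = kT, gamma = kT / D), class = "medium_params")
}

#' @export
print.medium_params <- function(x, ...) {
  cat(sprintf("Medium: D = %.4g um^2/s, kT = %.4g fN um, gamma = %.4g fN s/um\n",
              x$D, x$kT, x$gamma))
  invisible(x)
}

#' Clamp potential energy
#'
#' The closed-form potential \eqn{U(x) = F_0 \sqrt{(x-x_0)^2 + h^2}} (fN um).
#' It is minimized at `x0` with value `F0 * h`, is even about `x0`, and
#' approaches the linear force-clamp form \eqn{F_0 |x - x_0|} for
#' \eqn{|x - x_0| \gg h}.
#'
#' @param x position(s), um.
#' @param p a [clamp_params] object.
#' @return Potential energy in fN um, same length as `x`.
#' @examples
#' p <- clamp_params(F0 = 10, x0 = 0, h = 0.5)
#' clamp_potential(0, p)    # F0 * h = 5
#' clamp_potential(0.5, p)  # 10 * sqrt(0.5) = 7.0711
#' @export
clamp_potential <- function(x, p) {
  stopifnot(inherits(p, "clamp_params"))
  if (!all(is.finite(x))) stop("non-finite positions are not allowed")
  p$F0 * sqrt((x - p$x0)^2 + p$h^2)
}

#' Clamp force (signed)
#'
#' The restoring force \eqn{F(x) = -\mathrm{d}U/\mathrm{d}x =
#' -F_0 (x-x_0)/\sqrt{(x-x_0)^2 + h^2}} (fN). Zero at `x0`, odd about `x0`,
#' monotone in magnitude, and saturating at `F0` for \eqn{|x - x_0| \gg h}.
#'
#' @inheritParams clamp_potential
#' @return Signed force in fN (pointing toward `x0`), same length as `x`.
#' @export
clamp_force <- function(x, p) {
  stopifnot(inherits(p, "clamp_params"))
  if (!all(is.finite(x))) stop("non-finite positions are not allowed")
  d <- x - p$x0
  -p$F0 * d / sqrt(d^2 + p$h^2)
}

#' Dimensionless clamp force
#'
#' The master curve \eqn{\tilde F(\tilde x) = \tilde x / \sqrt{\tilde x^2 + 1}}
#' onto which trajectories of particles with different charge collapse after
#' rescaling by their own fitted \eqn{(x_0, h, F_0)}. Odd and bounded in
#' (-1, 1).
#'
#' @param xt dimensionless position \eqn{\tilde x = (x - x_0)/h}.
#' @return Dimensionless force, same length as `xt`.
#' @export
dimensionless_force <- function(xt) {
  xt / sqrt(xt^2 + 1)
}

# default quadrature grid: uniform points over +/- width characteristic
# lengths around x0 (the decay length is max(h, kT/F0)). 16 decay lengths and
# 8001 points keep the truncated tail and trapezoid error of the variance
# below 1e-5 relative even in the sharp (Laplace) limit.
boltzmann_grid <- function(p, m, width = 16, n = 8001L) {
  L <- width * max(p$h, if (p$F0 > 0) m$kT / p$F0 else Inf)
  if (!is.finite(L)) stop("F0 = 0: the clamp potential does not confine; no equilibrium density exists")
  seq(p$x0 - L, p$x0 + L, length.out = n)
}

trapz <- function(x, y) sum((y[-1] + y[-length(y)]) * diff(x)) / 2

#' Boltzmann (equilibrium) position density of the clamp
#'
#' Normalized equilibrium density \eqn{\propto \exp(-U(x)/kT)} of the
#' overdamped dynamics in the clamp potential, evaluated by trapezoid
#' quadrature on a uniform grid. Used as the thermalization oracle for the
#' simulator and the MSD plateau.
#'
#' @param p a [clamp_params] object with `F0 > 0`.
#' @param m a [medium_params] object.
#' @param grid optional uniform position grid (um). Must span at least
#'   +/- 10 max(h, kT/F0) around `x0`; the default grid does.
#' @return A data.frame with columns `x` (um) and `density` (1/um),
#'   trapezoid-normalized to 1 within 1e-6.
#' @export
boltzmann_density <- function(p, m, grid = NULL) {
  stopifnot(inherits(p, "clamp_params"), inherits(m, "medium_params"))
  if (is.null(grid)) grid <- boltzmann_grid(p, m)
  stopifnot(is.numeric(grid), length(grid) >= 101L, !is.unsorted(grid))
  u <- clamp_potential(grid, p)
  dens <- exp(-(u - min(u)) / m$kT)
  z <- trapz(grid, dens)
  dens <- dens / z
  dx <- diff(grid[1:2])
  edge_mass <- (dens[1] + dens[length(dens)]) * dx / 2
  if (edge_mass > 1e-4)
    stop("grid too narrow: probability mass at the grid edges exceeds 1e-4")
  data.frame(x = grid, density = dens)
}

#' Stationary position variance in the clamp
#'
#' Variance of the Boltzmann density, by quadrature. In the sharp-potential
#' limit \eqn{h \to 0} the density is Laplace (double-exponential) with
#' decay length \eqn{kT/F_0} and the variance equals \eqn{2 (kT/F_0)^2};
#' a finite `h` softens the well and widens the distribution.
#'
#' @inheritParams boltzmann_density
#' @return Variance, um^2.
#' @export
stationary_variance <- function(p, m, grid = NULL) {
  if (p$F0 <= 0) stop("F0 = 0: unconfined particle, stationary variance diverges")
  bd <- boltzmann_density(p, m, grid)
  mu <- trapz(bd$x, bd$x * bd$density)
  trapz(bd$x, (bd$x - mu)^2 * bd$density)
}

#' Thermalization (relaxation) time scale of the clamp
#'
#' The order-of-magnitude time for a particle to thermalize in the linear
#' region of the clamp: \eqn{(kT/F_0)^2 / D}, i.e. the time to diffuse over
#' the Boltzmann decay length. Strictly decreasing in `F0` -- stronger clamps
#' thermalize faster.
#'
#' @inheritParams boltzmann_density
#' @return Time scale, s.
#' @export
relaxation_scale <- function(p, m) {
  stopifnot(inherits(p, "clamp_params"), inherits(m, "medium_params"))
  if (p$F0 <= 0) stop("F0 must be > 0")
  (m$kT / p$F0)^2 / m$D
}
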