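---
title: "Methods: calibrating a passive electrostatic force clamp from Brownian trajectories"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: calibrating a passive electrostatic force clamp from Brownian trajectories}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(forceclamp)
```

This vignette is the package's own account of the model it implements, the
estimators it provides, the numerical and design choices that were genuinely
open, and what its synthetic-data tests do and do not demonstrate.

## The physical model

A charged nanoparticle diffuses in water in a shallow nanochannel above a
charged nanoribbon electrode. The water–silica conductivity contrast
flattens the electrostatic field inside the channel so that the attractive
potential felt by the particle is well approximated by the closed form

$$U(x) = F_0 \sqrt{(x - x_0)^2 + h^2},$$

which is harmonic-like within a crossover distance $h$ of the minimum $x_0$
and *linear* beyond it: the force
$F(x) = -F_0 (x - x_0)/\sqrt{(x-x_0)^2 + h^2}$ saturates at the clamp force
$F_0$ for $|x - x_0| \gg h$ (97% of $F_0$ at $4h$, 99% at $7h$). $h$ is of
the order of the channel height. This closed form is the single model used
throughout the package; the full electrode–silica–water field geometry is
out of scope.

Along the clamp axis the particle obeys an overdamped Langevin equation
$\mathrm{d}x = F(x)/\gamma\,\mathrm{d}t + \sqrt{2D\,\mathrm{d}t}\,\xi$ with
damping $\gamma$ and diffusion coefficient $D$. The package enforces
fluctuation–dissipation structurally: `medium_params()` accepts only $D$ and
$kT$ and *derives* $\gamma = kT/D$; no independent mobility exists anywhere.

**Units.** µm, s, fN, and fN·µm ($1\,\mathrm{fN\,\mu m} = 10^{-21}$ J), so
all quantities are $O(1)$–$O(10)$. The default thermal energy is
$kT = 4.11$ fN·µm (298 K); the experiment's temperature is not stated
anywhere, so room temperature is assumed. Defaults mirror the stated
acquisition: 1 kHz frame rate, 50 s trajectories, $D = 3.8\,\mu m^2/s$,
$h = 0.3\,\mu m$, localization noise $\sigma = 10$ nm, clamp forces
1.8–18.3 fN.

## Equilibrium statistics as the package's oracle

`boltzmann_density()` evaluates $p(x) \propto e^{-U(x)/kT}$ by trapezoid
quadrature on a uniform grid and is the reference against which both the
simulator and the MSD analysis are tested. In the sharp limit $h \to 0$ the
density is Laplace with decay length $kT/F_0$ and variance $2(kT/F_0)^2$ — a
closed form used as an independent oracle. The default grid spans ±16 decay
lengths with 8001 points: at ±10 lengths the truncated Laplace tail alone
costs $\sim 3\times 10^{-3}$ of the variance, while ±16/8001 keeps
truncation and discretization below $10^{-5}$ relative, comfortably inside
the $10^{-4}$ oracle tolerance the test suite asserts. A grid whose edge
cells carry more than $10^{-4}$ probability mass is rejected rather than
silently renormalized.

`relaxation_scale()` returns $(kT/F_0)^2/D$, the time to diffuse across the
Boltzmann decay length — an order-of-magnitude thermalization scale (1.37 s
at 1.8 fN, 13 ms at 18.3 fN). For *quantitative* plateau checks the package
uses the better generalization $\tau_w = \mathrm{Var}_\mathrm{eq}/D$, which
reduces to twice the sharp-limit scale as $h \to 0$ and grows with softer
wells.

## The trajectory simulator

`simulate_trajectories()` integrates the Langevin equation by Euler–Maruyama
with sub-stepping (default $\mathrm{d}t_\mathrm{int} = 100\,\mu s$ beneath
1 ms frames) and records positions at the frame rate. Choices:

* **Stability guard.** The simulator refuses to run unless the drift step is
  at most 10% of the diffusive step,
  $F_0\,\mathrm{d}t/\gamma \le 0.1\sqrt{2D\,\mathrm{d}t}$. Multi-particle
  experiments (`synthetic_experiment()`) re-derive the step from the
  strongest drawn particle.
* **Initialization.** `"stationary"` draws $x(0)$ from the Boltzmann density
  by inverse-CDF on the quadrature grid (for thermalized MSD and estimator
  studies); `"point"` starts at a fixed position (for relaxation studies and
  free diffusion).
* **Boundaries.** A reflecting wall sits at ±17.5 µm (half the electrode
  spacing). For every clamped condition studied here the stationary spread
  is ≤ a few µm, so the wall is statistically invisible — verified by a
  KS test between walled and unwalled ensembles.
* **Localization noise** is added to recorded positions as i.i.d. Gaussian
  offsets (default 10 nm), emulating the imaging stage's sub-pixel error.
* **Heterogeneity.** Per-particle clamp forces are drawn log-normal
  (median 8 fN, geometric SD 1.8 by default). Only the fact that charge
  differs between particles is documented for the real experiment; the
  log-normal is this package's choice — it keeps $F_0 > 0$ and spans the
  1.8–18.3 fN range actually studied. In voltage mode the per-particle force
  is exactly $c_i (V - V_\mathrm{off})$, emulating the linear force–voltage
  control (4.3–4.8 V, zero-force offset 4.0 V, ~30 fN/V by default).
* **Determinism.** Identical configuration + seed gives bit-identical
  output; every trajectory's metadata records its ground truth.

One dimension is simulated quantitatively; an optional free-diffusion $y$
exists only for visual fidelity. The simulator treats $D$ as a free
constant: hydrodynamic wall corrections, z-motion and electrode charge
dynamics are not modeled. Halving the integration step moves the stationary
variance by well under 1% at the strongest force studied.

## Drift estimation and the clamp fit

`estimate_drift_profile()` implements the binned conditional-first-moment
(Kramers–Moyal) estimator: steps $v_i = x_{i+1} - x_i$ beginning in the
half-open interval $[x - l/2,\, x + l/2)$ around each grid position are
pooled, and $\hat F(x) = \gamma \langle v_i\rangle/\Delta t$ with standard
error $\gamma\,\mathrm{sd}(v_i)/(\sqrt{n}\,\Delta t)$. Defaults $l = 0.1$ µm
(potential variation per bin $\ll kT$, yet hundreds of steps per central bin
at 50 s) and $n_\mathrm{min} = 50$ (bins below it are reported *absent*,
never zero). Bin edges are half-open and the grid is anchored at integer
multiples of $l$, so the estimator is bit-reproducible and matches a naive
enumeration exactly — one of the acceptance oracles.

`fit_clamp_model()` fits $F(x) = -F_0(x - x_0)/\sqrt{(x-x_0)^2 + h^2}$ by
weighted (1/SE²) Levenberg–Marquardt with data-driven starts (zero crossing
of a lightly smoothed profile, outer-third plateau mean, half-maximum width)
and box bounds $F_0 \in (0, 10^3]$ fN, $h \in [0.01, 5]$ µm. Two issues of
this fit were genuinely open and are resolved as follows:

* **Multi-start.** On weak-force profiles the weighted-SSR surface is nearly
  flat in $h$ and a single start frequently stalls on an $h$ bound even when
  the global optimum is interior (measured: the large majority of bound
  "runaways" at 1.8 fN were local minima). The fit therefore restarts from a
  small set of $h$ values and keeps the lowest weighted SSR.
* **Identifiability and model reduction.** When the fitted $h$ collapses
  onto its lower bound, or its 95% upper limit reaches the upper bound, $h$
  is not identified: as $h \to 0$ the model reduces to the sharp clamp
  $-F_0\,\mathrm{sign}(x - x_0)$ (where $F_0$ is still the fully identified
  plateau force), while as $h \to \infty$ it degenerates to a straight line
  where only $F_0/h$ is constrained and $F_0$ means nothing. In either case
  the fit falls back to the sharp-limit model (closed-form weighted $F_0$
  with the split point searched over bin edges; ties broken by the first
  minimal SSR). Such fits keep a valid `F0_hat` but are *flagged*: without
  $h$ they cannot be rescaled into dimensionless form, so pooling excludes
  them. This matters in practice: at 1.8 fN roughly half of 50 s
  trajectories do not constrain $h$, and keeping their inflated
  saturating-model $F_0$ would bias the recovered force by ~10–15%, while
  the reduced fits recover it within a few percent.

`calibrate_trajectory()` is the full per-trajectory chain and makes two
small, declared corrections:

* **Measured diffusion.** $\gamma$ is never assumed: $D$ is estimated from
  the trajectory's own short-time MSD (first 4 lags, free intercept). In a
  strong clamp even millisecond lags bend below $2D\tau$ (relaxation times
  reach tens of ms), so the calibration iterates once: the measured
  short-time MSD is divided by the confinement factor of an
  Ornstein–Uhlenbeck process matched to the fitted clamp's stationary
  variance, and $D$ is re-fit. Without this, the 18.3 fN force is recovered
  ~8% high; with it, within ~2%.
* **Noise conditioning.** Conditioning steps on *measured* positions
  inflates the apparent drift by $1 + \sigma^2/(D\,\Delta t)$ (the Tweedie
  posterior-mean shift of the true position). At $\sigma = 10$ nm and 1 kHz
  this is +2.6% and is divided out when $\sigma$ is known.

`rescale_and_pool()` maps each unflagged particle onto
$\tilde x = (x - \hat x_0)/\hat h$, $\tilde F = -\hat F/\hat F_0$ (sign
chosen so the master curve is $+\tilde x/\sqrt{\tilde x^2 + 1}$; the
physical restoring force is its negative) and averages within half-open
$\tilde x$ bins of pitch 0.25 over $|\tilde x| \le 6$. The pooled standard
error is the within-bin standard error of the contributing points — a
declared convention, as is the per-bin drift SE above; no claim is made that
the original experiment computed its error bars the same way.

`force_voltage_fit()` is ordinary least squares of recovered force against
voltage with slope/intercept standard errors and $R^2$; the voltage pipeline
reports whether the 95% slope interval covers the programmed ground truth.

## MSD analysis

`compute_msd()` supports time-averaged (all overlapping pairs within a
trajectory; standard single-particle-tracking practice) and ensemble
($x(\tau) - x(0)$ across trajectories) modes, with pair counts recorded. For
a single trajectory the standard error uses the *non-overlapping window
count* $n/k$ as the effective sample size — overlapping pairs at lag $k$ are
strongly correlated, and the naive $\sqrt{n_\mathrm{pairs}}$ SE is far too
small at long lags. The default lag grid is log-spaced, 25 points per decade
from the frame interval to a fifth of the duration.

`predict_msd_numerical()` exists because the saturating force admits no
closed-form MSD at arbitrary times: it simulates a stationary-start ensemble
(with the integration step refined to resolve the well-curvature time
$\gamma h/F_0$ and the stability criterion) and evaluates its MSD; by
ergodicity the default time-averaged mode equals the ensemble MSD in
expectation while using far more pairs. `msd_asymptotics()` supplies the two
limits: $2D\tau$ (plus $2\sigma^2$ when noise is declared) and the plateau
$2\,\mathrm{Var}_\mathrm{eq}$.

`relaxation_time()` needs an operational definition, which no source
states: the plateau is the mean MSD over the last decade of lags, a curve
counts as plateaued only if its last-decade slope is below 5% of its initial
slope, and the relaxation time is the first lag reaching $(1 - 1/e)$ of the
plateau, linearly interpolated. The definition is deterministic and
closed-form-checkable (exact on $P(1 - e^{-\tau/\tau_0})$ to the grid
resolution); curves that have not plateaued return `NA` with a diagnostic
rather than an extrapolation. A single 50 s trajectory at 1.8 fN genuinely
does not satisfy the plateau criterion — its relaxation time (~1.4 s) is too
close to the usable lag range — so the figure-style pipeline reports the
diagnostic for that condition and quantitative relaxation/plateau checks use
simulated ensembles.

## The synthetic imaging stage

`render_ipsf_frame()` is a *phenomenological* stand-in for interferometric
scattering (iSCAT) frames: background × (1 + contrast · cos(2πr/Λ) ·
Gaussian envelope), an optional static additive band for the electrode, and
Poisson shot noise. Defaults: 0.143 µm pixels (at which 10 nm is 0.07 px),
ring period 0.25 µm, envelope σ = 2 µm, contrast 0.03 on a 10⁴-count
background. It reproduces the *geometry* the localizer relies on — many
concentric rings, a distorted center, partial occlusion — and nothing else
(no axial dependence, no physical 3-wave interference).

Localization is two-stage, restricted to the annulus [3, 10] ring periods
so the central lobe and known band pixels are excluded:

1. **Radial symmetry:** every 2×2 pixel cell contributes a line through its
   midpoint along its Roberts-cross gradient; for a radially symmetric
   pattern all lines meet at the center, found as the gradient-weighted
   least-squares intersection. This stage is seeded by a box-filtered
   squared-intensity peak and is accurate to a few tenths of a pixel — it
   only needs to place the annulus and the search window.
2. **Ring coherence:** the score
   $|\sum_k I_k e^{2\pi i\, r_k(c)/\Lambda}|^2$ is smooth in the candidate
   center and sharply maximal where the rings are phase-coherent; it is
   scanned coarsely (0.5 px over ±5 px, absorbing stage-1 error and ring
   ambiguity), refined at 0.25 px, and finished with a 2-D quadratic fit on
   a 0.1 px grid (fallback to the grid maximum if the fitted quadratic is
   not concave or shifts beyond the grid).

On background-subtracted synthetic frames at the default photon budget with
a static band this achieves a few nm RMS (well under the 10 nm / 0.07 px
contract), is unbiased below 0.005 px, and degrades less than 2× under ≤30%
annulus occlusion. Frames whose annulus is mostly occluded or off-frame are
flagged as failures, never extrapolated. `median_background()` implements
aligned median background subtraction (per-pixel temporal median), which
removes the static band provided the particle keeps moving.
`link_localizations()` is deliberately simple greedy nearest-neighbor
linking with a gap memory — the synthetic scenes have one or two particles,
and a global assignment solver is not warranted.

## Problem sizes, runtimes and test design

The test suite checks every closed-form example directly, every invariant as
a property over seeded ensembles, and the end-to-end contracts at the
standard operating point. Ensemble sizes were chosen so that each stochastic
assertion has ≥2.5σ headroom at its stated tolerance while the whole suite
runs in a couple of minutes on one CPU: 24 trajectories per operating point
for force recovery (the median's sampling SD at 1.8 fN is ~10%), 800
stationary trajectories per cell for the 3×3 plateau grid (per-lag SE ≤2% of
the plateau), 200 noisy frames for localization. The acceptance script
(`scripts/acceptance.R`) re-runs the force-recovery, diffusion-recovery and
localization analyses from scratch under a caller-supplied seed in about
15 s.

## What passing these tests does and does not show

The synthetic generator emulates the *statistical* structure of the
experiment — exact clamp-form force fields, homogeneous D, Gaussian
localization noise, Poisson shot noise, a static occluder. Passing tests
therefore demonstrates that the estimators are correct and well-calibrated
under the stated model. Real recordings add drift of the setup, hydrodynamic
coupling to the walls, axial motion through the interferometric point-spread
function, non-Gaussian localization errors near the electrode, and deviations
of the true field from the closed form near the wire; none of these are
represented, and agreement on synthetic data does not bound their effects.
Known limitations of the estimators themselves: per-trajectory h is
unidentifiable for weak clamps at 50 s (handled by model reduction, so F0
remains usable but such particles drop out of pooling), single-trajectory
time-averaged MSDs carry correlated errors at long lags (reflected in the
effective-sample-size SEs), and the localization-noise drift correction
assumes the noise level is known.
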