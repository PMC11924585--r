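#' Phenomenological interferometric-ring PSF model
#'
#' Synthetic stand-in for wide-field interferometric scattering (iSCAT)
#' frames: a radially symmetric fringe pattern
#' \eqn{B (1 + c \cos(2\pi r/\Lambda) e^{-r^2/2\sigma^2})} around the particle
#' (central lobe plus concentric rings), an optional static additive band
#' representing scattering from the embedded electrode, and Poisson shot
#' noise. It is a geometric model of the ring structure, not a physical
#' interferometric PSF computation: the analysis stage only needs ring
#' geometry and occlusion.
#'
#' @param pixel_size um per pixel. Default 0.143 um/px (at which a 10 nm
#'   localization error is 0.07 px).
#' @param ring_period fringe period \eqn{\Lambda}, um.
#' @param envelope_sigma Gaussian envelope of the fringe contrast, um.
#' @param inner_mask_radius,outer_radius annulus (um) used for localization:
#'   the central lobe (distorted near the electrode) is excluded and only the
#'   outer rings are used. Defaults 3 and 10 ring periods.
#' @param contrast interferometric fringe contrast, in (0, 1).
#' @param background_level mean background, counts (sets the shot-noise
#'   budget).
#' @param electrode_band optional static occluding stripe: list/vector with
#'   `center` (um, x position), `width` (um) and `amplitude` (counts).
#' @param frame_size_px frame side length, pixels.
#' @return An object of class `ipsf_model`.
#' @export
ipsf_model <- function(pixel_size = 0.143, ring_period = 0.25,
                       envelope_sigma = 2.0,
                       inner_mask_radius = 3 * ring_period,
                       outer_radius = 10 * ring_period,
                       contrast = 0.03, background_level = 1e4,
                       electrode_band = NULL, frame_size_px = 64L) {
  stopifnot(pixel_size > 0, ring_period > 0, envelope_sigma > 0,
            inner_mask_radius < outer_radius,
            contrast > 0, contrast < 1, background_level > 0,
            frame_size_px >= 16L)
  if (!is.null(electrode_band)) {
    electrode_band <- as.list(electrode_band)
    stopifnot(all(c("center", "width", "amplitude") %in% names(electrode_band)))
  }
  structure(list(pixel_size = pixel_size, ring_period = ring_period,
                 envelope_sigma = envelope_sigma,
                 inner_mask_radius = inner_mask_radius,
                 outer_radius = outer_radius, contrast = contrast,
                 background_level = background_level,
                 electrode_band = electrode_band,
                 frame_size_px = as.integer(frame_size_px)),
            class = "ipsf_model")
}

#' A single camera frame
#'
#' @param counts matrix of pixel counts (rows = y, columns = x).
#' @param pixel_size um per pixel.
#' @param true_center optional known center `c(x, y)` in um (synthetic data).
#' @return An object of class `image_frame`.
#' @export
image_frame <- function(counts, pixel_size, true_center = NULL) {
  stopifnot(is.matrix(counts), pixel_size > 0)
  structure(list(counts = counts, pixel_size = pixel_size,
                 true_center = true_center), class = "image_frame")
}

# pixel-center coordinates (um): column j -> x = (j - 0.5) * pixel_size
pixel_axes <- function(counts, pixel_size) {
  list(x = (seq_len(ncol(counts)) - 0.5) * pixel_size,
       y = (seq_len(nrow(counts)) - 0.5) * pixel_size)
}

#' Render one synthetic interferometric-ring frame
#'
#' @param model an [ipsf_model].
#' @param center particle center `c(x, y)`, um; must lie inside the frame.
#' @param seed optional integer seed for the shot noise.
#' @param shot_noise add Poisson noise (`FALSE` gives the noiseless
#'   expectation, useful as ground truth).
#' @return An [image_frame] with `true_center` recorded.
#' @export
render_ipsf_frame <- function(model, center, seed = NULL, shot_noise = TRUE) {
  stopifnot(inherits(model, "ipsf_model"), length(center) == 2L)
  n <- model$frame_size_px
  fw <- n * model$pixel_size
  if (center[1] < 0 || center[1] > fw || center[2] < 0 || center[2] > fw)
    stop("center outside the frame")
  ax <- pixel_axes(matrix(0, n, n), model$pixel_size)
  dx <- matrix(ax$x - center[1], n, n, byrow = TRUE)
  dy <- matrix(ax$y - center[2], n, n)
  r <- sqrt(dx^2 + dy^2)
  I <- model$background_level *
    (1 + model$contrast * cos(2 * pi * r / model$ring_period) *
       exp(-r^2 / (2 * model$envelope_sigma^2)))
  if (!is.null(model$electrode_band)) {
    b <- model$electrode_band
    in_band <- abs(matrix(ax$x, n, n, byrow = TRUE) - b$center) < b$width / 2
    I[in_band] <- I[in_band] + b$amplitude
  }
  if (shot_noise) {
    if (!is.null(seed)) set.seed(seed)
    I <- matrix(stats::rpois(length(I), I), n, n)
  }
  image_frame(I, model$pixel_size, true_center = center)
}

#' Temporal median background of an image stack
#'
#' Per-pixel median over frames. With the particle moving (visiting any given
#' pixel in a minority of frames) the median retains only the static features
#' -- flat background and the electrode band -- so subtracting it suppresses
#' the band while preserving the moving ring pattern.
#'
#' @param stack list of [image_frame]s (>= 11 frames).
#' @return An [image_frame] holding the median background.
#' @export
median_background <- function(stack) {
  stopifnot(length(stack) >= 11L, inherits(stack[[1]], "image_frame"))
  dims <- dim(stack[[1]]$counts)
  arr <- vapply(stack, function(f) f$counts, matrix(0, dims[1], dims[2]))
  med <- apply(arr, c(1, 2), stats::median)
  image_frame(med, stack[[1]]$pixel_size)
}

#' Subtract a background frame
#' @param frame,background [image_frame]s of equal size.
#' @return An [image_frame] of differences (may be negative).
#' @export
subtract_background <- function(frame, background) {
  stopifnot(all(dim(frame$counts) == dim(background$counts)))
  image_frame(frame$counts - background$counts, frame$pixel_size,
              true_center = frame$true_center)
}

# 2-D box sum by two 1-D running sums (NA borders)
boxsum <- function(m, k) {
  f <- rep(1, k)
  a <- apply(m, 2, function(col) stats::filter(col, f, sides = 2))
  t(apply(a, 1, function(row) stats::filter(row, f, sides = 2)))
}

# coarse detection on a background-subtracted frame: the ring pattern is the
# only extended structure left, so the box-filtered squared intensity peaks
# at the particle (to within a pixel or two -- enough to seed stage 1)
detect_center <- function(frame, box_px = 25L) {
  cts <- frame$counts
  w <- (cts - stats::median(cts))^2
  E <- boxsum(w, min(box_px, nrow(cts) - 2L))
  E[is.na(E)] <- -Inf
  ij <- arrayInd(which.max(E), dim(E))
  c((ij[2] - 0.5) * frame$pixel_size, (ij[1] - 0.5) * frame$pixel_size)
}

# pixels to exclude because of the (known, static) electrode band
band_exclusion <- function(model, ax, n) {
  if (is.null(model$electrode_band)) return(matrix(FALSE, n, n))
  b <- model$electrode_band
  abs(matrix(ax$x, n, n, byrow = TRUE) - b$center) < b$width / 2 + model$pixel_size
}

#' Sub-pixel localization by radial symmetry of the outer rings
#'
#' Two stages, both restricted to the annulus
#' `[inner_mask_radius, outer_radius]` around the current guess so that the
#' (possibly distorted or occluded) central lobe and any pixels under the
#' electrode band are excluded:
#' \enumerate{
#'   \item radial-symmetry center: every 2x2 pixel cell contributes a line
#'     through its midpoint along its intensity gradient; for a radially
#'     symmetric pattern all lines pass through the center, which is found as
#'     the gradient-magnitude-weighted least-squares intersection point;
#'   \item sub-pixel refinement: a ring-coherence score
#'     \eqn{|\sum_k I_k e^{2\pi i r_k(c)/\Lambda}|^2} (smooth in the candidate
#'     center c) is evaluated on a 5x5 grid of 0.1 px pitch around the
#'     stage-1 estimate and a 2-D quadratic peak is fitted.
#' }
#'
#' @param frame an [image_frame], normally background-subtracted.
#' @param model the [ipsf_model] (annulus geometry, ring period, band).
#' @param initial_guess optional center guess `c(x, y)`, um; defaults to the
#'   intensity-squared centroid of the frame.
#' @return An object of class `localization`: list with `center` (um,
#'   `c(x, y)`), `quality` (ring-coherence fraction in [0, 1]), `ok`
#'   (logical) and `reason` (why a localization failed). Failure (annulus
#'   off-frame or nearly fully occluded) is flagged, never silently
#'   extrapolated.
#' @export
localize_rings <- function(frame, model, initial_guess = NULL) {
  stopifnot(inherits(frame, "image_frame"), inherits(model, "ipsf_model"))
  cts <- frame$counts
  n <- nrow(cts)
  ax <- pixel_axes(cts, frame$pixel_size)
  fail <- function(reason) structure(list(center = c(NA_real_, NA_real_),
                                          quality = NA_real_, ok = FALSE,
                                          reason = reason),
                                     class = "localization")
  guess <- if (is.null(initial_guess)) detect_center(frame) else initial_guess
  fw <- n * frame$pixel_size
  if (any(!is.finite(guess)) || guess[1] < 0 || guess[1] > fw ||
      guess[2] < 0 || guess[2] > fw)
    return(fail("initial guess outside the frame"))

  excl <- band_exclusion(model, ax, n)
  px <- matrix(ax$x, n, n, byrow = TRUE)
  py <- matrix(ax$y, n, n)

  annulus_valid <- function(center) {
    r <- sqrt((px - center[1])^2 + (py - center[2])^2)
    r >= model$inner_mask_radius & r <= model$outer_radius & !excl
  }
  # require a usable fraction of the annulus inside the frame and unmasked
  ann_area <- pi * (model$outer_radius^2 - model$inner_mask_radius^2) /
    frame$pixel_size^2
  valid0 <- annulus_valid(guess)
  if (sum(valid0) < 0.3 * ann_area)
    return(fail("annulus mostly occluded or off-frame"))

  ## stage 1: radial-symmetry (gradient-line intersection) on 2x2 cells
  A <- cts[-n, -n]; B <- cts[-n, -1]; C <- cts[-1, -n]; D <- cts[-1, -1]
  d1 <- D - A   # derivative along (+x, +y)
  d2 <- B - C   # derivative along (+x, -y)
  gx <- (d1 + d2) / 2
  gy <- (d1 - d2) / 2
  mx <- (px[-n, -n] + px[-n, -1]) / 2   # cell midpoints
  my <- (py[-n, -n] + py[-1, -n]) / 2
  rmid <- sqrt((mx - guess[1])^2 + (my - guess[2])^2)
  cell_excl <- excl[-n, -n] | excl[-n, -1] | excl[-1, -n] | excl[-1, -1]
  use <- rmid >= model$inner_mask_radius & rmid <= model$outer_radius &
    !cell_excl & (gx^2 + gy^2) > 0
  if (sum(use) < 20L) return(fail("too few usable gradient cells"))
  gxu <- gx[use]; gyu <- gy[use]; mxu <- mx[use]; myu <- my[use]
  m11 <- sum(gyu^2); m22 <- sum(gxu^2); m12 <- -sum(gxu * gyu)
  b1 <- sum(gyu^2 * mxu - gxu * gyu * myu)
  b2 <- sum(-gxu * gyu * mxu + gxu^2 * myu)
  det <- m11 * m22 - m12^2
  if (abs(det) < .Machine$double.eps * (m11 + m22)^2)
    return(fail("degenerate gradient geometry"))
  c1 <- c(m22 * b1 - m12 * b2, m11 * b2 - m12 * b1) / det
  if (any(c1 < 0) || any(c1 > fw)) return(fail("stage-1 center off-frame"))

  ## stage 2: peak of the ring-coherence score map around c1.
  ## The score |sum_k I_k exp(2*pi*i*r_k(c)/Lambda)|^2 is smooth in the
  ## candidate center c and maximal where the rings are coherent; it is
  ## sampled coarsely (0.25 px over +/- 1 px, absorbing the stage-1 error)
  ## and the maximum refined by a 2-D quadratic fit on a 0.1 px grid.
  valid <- annulus_valid(c1)
  I <- cts[valid] - mean(cts[valid])
  vx <- px[valid]; vy <- py[valid]
  norm2 <- sum(I^2)
  score <- function(cc) {
    r <- sqrt((vx - cc[1])^2 + (vy - cc[2])^2)
    ph <- 2 * pi * r / model$ring_period
    (sum(I * cos(ph))^2 + sum(I * sin(ph))^2) / (norm2 * length(I))
  }
  psz <- frame$pixel_size
  # vectorized score over a matrix of candidate centers (rows = candidates)
  score_many <- function(cands) {
    dx <- outer(cands[, 1], vx, "-")
    dy <- outer(cands[, 2], vy, "-")
    ph <- (2 * pi / model$ring_period) * sqrt(dx * dx + dy * dy)
    ((cos(ph) %*% I)^2 + (sin(ph) %*% I)^2)[, 1] / (norm2 * length(I))
  }
  grid_around <- function(ctr, half, step) {
    offs <- seq(-half, half, by = step) * psz
    cbind(ctr[1] + rep(offs, times = length(offs)),
          ctr[2] + rep(offs, each = length(offs)))
  }
  # coarse (absorbs several px of stage-1 error), then mid-level refinement
  g1 <- grid_around(c1, 5, 0.5)
  c2 <- g1[which.max(score_many(g1)), ]
  g2 <- grid_around(c2, 0.6, 0.2)
  c2 <- g2[which.max(score_many(g2)), ]
  step <- 0.1 * psz
  gridpts <- expand.grid(dx = seq(-2L, 2L) * step, dy = seq(-2L, 2L) * step)
  sc2 <- score_many(cbind(c2[1] + gridpts$dx, c2[2] + gridpts$dy))
  qf <- stats::lm(sc2 ~ dx + dy + I(dx^2) + I(dy^2) + I(dx * dy),
                  data = gridpts)
  co <- stats::coef(qf)
  H <- matrix(c(2 * co[["I(dx^2)"]], co[["I(dx * dy)"]],
                co[["I(dx * dy)"]], 2 * co[["I(dy^2)"]]), 2, 2)
  shift <- c(0, 0)
  ev <- tryCatch(eigen(H, symmetric = TRUE, only.values = TRUE)$values,
                 error = function(e) c(0, 0))
  if (all(ev < 0)) {
    shift <- tryCatch(-solve(H, c(co[["dx"]], co[["dy"]])),
                      error = function(e) c(0, 0))
    if (any(abs(shift) > 2.5 * step)) shift <- c(0, 0)  # keep the grid max
  }
  center <- c2 + shift
  if (any(center < 0) || any(center > fw))
    return(fail("refined center off-frame"))
  structure(list(center = center, quality = score(center), ok = TRUE,
                 stage1 = c1, reason = NA_character_), class = "localization")
}

#' Link per-frame localizations into trajectories
#'
#' Greedy nearest-neighbor linking for the sparse (single- or few-particle)
#' regime: each detection is attached to the nearest open chain end provided
#' the displacement does not exceed `max_disp` (scaled by the square root of
#' the frame gap); otherwise it starts a new chain. Chains survive up to
#' `memory` missed frames; skipped frames are recorded as gaps.
#'
#' @param per_frame list (one element per frame, in order) of data.frames
#'   with columns `x`, `y` (um); zero-row frames mark missed detections.
#' @param max_disp maximum one-frame link displacement, um. A sensible
#'   default is `5 * sqrt(2 * D * frame_dt)`.
#' @param memory maximum number of consecutive missed frames a chain
#'   survives.
#' @return A list of chains, each a data.frame `(frame, x, y)` with an
#'   attribute `gaps` (the frame indices skipped inside the chain).
#' @export
link_localizations <- function(per_frame, max_disp, memory = 2L) {
  stopifnot(length(per_frame) >= 1L, max_disp > 0)
  chains <- list()   # each: list(frame=, x=, y=, open=)
  for (f in seq_along(per_frame)) {
    det <- per_frame[[f]]
    if (is.null(det) || nrow(det) == 0L) next
    open <- which(vapply(chains, function(ch)
      f - ch$frame[length(ch$frame)] <= memory + 1L, TRUE))
    taken_chain <- integer(0); taken_det <- integer(0)
    if (length(open)) {
      pairs <- expand.grid(ci = open, di = seq_len(nrow(det)))
      pairs$gap <- vapply(pairs$ci, function(ci)
        f - chains[[ci]]$frame[length(chains[[ci]]$frame)], 0L)
      pairs$dist <- sqrt(
        (det$x[pairs$di] - vapply(pairs$ci, function(ci)
          chains[[ci]]$x[length(chains[[ci]]$x)], 0))^2 +
        (det$y[pairs$di] - vapply(pairs$ci, function(ci)
          chains[[ci]]$y[length(chains[[ci]]$y)], 0))^2)
      pairs <- pairs[pairs$dist <= max_disp * sqrt(pairs$gap), , drop = FALSE]
      pairs <- pairs[order(pairs$dist), , drop = FALSE]
      for (k in seq_len(nrow(pairs))) {
        ci <- pairs$ci[k]; di <- pairs$di[k]
        if (ci %in% taken_chain || di %in% taken_det) next
        chains[[ci]]$frame <- c(chains[[ci]]$frame, f)
        chains[[ci]]$x <- c(chains[[ci]]$x, det$x[di])
        chains[[ci]]$y <- c(chains[[ci]]$y, det$y[di])
        taken_chain <- c(taken_chain, ci); taken_det <- c(taken_det, di)
      }
    }
    for (di in setdiff(seq_len(nrow(det)), taken_det))
      chains[[length(chains) + 1L]] <- list(frame = f, x = det$x[di],
                                            y = det$y[di])
  }
  lapply(chains, function(ch) {
    d <- data.frame(frame = ch$frame, x = ch$x, y = ch$y)
    gaps <- setdiff(seq(min(ch$frame), max(ch$frame)), ch$frame)
    attr(d, "gaps") <- gaps
    d
  })
}

#' Write an image stack as multi-frame 16-bit TIFF
#'
#' @param stack list of [image_frame]s with counts in [0, 65535].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_image_stack <- function(stack, path) {
  imgs <- lapply(stack, function(f) {
    cts <- pmin(pmax(round(f$counts), 0), 65535)
    cts / 65535
  })
  tiff::writeTIFF(imgs, path, bits.per.sample = 16L)
  invisible(path)
}

#' Read a multi-frame 16-bit TIFF written by [write_image_stack]
#'
#' @param path file path.
#' @param pixel_size um per pixel to attach to the frames.
#' @return A list of [image_frame]s (integer counts).
#' @export
read_image_stack <- function(path, pixel_size) {
  imgs <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(imgs)) imgs <- list(imgs)
  lapply(imgs, function(m) image_frame(round(m * 65535), pixel_size))
}
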