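# shared geometry for the imaging tests
PSZ <- 0.143
FCTR <- c(32, 32) * PSZ   # frame center of the default 64 px frame

test_that("noiseless rendering is radially symmetric; the band breaks it locally", {
  mod <- ipsf_model()
  fr <- render_ipsf_frame(mod, FCTR, shot_noise = FALSE)
  # reflection through the center maps pixel (i, j) to (65 - i, 65 - j)
  flipped <- fr$counts[64:1, 64:1]
  expect_lt(max(abs(fr$counts - flipped)), 1e-12 * mod$background_level)
  band <- list(center = FCTR[1] - 1.0, width = 0.4, amplitude = 1500)
  modb <- ipsf_model(electrode_band = band)
  frb <- render_ipsf_frame(modb, FCTR, shot_noise = FALSE)
  dev <- abs(frb$counts - frb$counts[64:1, 64:1])
  cols <- (seq_len(64) - 0.5) * PSZ
  in_band <- abs(cols - band$center) < band$width / 2 |
    abs(rev(cols) - band$center) < band$width / 2
  expect_true(all(dev[, !in_band] < 1e-12 * modb$background_level))
  expect_gt(max(dev[, in_band]), 1000)
})

test_that("shot noise has the declared Poisson mean on a near-flat field", {
  mod <- ipsf_model(contrast = 1e-9, background_level = 1e4)
  fr <- render_ipsf_frame(mod, FCTR, seed = 2L)
  n <- length(fr$counts)
  se <- sqrt(1e4 / n)
  expect_lt(abs(mean(fr$counts) - 1e4), 3 * se)
  expect_true(all(fr$counts >= 0))
})

test_that("median background retains static features and removes them on subtraction", {
  mod <- ipsf_model()
  fr <- render_ipsf_frame(mod, FCTR, shot_noise = FALSE)
  stack <- rep(list(fr), 12L)
  bg <- median_background(stack)
  expect_identical(bg$counts, fr$counts)
  expect_true(all(subtract_background(fr, bg)$counts == 0))
  # particle-free noisy stack: residual consistent with zero
  flat <- ipsf_model(contrast = 1e-9)
  set.seed(4)
  stack2 <- lapply(1:31, function(i) render_ipsf_frame(flat, FCTR))
  bg2 <- median_background(stack2)
  resid <- subtract_background(stack2[[1]], bg2)$counts
  expect_lt(abs(mean(resid)), 3 * sqrt(1e4 / length(resid)))
})

test_that("a moving particle leaves the electrode band suppressed 10x after subtraction", {
  band <- list(center = FCTR[1] - 1.2, width = 0.5, amplitude = 2000)
  mod <- ipsf_model(electrode_band = band)
  set.seed(6)
  ctrs <- cbind(runif(40, FCTR[1] - 1.5, FCTR[1] + 1.5),
                runif(40, FCTR[2] - 1.5, FCTR[2] + 1.5))
  stack <- lapply(1:40, function(i) render_ipsf_frame(mod, ctrs[i, ]))
  bg <- median_background(stack)
  sub <- subtract_background(stack[[1]], bg)$counts
  cols <- (seq_len(64) - 0.5) * PSZ
  in_band <- abs(cols - band$center) < band$width / 2
  far_rows <- 1:10   # away from the particle rings
  expect_lt(abs(mean(sub[far_rows, in_band])), band$amplitude / 10)
})

test_that("noiseless frames are localized to well under a hundredth of a pixel", {
  mod <- ipsf_model()
  # center exactly on a pixel center
  ctr0 <- (c(32, 32) - 0.5) * PSZ
  fr <- render_ipsf_frame(mod, ctr0, shot_noise = FALSE)
  fr$counts <- fr$counts - mod$background_level
  loc <- localize_rings(fr, mod)
  expect_true(loc$ok)
  expect_lt(sqrt(sum((loc$center - ctr0)^2)) / PSZ, 1e-3)
  # 5x5 grid of known sub-pixel offsets
  offs <- expand.grid(dx = seq(-0.4, 0.4, by = 0.2),
                      dy = seq(-0.4, 0.4, by = 0.2))
  errs <- apply(offs, 1, function(o) {
    ctr <- ctr0 + as.numeric(o) * PSZ
    f <- render_ipsf_frame(mod, ctr, shot_noise = FALSE)
    f$counts <- f$counts - mod$background_level
    l <- localize_rings(f, mod)
    sqrt(sum((l$center - ctr)^2)) / PSZ
  })
  expect_lt(max(errs), 0.01)
})

test_that("localization is unbiased over many noisy frames", {
  mod <- ipsf_model()
  set.seed(8)
  errs <- t(vapply(1:500, function(i) {
    ctr <- FCTR + runif(2, -0.5, 0.5) * PSZ
    fr <- render_ipsf_frame(mod, ctr)
    fr$counts <- fr$counts - mod$background_level
    loc <- localize_rings(fr, mod)
    loc$center - ctr
  }, numeric(2)))
  expect_lt(max(abs(colMeans(errs))) / PSZ, 0.005)
})

test_that("localization error shrinks with photon budget and tolerates occlusion", {
  rms_for <- function(mod, n = 100L, seed = 9L) {
    set.seed(seed)
    errs <- vapply(seq_len(n), function(i) {
      ctr <- FCTR + runif(2, -0.5, 0.5) * PSZ
      fr <- render_ipsf_frame(mod, ctr)
      # remove the static part (flat background + band) up front, as the
      # median-subtraction stage does in the full pipeline
      static <- matrix(mod$background_level, 64, 64)
      if (!is.null(mod$electrode_band)) {
        b <- mod$electrode_band
        cols <- abs((seq_len(64) - 0.5) * PSZ - b$center) < b$width / 2
        static[, cols] <- static[, cols] + b$amplitude
      }
      fr$counts <- fr$counts - static
      loc <- localize_rings(fr, mod)
      sqrt(sum((loc$center - ctr)^2))
    }, 0)
    sqrt(mean(errs^2))
  }
  lo <- rms_for(ipsf_model(background_level = 1e4))
  hi <- rms_for(ipsf_model(background_level = 4e4))
  expect_lt(hi, lo)
  band <- list(center = FCTR[1] - 1.0, width = 0.6, amplitude = 2000)
  occ <- rms_for(ipsf_model(background_level = 1e4, electrode_band = band))
  expect_lt(occ, 2 * lo)
})

test_that("impossible localizations are flagged, not extrapolated", {
  mod <- ipsf_model()
  fr <- render_ipsf_frame(mod, FCTR, shot_noise = FALSE)
  # guess far outside the frame
  bad <- localize_rings(fr, mod, initial_guess = c(50, 50))
  expect_false(bad$ok)
  # annulus fully occluded by a frame-wide band
  wide <- ipsf_model(electrode_band = list(center = FCTR[1], width = 10,
                                           amplitude = 100))
  froc <- render_ipsf_frame(wide, FCTR, shot_noise = FALSE)
  occ <- localize_rings(froc, wide, initial_guess = FCTR)
  expect_false(occ$ok)
  expect_match(occ$reason, "occluded")
})

test_that("nearest-neighbor linking chains particles and records gaps", {
  # single particle, contiguous frames: identity ordering
  pf <- lapply(1:10, function(f) data.frame(x = 0.01 * f, y = 0.5))
  ch <- link_localizations(pf, max_disp = 0.1)
  expect_length(ch, 1L)
  expect_identical(ch[[1]]$frame, 1:10)
  expect_length(attr(ch[[1]], "gaps"), 0L)
  # two well-separated particles: two chains, no swaps
  pf2 <- lapply(1:10, function(f)
    data.frame(x = c(0.01 * f, 3 + 0.01 * f), y = c(0.5, 0.5)))
  ch2 <- link_localizations(pf2, max_disp = 0.1)
  expect_length(ch2, 2L)
  expect_true(all(ch2[[1]]$x < 1) || all(ch2[[1]]$x > 1))
  expect_true(all(ch2[[2]]$x < 1) || all(ch2[[2]]$x > 1))
  # a dropped frame is flagged as a gap and the chain continues
  pf3 <- pf
  pf3[[5]] <- data.frame(x = numeric(0), y = numeric(0))
  ch3 <- link_localizations(pf3, max_disp = 0.1)
  expect_length(ch3, 1L)
  expect_identical(attr(ch3[[1]], "gaps"), 5L)
  expect_identical(nrow(ch3[[1]]), 9L)
  # displacements beyond max_disp break the chain
  pf4 <- lapply(1:6, function(f) data.frame(x = ifelse(f > 3, 5, 0), y = 0))
  ch4 <- link_localizations(pf4, max_disp = 0.5)
  expect_length(ch4, 2L)
})

test_that("image stacks round-trip through 16-bit TIFF", {
  mod <- ipsf_model()
  set.seed(10)
  stack <- lapply(1:3, function(i) render_ipsf_frame(mod, FCTR))
  path <- tempfile(fileext = ".tif")
  write_image_stack(stack, path)
  back <- read_image_stack(path, PSZ)
  expect_length(back, 3L)
  expect_equal(back[[1]]$counts, round(stack[[1]]$counts), tolerance = 1e-9)
  unlink(path)
})
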