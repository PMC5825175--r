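#' Render a structured stimulation image
#'
#' Generates one image (or, for moving gratings, a frame sequence) of current
#' amplitudes on a 500 x 500 grid of 10 um pixels (5 x 5 mm), in one of four
#' modes: blurred `spots`, blurred `lines`, a `static_grating`, or a
#' `moving_grating` drifting in the direction of the wave.  Static images are
#' scaled so the largest-magnitude pixel is exactly +/-250 uA; a moving
#' grating is scaled over the whole frame set.
#'
#' Randomized choices follow the generation rules of the recorded protocol:
#' up to four spots (max 1.5 mm before blurring) or lines (min length 1 mm),
#' orientations uniform on 0-179 degrees in 1 degree steps, grating spatial
#' frequency below the 0.5 cycles/mm Nyquist limit set by the 1 mm electrode
#' pitch, and drift rates in 0.1 Hz steps up to 2 Hz.  Spots and lines are
#' smoothed with a Gaussian blur (default SD 100 um) and each feature gets an
#' independent random polarity.
#'
#' @param mode One of `"spots"`, `"lines"`, `"static_grating"`,
#'   `"moving_grating"`.
#' @param seed Integer seed driving all random choices.
#' @param frequency_hz Pulse rate; a moving grating emits one frame per pulse
#'   over its 300 ms duration.
#' @param blur_sd_um Gaussian blur SD for spots/lines, micrometres.
#' @param max_ua Scaling target for the largest-magnitude pixel, uA.
#'
#' @return For static modes, a 500 x 500 matrix of class `stim_image` with
#'   attributes `mode` and `pixel_pitch_um = 10`.  For `moving_grating`, a
#'   list of such matrices (class `stim_image_seq`) with drift metadata.
#' @export
render_structured_image <- function(mode = c("spots", "lines",
                                             "static_grating",
                                             "moving_grating"),
                                    seed = 1, frequency_hz = 30,
                                    blur_sd_um = 100, max_ua = 250) {
  mode <- match.arg(mode)
  npx <- 500L
  px_mm <- 100 # pixels per mm at 10 um pitch
  with_seed(derive_seed(seed, paste0("image_", mode)), {
    if (mode == "spots") {
      img <- matrix(0, npx, npx)
      for (k in seq_len(sample(1:4, 1))) {
        ctr <- runif(2, 1, npx)
        radius <- runif(1, 0.1, 0.75) * px_mm # diameter up to 1.5 mm
        sign_k <- sample(c(-1, 1), 1)
        img <- img + sign_k * disc_mask(npx, ctr, radius)
      }
      img <- gaussian_blur(img, blur_sd_um / 10)
      scale_image(img, max_ua, mode)
    } else if (mode == "lines") {
      img <- matrix(0, npx, npx)
      for (k in seq_len(sample(1:4, 1))) {
        len <- runif(1, 1, 5) * px_mm # 1 mm up to the image size
        theta <- sample(0:179, 1) * pi / 180
        ctr <- runif(2, 1, npx)
        sign_k <- sample(c(-1, 1), 1)
        img <- img + sign_k * segment_mask(npx, ctr, theta, len, width = 3)
      }
      img <- gaussian_blur(img, blur_sd_um / 10)
      scale_image(img, max_ua, mode)
    } else {
      sf <- runif(1, 0.05, 0.5)       # cycles/mm, below Nyquist at 1 mm pitch
      theta <- sample(0:179, 1) * pi / 180
      phase <- runif(1, 0, 2 * pi)
      if (mode == "static_grating") {
        scale_image(grating_frame(npx, sf, theta, phase), max_ua, mode)
      } else {
        tf <- sample(1:20, 1) / 10    # drift rate, 0.1 .. 2 Hz
        n_frames <- max(1L, as.integer(round(0.3 * frequency_hz)))
        frames <- lapply(seq_len(n_frames) - 1L, function(k) {
          grating_frame(npx, sf, theta, phase - 2 * pi * tf * k / frequency_hz)
        })
        peak <- max(vapply(frames, function(f) max(abs(f)), numeric(1)))
        frames <- lapply(frames, function(f) {
          out <- f * (max_ua / peak)
          attr(out, "mode") <- mode
          attr(out, "pixel_pitch_um") <- 10
          class(out) <- c("stim_image", class(out))
          out
        })
        structure(frames, class = "stim_image_seq", mode = mode,
                  temporal_freq_hz = tf, spatial_freq_cpmm = sf,
                  orientation_deg = theta * 180 / pi,
                  frequency_hz = frequency_hz)
      }
    }
  })
}

scale_image <- function(img, max_ua, mode) {
  peak <- max(abs(img))
  if (peak > 0) img <- img * (max_ua / peak)
  attr(img, "mode") <- mode
  attr(img, "pixel_pitch_um") <- 10
  class(img) <- c("stim_image", class(img))
  img
}

disc_mask <- function(npx, ctr, radius) {
  cols <- matrix(seq_len(npx), npx, npx, byrow = TRUE)
  rows <- matrix(seq_len(npx), npx, npx)
  ((cols - ctr[1])^2 + (rows - ctr[2])^2 <= radius^2) * 1
}

segment_mask <- function(npx, ctr, theta, len, width) {
  cols <- matrix(seq_len(npx), npx, npx, byrow = TRUE) - ctr[1]
  rows <- matrix(seq_len(npx), npx, npx) - ctr[2]
  u <- cols * cos(theta) + rows * sin(theta)   # along the line
  v <- -cols * sin(theta) + rows * cos(theta)  # across the line
  (abs(u) <= len / 2 & abs(v) <= width / 2) * 1
}

grating_frame <- function(npx, sf_cpmm, theta, phase) {
  px_mm <- 100
  cols <- matrix(seq_len(npx) - 0.5, npx, npx, byrow = TRUE) / px_mm
  rows <- matrix(seq_len(npx) - 0.5, npx, npx) / px_mm
  sin(2 * pi * sf_cpmm * (cols * cos(theta) + rows * sin(theta)) + phase)
}

# Separable Gaussian blur via banded kernel matrices (rows renormalized at
# the image border).
gaussian_blur <- function(img, sd_px) {
  if (sd_px <= 0) return(img)
  n <- nrow(img)
  idx <- seq_len(n)
  K <- outer(idx, idx, function(i, j) dnorm(j - i, sd = sd_px))
  K[abs(outer(idx, idx, `-`)) > ceiling(4 * sd_px)] <- 0
  K <- K / rowSums(K)
  K %*% img %*% t(K)
}

#' Sample the image pixels at the electrode centres
#'
#' Superimposes the electrode array on a stimulation image (array centroid
#' aligned with the image centre) and reads the pixel value at the centre of
#' each electrode by nearest-pixel lookup.  Pixel convention: origin at the
#' image's top-left, row-major; x in mm maps to columns, +y in mm maps
#' upwards (decreasing row); the array centroid sits at (row, col) =
#' (249.5, 249.5) in 0-based pixel coordinates.
#'
#' @param image A `stim_image`.
#' @param array An `electrode_array` whose footprint fits inside the image.
#' @return Numeric vector of amplitudes (uA), one per electrode.
#' @export
image_to_pulse_amplitudes <- function(image, array) {
  stopifnot(inherits(image, "stim_image"), inherits(array, "electrode_array"))
  px_mm <- 1000 / attr(image, "pixel_pitch_um")
  npx <- nrow(image)
  ctr <- c(mean(array$x_mm), mean(array$y_mm))
  col0 <- (npx - 1) / 2 + (array$x_mm - ctr[1]) * px_mm
  row0 <- (npx - 1) / 2 - (array$y_mm - ctr[2]) * px_mm
  ci <- as.integer(round(col0)) + 1L
  ri <- as.integer(round(row0)) + 1L
  bad <- which(ci < 1 | ci > npx | ri < 1 | ri > npx)
  if (length(bad) > 0) {
    abort(sprintf("electrode(s) outside image bounds: %s",
                  paste(array$electrode[bad], collapse = ", ")))
  }
  image[cbind(ri, ci)]
}

#' Generate a structured-stimulus pulse train
#'
#' Draws a sequence of structured images, converts each to per-electrode
#' pulse amplitudes, and holds static images for `image_ms` (moving gratings
#' contribute one frame per pulse over 300 ms).  Used to test how a model
#' fitted on white noise generalizes to correlated, non-Gaussian stimuli.
#'
#' @param n_images Number of images in the session.
#' @param array An `electrode_array`.
#' @param frequency_hz Pulse rate, Hz.
#' @param image_ms Hold time for static images, ms.
#' @param modes Modes to sample from (uniformly).
#' @param seed Integer seed.
#' @return A `stim_train` tibble.
#' @export
sample_structured_train <- function(n_images, array, frequency_hz = 30,
                                    image_ms = 180,
                                    modes = c("spots", "lines",
                                              "static_grating",
                                              "moving_grating"),
                                    seed = 1) {
  n_images <- check_count(n_images, "n_images")
  hold <- max(1L, as.integer(round(image_ms * frequency_hz / 1000)))
  picks <- with_seed(derive_seed(seed, "structured_modes"),
                     sample(modes, n_images, replace = TRUE))
  blocks <- lapply(seq_len(n_images), function(i) {
    img <- render_structured_image(picks[i], seed = derive_seed(seed, i),
                                   frequency_hz = frequency_hz)
    if (inherits(img, "stim_image_seq")) {
      t(vapply(img, image_to_pulse_amplitudes, numeric(nrow(array)),
               array = array))
    } else {
      matrix(image_to_pulse_amplitudes(img, array), hold, nrow(array),
             byrow = TRUE)
    }
  })
  new_stim_train(do.call(rbind, blocks), frequency_hz = frequency_hz,
                 seed = seed)
}
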