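#' Generate a smooth random residual distortion field
#'
#' Simulates the nonlinear residual that remains after rigid scaling of an
#' expanded sample: per-component low-pass-filtered white noise, zero-mean,
#' rescaled so that the RMS magnitude of the *pairwise differential*
#' displacement between points separated by the calibration length matches
#' the requested amplitude (in pre-expansion micrometres). Calibrating on
#' differential rather than absolute displacement matches what the
#' measurement-error statistic sees: constant offsets are removed by rigid
#' alignment and invisible to it.
#'
#' @param shape Grid shape `(ny, nx)` in pixels.
#' @param rms_amplitude_um Target differential RMS (pre-expansion um) at the
#'   calibration length; 0 gives an identically zero field.
#' @param correlation_length_px Smoothing sigma of the low-pass filter
#'   (>= 3 px); sets the spatial scale of the distortion.
#' @param seed Integer RNG seed; same seed and parameters give a
#'   bit-identical field.
#' @param voxel_size_nm Grid pixel size (nm, expanded scale).
#' @param expansion_factor Linear expansion factor.
#' @param calibration_length_um Pair separation (pre-expansion um) at which
#'   the amplitude is calibrated.
#' @param n_calibration_pairs Number of random pairs used for calibration.
#' @param mask Optional logical matrix (same shape): calibration pairs are
#'   drawn with both endpoints inside the mask, so the amplitude refers to
#'   the structure the distortion statistic will sample; default is the
#'   full grid.
#' @return A [displacement_field()] in grid pixels.
#' @export
make_residual_field <- function(shape, rms_amplitude_um, correlation_length_px,
                                seed = NULL, voxel_size_nm = 300,
                                expansion_factor = 4,
                                calibration_length_um = 20,
                                n_calibration_pairs = 50000, mask = NULL) {
  if (rms_amplitude_um < 0)
    abort("`rms_amplitude_um` must be >= 0.", class = "exmqc_validation_error")
  if (correlation_length_px < 3)
    abort("`correlation_length_px` must be >= 3.", class = "exmqc_validation_error")
  shape <- as.integer(shape)
  meta <- list(rms_amplitude_um = rms_amplitude_um,
               correlation_length_px = correlation_length_px,
               calibration_length_um = calibration_length_um, seed = seed)
  if (rms_amplitude_um == 0) {
    return(displacement_field(array(0, c(shape, 2)), voxel_size_nm,
                              expansion_factor, metadata = meta))
  }
  um_per_px <- mean(rep_len(voxel_size_nm, 2)) / 1000 / expansion_factor
  L_px <- calibration_length_um / um_per_px
  diag_px <- sqrt(sum((shape - 1)^2))
  if (L_px >= diag_px)
    abort("Calibration length exceeds the grid extent.",
          class = "exmqc_validation_error")
  with_seed(seed, {
    # generate on a padded grid and crop so the smoothed field is
    # statistically stationary (no edge effects from the filter support)
    pad <- ceiling(3 * correlation_length_px)
    pshape <- shape + 2L * pad
    f <- array(0, c(shape, 2))
    for (k in 1:2) {
      comp <- gaussian_blur(matrix(rnorm(prod(pshape)), pshape[1], pshape[2]),
                            correlation_length_px)
      comp <- comp[(pad + 1):(pad + shape[1]), (pad + 1):(pad + shape[2])]
      f[, , k] <- comp - mean(comp)
    }
    # calibration: RMS |d(p) - d(q)| over random pairs at separation L_px,
    # both endpoints inside the mask (full grid when no mask is given)
    if (is.null(mask)) {
      p <- cbind(runif(n_calibration_pairs, 1, shape[1]),
                 runif(n_calibration_pairs, 1, shape[2]))
    } else {
      midx <- which(mask)
      pi1 <- sample(midx, n_calibration_pairs, replace = TRUE)
      p <- cbind((pi1 - 1) %% shape[1] + 1, (pi1 - 1) %/% shape[1] + 1)
    }
    th <- runif(n_calibration_pairs, 0, 2 * pi)
    q <- p + L_px * cbind(sin(th), cos(th))
    ok <- q[, 1] >= 1 & q[, 1] <= shape[1] & q[, 2] >= 1 & q[, 2] <= shape[2]
    if (!is.null(mask))
      ok <- ok & mask[cbind(pmin(pmax(round(q[, 1]), 1), shape[1]),
                            pmin(pmax(round(q[, 2]), 1), shape[2]))]
    if (sum(ok) < 100)
      abort("Too few in-bounds calibration pairs; reduce calibration length.",
            class = "exmqc_validation_error")
    p <- p[ok, , drop = FALSE]; q <- q[ok, , drop = FALSE]
    dp_y <- interp_bilinear(f[, , 1], p[, 1], p[, 2]) -
      interp_bilinear(f[, , 1], q[, 1], q[, 2])
    dp_x <- interp_bilinear(f[, , 2], p[, 1], p[, 2]) -
      interp_bilinear(f[, , 2], q[, 1], q[, 2])
    rms_px <- sqrt(mean(dp_y^2 + dp_x^2))
    f <- f * (rms_amplitude_um / (rms_px * um_per_px))
  })
  displacement_field(f, voxel_size_nm, expansion_factor, metadata = meta)
}
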