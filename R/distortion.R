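#' Preprocess an aligned pre-/post-expansion image pair
#'
#' Matches resolution and appearance of the rigidly aligned pre-expansion
#' image and the post-expansion image before nonrigid registration: each
#' image is smoothed with its own 2D Gaussian (`sigma_pre`, `sigma_post`
#' px), then background-subtracted using a strong Gaussian blur
#' (`sigma_bg`) of itself, and negative values are clipped to zero.
#'
#' @param pre_aligned Pre-expansion [image_volume()] resampled onto the
#'   post grid (see [apply_similarity()]); 2D.
#' @param post Post-expansion [image_volume()]; 2D, same grid.
#' @param sigma_pre,sigma_post Smoothing sigma (px) for the pre and post
#'   image. The defaults (1 and 6) reflect that the resampled pre image is
#'   already magnified and therefore smooth; swap them via arguments if
#'   desired.
#' @param sigma_bg Background-estimation blur sigma (px).
#' @return List with preprocessed `pre` and `post` [image_volume()]s.
#' @export
preprocess_pair <- function(pre_aligned, post, sigma_pre = 1, sigma_post = 6,
                            sigma_bg = 80) {
  stopifnot(inherits(pre_aligned, "image_volume"), inherits(post, "image_volume"))
  if (any(c(sigma_pre, sigma_post, sigma_bg) <= 0))
    abort("All sigmas must be > 0.", class = "exmqc_validation_error")
  if (!all(dim(pre_aligned$data) == dim(post$data)))
    abort("Images must share a grid.", class = "exmqc_validation_error")
  pp <- function(vol, sigma) {
    sm <- gaussian_blur(vol$data, sigma)
    out <- pmax(sm - gaussian_blur(sm, sigma_bg), 0)
    v <- vol; v$data <- out; v
  }
  list(pre = pp(pre_aligned, sigma_pre), post = pp(post, sigma_post))
}

#' Build a signal-containing foreground mask
#'
#' Thresholds the preprocessed pre and/or post image, combines the binary
#' masks (logical OR by default) and closes small spurious holes with a
#' morphological closing.
#'
#' @param pre,post Preprocessed [image_volume()]s (see [preprocess_pair()]).
#' @param method `"otsu"` (deterministic default) or `"manual"` with an
#'   absolute `threshold`.
#' @param threshold Absolute intensity threshold when `method = "manual"`.
#' @param closing_radius Radius (px) of the disc structuring element; 0
#'   skips closing.
#' @param combine `"or"` (default), `"pre"` or `"post"`.
#' @return A `foreground_mask`: list with logical `mask` and `provenance`.
#' @export
foreground_mask <- function(pre, post, method = c("otsu", "manual"),
                            threshold = NULL, closing_radius = 2,
                            combine = c("or", "pre", "post")) {
  method <- match.arg(method)
  combine <- match.arg(combine)
  one_mask <- function(vol) {
    x <- vol$data
    mx <- max(x)
    if (mx <= 0) return(matrix(FALSE, nrow(x), ncol(x)))
    if (method == "otsu") {
      th <- EBImage::otsu(x / mx, range = c(0, 1))
      x / mx > th
    } else {
      if (is.null(threshold))
        abort("`threshold` required for manual thresholding.",
              class = "exmqc_validation_error")
      x > threshold
    }
  }
  m <- switch(combine,
              or = one_mask(pre) | one_mask(post),
              pre = one_mask(pre),
              post = one_mask(post))
  if (closing_radius > 0) {
    brush <- EBImage::makeBrush(2 * closing_radius + 1, shape = "disc")
    m <- EBImage::closing(m * 1, brush) > 0.5
  }
  if (!any(m))
    abort("Foreground mask is empty; lower the threshold.",
          class = "exmqc_empty_foreground_error")
  structure(list(mask = m,
                 provenance = list(method = method, threshold = threshold,
                                   closing_radius = closing_radius,
                                   combine = combine)),
            class = "foreground_mask")
}

# image pyramid level: block-mean downsample by 2^k
downsample2 <- function(img) {
  ny <- floor(nrow(img) / 2) * 2; nx <- floor(ncol(img) / 2) * 2
  img <- img[seq_len(ny), seq_len(nx)]
  (img[seq(1, ny, 2), seq(1, nx, 2)] + img[seq(2, ny, 2), seq(1, nx, 2)] +
     img[seq(1, ny, 2), seq(2, nx, 2)] + img[seq(2, ny, 2), seq(2, nx, 2)]) / 4
}

upsample_field2 <- function(u, shape) {
  # bilinear upsample of one field component to `shape`, values doubled
  ny <- nrow(u); nx <- ncol(u)
  yy <- seq(1, ny, length.out = shape[1])
  xx <- seq(1, nx, length.out = shape[2])
  Y <- matrix(yy, shape[1], shape[2])
  X <- matrix(xx, shape[1], shape[2], byrow = TRUE)
  2 * matrix(interp_bilinear(u, as.vector(Y), as.vector(X)), shape[1], shape[2])
}

#' Estimate the nonrigid distortion field between aligned images
#'
#' Demons-type intensity-based nonrigid registration: multi-resolution
#' pyramid; at each level an iterative update driven by intensity
#' differences and (symmetric) image gradients, with Gaussian regularization
#' of the accumulated field after every iteration. The returned
#' [displacement_field()] gives, at every pixel of the post grid, the
#' residual distortion vector (px) of the pre-expansion structure relative
#' to ideal similarity expansion; physical conversion metadata is inherited
#' from `post`.
#'
#' @param pre,post Preprocessed, rigidly aligned 2D [image_volume()]s
#'   (`pre` is the moving image, `post` the fixed one).
#' @param n_levels Pyramid levels (coarsest is `2^(n_levels-1)`-fold
#'   downsampled).
#' @param n_iterations Iterations per level (scalar or per-level vector,
#'   coarse to fine).
#' @param smooth_sigma Field-regularization sigma (px) per iteration.
#' @param step_cap Maximum per-iteration update magnitude (px).
#' @param expansion_factor Override for the expansion factor used for
#'   physical conversion (defaults to `post$expansion_factor`).
#' @return A [displacement_field()]; `metadata$converged` is `FALSE` (with
#'   a warning) when the mean absolute intensity difference did not
#'   decrease over the final level.
#' @export
estimate_displacement_field <- function(pre, post, n_levels = 3,
                                        n_iterations = 100, smooth_sigma = 3,
                                        step_cap = 2,
                                        expansion_factor = NULL) {
  stopifnot(inherits(pre, "image_volume"), inherits(post, "image_volume"))
  if (!all(dim(pre$data) == dim(post$data)))
    abort("Images must share a grid.", class = "exmqc_validation_error")
  exf <- expansion_factor %||% post$expansion_factor
  if (is.null(exf) || is.na(exf))
    abort("An expansion factor is required (set it on `post` or pass it).",
          class = "exmqc_validation_error")
  n_iterations <- rep_len(n_iterations, n_levels)
  # demons updates are driven by intensity differences, so bring both
  # images to a common brightness scale first
  norm1 <- function(x) if (max(x) > 0) x / max(x) else x
  moving0 <- norm1(pre$data)
  fixed0 <- norm1(post$data)
  pyr_m <- list(moving0); pyr_f <- list(fixed0)
  for (l in seq_len(n_levels - 1)) {
    pyr_m[[l + 1]] <- downsample2(pyr_m[[l]])
    pyr_f[[l + 1]] <- downsample2(pyr_f[[l]])
  }
  uy <- matrix(0, nrow(pyr_f[[n_levels]]), ncol(pyr_f[[n_levels]]))
  ux <- uy
  mad_final <- NULL
  for (l in rev(seq_len(n_levels))) {
    fx <- pyr_f[[l]]; mv <- pyr_m[[l]]
    if (!all(dim(uy) == dim(fx))) {
      uy <- upsample_field2(uy, dim(fx))
      ux <- upsample_field2(ux, dim(fx))
    }
    res <- demons_level(fx, mv, uy, ux, as.integer(n_iterations[n_levels - l + 1]),
                        smooth_sigma, step_cap)
    uy <- res$uy; ux <- res$ux
    mad_final <- res$mad_history
  }
  converged <- length(mad_final) < 2 ||
    tail(mad_final, 1) <= head(mad_final, 1)
  if (!converged)
    warn("Demons registration did not reduce the intensity mismatch; returning best field.")
  # distortion of post-expansion structure relative to ideal similarity:
  # the warp u maps aligned-pre onto post, so the planted distortion is -u.
  f <- array(0, c(dim(fixed0), 2))
  f[, , 1] <- -uy; f[, , 2] <- -ux
  displacement_field(f, voxel_size_nm = tail(post$voxel_size_nm, 2),
                     expansion_factor = exf,
                     metadata = list(n_levels = n_levels,
                                     n_iterations = n_iterations,
                                     smooth_sigma = smooth_sigma,
                                     step_cap = step_cap,
                                     converged = converged,
                                     mad_history = mad_final))
}
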