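# Synthetic pre-/post-expansion image pairs with planted ground truth.
#
# Filamentous (microtubule-like) structures are rendered as cubic splines
# through random control points with a Gaussian cross-section; the post
# image renders the same filaments mapped through a planted similarity
# transform (scale = expansion factor) composed with an optional smooth
# residual distortion field. Landmarks are exact corresponding filament
# control points. Photon statistics follow photon-counting detection:
# Poisson noise on signal + background, optional Gaussian read noise.

# Densely sample cubic splines through `n_ctrl` random control points.
# Returns list(points = dense (y, x) matrix 1-based-free (0-based px),
#              ctrl = control-point matrix).
render_filament_points <- function(shape, n_ctrl, margin, samples_per_px = 2) {
  ctrl <- cbind(runif(n_ctrl, margin, shape[1] - 1 - margin),
                runif(n_ctrl, margin, shape[2] - 1 - margin))
  tt <- seq_len(n_ctrl)
  arc <- sum(sqrt(rowSums(diff(ctrl)^2)))
  n_dense <- max(50L, ceiling(arc * samples_per_px))
  td <- seq(1, n_ctrl, length.out = n_dense)
  dense <- cbind(stats::spline(tt, ctrl[, 1], xout = td)$y,
                 stats::spline(tt, ctrl[, 2], xout = td)$y)
  list(points = dense, ctrl = ctrl)
}

# Accumulate unit mass at fractional 0-based (y, x) positions onto a grid
# with bilinear splatting.
splat_points <- function(points, shape) {
  img <- matrix(0, shape[1], shape[2])
  y <- points[, 1] + 1; x <- points[, 2] + 1
  ok <- y >= 1 & y <= shape[1] & x >= 1 & x <= shape[2]
  y <- y[ok]; x <- x[ok]
  y0 <- floor(y); x0 <- floor(x)
  fy <- y - y0; fx <- x - x0
  add <- function(yy, xx, w) {
    keep <- yy >= 1 & yy <= shape[1] & xx >= 1 & xx <= shape[2] & w > 0
    if (!any(keep)) return()
    idx <- (xx[keep] - 1) * shape[1] + yy[keep]
    acc <- rowsum(w[keep], idx)
    img[as.integer(rownames(acc))] <<- img[as.integer(rownames(acc))] + acc[, 1]
  }
  add(y0, x0, (1 - fy) * (1 - fx))
  add(y0, x0 + 1, (1 - fy) * fx)
  add(y0 + 1, x0, fy * (1 - fx))
  add(y0 + 1, x0 + 1, fy * fx)
  img
}

render_scene_image <- function(points, shape, psf_sigma_px, peak_photons,
                               background, poisson, read_noise_sd) {
  img <- splat_points(points, shape)
  img <- gaussian_blur(img, psf_sigma_px)
  if (max(img) > 0) img <- img / max(img) * peak_photons
  img <- img + background
  if (poisson) img <- matrix(rpois(length(img), img), nrow(img), ncol(img))
  if (read_noise_sd > 0)
    img <- pmax(img + rnorm(length(img), 0, read_noise_sd), 0)
  img
}

#' Simulate a pre-/post-expansion image pair with known ground truth
#'
#' Generates matched pre- and post-expansion images of the same filamentous
#' structures, related by a planted similarity transform (isotropic scale =
#' expansion factor, rotation, translation) composed with an optional
#' smooth residual distortion field of controlled differential RMS
#' amplitude, plus exact corresponding landmarks. Used to validate
#' expansion-factor estimation and the distortion pipeline against planted
#' truth.
#'
#' @param shape_pre Pre-image shape `(ny, nx)` px.
#' @param voxel_size_pre_nm,voxel_size_post_nm Pixel sizes (nm). The pre
#'   image is at native scale, the post image at expanded scale.
#' @param scale Planted expansion factor (isotropic scale, in `[1, 6]`
#'   typically ~4).
#' @param rotation_deg Planted rotation (degrees, counter-clockwise in the
#'   `(y, x)` plane).
#' @param translation_px Planted translation in post-grid pixels `(dy, dx)`.
#' @param residual_rms_um Differential RMS amplitude of the planted residual
#'   field at `calibration_length_um`, in pre-expansion um (0 = perfectly
#'   similar expansion).
#' @param residual_correlation_px Correlation length of the residual field
#'   on the post grid (px).
#' @param calibration_length_um Length (pre-expansion um) at which the
#'   residual amplitude is defined.
#' @param n_filaments,n_ctrl Number of filaments and of spline control
#'   points per filament.
#' @param n_landmarks Number of landmark pairs (exact filament control
#'   points; at most `n_filaments * n_ctrl`).
#' @param psf_sigma_pre_px,psf_sigma_post_px Gaussian PSF sigma applied to
#'   each rendered image (px of the respective grid).
#' @param peak_photons,background Peak signal and flat background (counts).
#' @param poisson Apply Poisson noise to signal + background.
#' @param read_noise_sd Additive Gaussian read noise SD (counts), default off.
#' @param seed Integer RNG seed (same seed: bit-identical output).
#' @return A list with `pre`, `post` ([image_volume()]), `landmarks`
#'   (tibble, 0-based px) and `scene` (ground truth: dense filament points
#'   in both frames, planted transform, residual field, parameters, seed).
#' @export
make_expansion_pair <- function(shape_pre = c(128, 128),
                                voxel_size_pre_nm = 300,
                                voxel_size_post_nm = 300,
                                scale = 4, rotation_deg = 3,
                                translation_px = c(5, -3),
                                residual_rms_um = 0,
                                residual_correlation_px = 40,
                                calibration_length_um = 20,
                                n_filaments = 12, n_ctrl = 5,
                                n_landmarks = 20,
                                psf_sigma_pre_px = 1.2,
                                psf_sigma_post_px = 2.5,
                                peak_photons = 150, background = 5,
                                poisson = TRUE, read_noise_sd = 0,
                                seed = NULL) {
  if (scale <= 0) abort("`scale` must be > 0.", class = "exmqc_validation_error")
  if (residual_rms_um < 0)
    abort("`residual_rms_um` must be >= 0.", class = "exmqc_validation_error")
  shape_pre <- as.integer(shape_pre)
  shape_post <- as.integer(ceiling(shape_pre * scale * voxel_size_pre_nm /
                                     voxel_size_post_nm))
  theta <- rotation_deg * pi / 180
  R <- matrix(c(cos(theta), -sin(theta), sin(theta), cos(theta)), 2, 2,
              byrow = TRUE)  # acts on (y, x)
  t_nm <- translation_px * rep_len(voxel_size_post_nm, 2)

  map_pre_to_post_px <- function(pts_pre_px) {
    phys <- sweep(pts_pre_px, 2, rep_len(voxel_size_pre_nm, 2), `*`)
    post_nm <- scale * phys %*% t(R) + matrix(t_nm, nrow(pts_pre_px), 2, byrow = TRUE)
    sweep(post_nm, 2, rep_len(voxel_size_post_nm, 2), `/`)
  }

  # stage 1 (seed): filament geometry
  geom <- with_seed(seed, {
    margin <- ceiling(0.08 * min(shape_pre))
    fils <- lapply(seq_len(n_filaments), function(i)
      render_filament_points(shape_pre, n_ctrl, margin))
    list(dense_pre = do.call(rbind, lapply(fils, `[[`, "points")),
         ctrl_pre = do.call(rbind, lapply(fils, `[[`, "ctrl")))
  })
  dense_post0 <- map_pre_to_post_px(geom$dense_pre)

  # stage 2 (seed + 1): residual field, calibrated over the structure
  # support so the planted amplitude is what the distortion statistic sees
  support <- splat_points(dense_post0, shape_post)
  support <- gaussian_blur(support, psf_sigma_post_px) > 1e-4
  field <- make_residual_field(
    shape_post, residual_rms_um, residual_correlation_px,
    seed = if (is.null(seed)) NULL else seed + 1L,
    voxel_size_nm = voxel_size_post_nm, expansion_factor = scale,
    calibration_length_um = calibration_length_um, mask = support)

  # stage 3 (seed + 2): rendering noise and landmark selection
  res <- with_seed(if (is.null(seed)) NULL else seed + 2L, {
    dense_pre <- geom$dense_pre
    ctrl_pre <- geom$ctrl_pre
    dense_post <- dense_post0
    ctrl_post <- map_pre_to_post_px(ctrl_pre)
    if (residual_rms_um > 0) {
      dense_post <- dense_post + sample_field(field, dense_post[, 1], dense_post[, 2])
      ctrl_post <- ctrl_post + sample_field(field, ctrl_post[, 1], ctrl_post[, 2])
    }
    pre_img <- render_scene_image(dense_pre, shape_pre, psf_sigma_pre_px,
                                  peak_photons, background, poisson, read_noise_sd)
    post_img <- render_scene_image(dense_post, shape_post, psf_sigma_post_px,
                                   peak_photons, background, poisson, read_noise_sd)
    li <- sample(nrow(ctrl_pre), min(n_landmarks, nrow(ctrl_pre)))
    list(pre_img = pre_img, post_img = post_img,
         dense_pre = dense_pre, dense_post = dense_post,
         ctrl_pre = ctrl_pre, ctrl_post = ctrl_post, li = li)
  })

  landmarks <- tibble::tibble(
    pre_y = res$ctrl_pre[res$li, 1], pre_x = res$ctrl_pre[res$li, 2],
    post_y = res$ctrl_post[res$li, 1], post_x = res$ctrl_post[res$li, 2])

  pre <- image_volume(res$pre_img, voxel_size_nm = voxel_size_pre_nm,
                      channel = "filaments")
  post <- image_volume(res$post_img, voxel_size_nm = voxel_size_post_nm,
                       expansion_factor = scale, channel = "filaments")
  scene <- list(
    truth_pre_px = res$dense_pre, truth_post_px = res$dense_post,
    control_pre_px = res$ctrl_pre, control_post_px = res$ctrl_post,
    transform = list(scale = scale, rotation = R, translation_nm = t_nm,
                     rotation_deg = rotation_deg),
    residual_field = field,
    params = list(shape_pre = shape_pre, shape_post = shape_post,
                  voxel_size_pre_nm = voxel_size_pre_nm,
                  voxel_size_post_nm = voxel_size_post_nm,
                  residual_rms_um = residual_rms_um,
                  residual_correlation_px = residual_correlation_px,
                  calibration_length_um = calibration_length_um,
                  n_filaments = n_filaments, n_ctrl = n_ctrl,
                  psf_sigma_pre_px = psf_sigma_pre_px,
                  psf_sigma_post_px = psf_sigma_post_px,
                  peak_photons = peak_photons, background = background,
                  poisson = poisson, read_noise_sd = read_noise_sd),
    seed = seed)
  list(pre = pre, post = post, landmarks = landmarks, scene = scene)
}
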