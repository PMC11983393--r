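#' Fit a similarity transform to paired landmarks
#'
#' Closed-form least-squares estimate (Procrustes/Umeyama) of the similarity
#' transform — isotropic scale `s`, proper rotation `R`, translation `t` —
#' minimizing `sum ||post_i - (s * R %*% pre_i + t)||^2`. Reflections are
#' excluded. When the transform maps a pre-expansion onto a post-expansion
#' image, the fitted scale *is* the expansion factor.
#'
#' Landmark coordinates are converted to physical units (nm) using the
#' per-image voxel sizes before fitting, so differing or anisotropic pixel
#' sizes cannot bias the scale.
#'
#' @param landmarks Landmark tibble (see [read_landmarks()]); 0-based pixel
#'   coordinates, 2D or 3D.
#' @param voxel_size_pre_nm,voxel_size_post_nm Per-axis voxel size (nm) of
#'   the pre and post image; scalars are recycled. Defaults of 1 fit in raw
#'   pixel units.
#' @return A `similarity_transform` object with elements `scale`,
#'   `rotation` (orthonormal, det +1), `translation_nm`, `translation_px`
#'   (post pixels), `rmse_nm`, `rmse_px`, `n` and `dim`. Supports [tidy()]
#'   and [glance()].
#' @export
#' @examples
#' lm <- tibble::tibble(pre_y = c(0, 0, 10, 7), pre_x = c(0, 10, 0, 3))
#' lm$post_y <- 4 * lm$pre_y + 5
#' lm$post_x <- 4 * lm$pre_x - 2
#' fit <- estimate_similarity(lm)
#' expansion_factor(fit)
estimate_similarity <- function(landmarks, voxel_size_pre_nm = 1,
                                voxel_size_post_nm = 1) {
  m <- landmark_matrices(landmarks)
  d <- ncol(m$pre)
  vox_pre <- rep_len(voxel_size_pre_nm, d)
  vox_post <- rep_len(voxel_size_post_nm, d)
  X <- sweep(m$pre, 2, vox_pre, `*`)    # physical nm
  Y <- sweep(m$post, 2, vox_post, `*`)
  n <- nrow(X)
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  var_x <- sum(Xc^2) / n
  sv_x <- svd(Xc, nu = 0, nv = 0)$d
  if (var_x == 0 || sv_x[2] <= 1e-10 * sv_x[1])
    abort("Degenerate landmark configuration (coincident or collinear).",
          class = "exmqc_degeneracy_error")
  S <- crossprod(Yc, Xc) / n            # maps pre -> post
  sv <- svd(S)
  sgn <- diag(d)
  if (det(sv$u) * det(sv$v) < 0) sgn[d, d] <- -1
  R <- sv$u %*% sgn %*% t(sv$v)
  s <- sum(diag(diag(sv$d, d, d) %*% sgn)) / var_x
  t_nm <- as.numeric(my - s * R %*% mx)
  resid <- Y - (s * X %*% t(R) + matrix(t_nm, n, d, byrow = TRUE))
  rmse_nm <- sqrt(mean(rowSums(resid^2)))
  structure(
    list(scale = s, rotation = R, translation_nm = t_nm,
         translation_px = t_nm / vox_post,
         rmse_nm = rmse_nm, rmse_px = rmse_nm / mean(vox_post),
         n = n, dim = d,
         voxel_size_pre_nm = vox_pre, voxel_size_post_nm = vox_post),
    class = "similarity_transform"
  )
}

#' Construct a similarity transform from known parameters
#'
#' Builds the transform object directly (rather than fitting it from
#' landmarks), e.g. to apply a planted or previously saved transform.
#'
#' @param scale Isotropic scale (> 0); the expansion factor for a pre-to-post
#'   mapping.
#' @param rotation Orthonormal rotation matrix with determinant +1 (defaults
#'   to the identity); dimension sets the transform dimensionality.
#' @param translation_px Translation in target-grid pixels.
#' @param voxel_size_pre_nm,voxel_size_post_nm Voxel sizes used to interpret
#'   coordinates physically.
#' @return A `similarity_transform`.
#' @export
similarity_transform <- function(scale, rotation = diag(2),
                                 translation_px = rep(0, nrow(rotation)),
                                 voxel_size_pre_nm = 1,
                                 voxel_size_post_nm = 1) {
  d <- nrow(rotation)
  if (scale <= 0) abort("`scale` must be > 0.", class = "exmqc_validation_error")
  if (max(abs(crossprod(rotation) - diag(d))) > 1e-8 || det(rotation) < 0)
    abort("`rotation` must be orthonormal with determinant +1.",
          class = "exmqc_validation_error")
  vox_post <- rep_len(voxel_size_post_nm, d)
  structure(
    list(scale = scale, rotation = rotation,
         translation_nm = translation_px * vox_post,
         translation_px = translation_px,
         rmse_nm = NA_real_, rmse_px = NA_real_, n = 0L, dim = d,
         voxel_size_pre_nm = rep_len(voxel_size_pre_nm, d),
         voxel_size_post_nm = vox_post),
    class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  cat("<similarity_transform> ", x$dim, "D, n = ", x$n, " landmarks\n", sep = "")
  cat("  scale (expansion factor): ", signif(x$scale, 6), "\n", sep = "")
  cat("  rotation angle (deg): ", signif(rotation_angle_deg(x$rotation), 6), "\n", sep = "")
  cat("  translation (px, post grid): ",
      paste(signif(x$translation_px, 6), collapse = ", "), "\n", sep = "")
  cat("  landmark RMSE (px): ", signif(x$rmse_px, 4), "\n", sep = "")
  invisible(x)
}

rotation_angle_deg <- function(R) {
  d <- nrow(R)
  tr <- sum(diag(R))
  cosang <- if (d == 2) tr / 2 else (tr - 1) / 2
  acos(min(1, max(-1, cosang))) * 180 / pi
}

#' Extract the expansion factor from a fitted transform
#'
#' The expansion factor is the isotropic scale of the similarity transform
#' fitted from pre- to post-expansion landmarks.
#'
#' @param transform A `similarity_transform` from [estimate_similarity()].
#' @return Numeric scalar scale.
#' @export
expansion_factor <- function(transform) {
  stopifnot(inherits(transform, "similarity_transform"))
  transform$scale
}

#' Summarize expansion factors across specimens
#'
#' @param factors Numeric vector of per-specimen expansion factors.
#' @return A tibble with `n`, `mean_exf`, `sd_exf`.
#' @export
summarize_expansion_factors <- function(factors) {
  tibble::tibble(n = length(factors), mean_exf = mean(factors),
                 sd_exf = stats::sd(factors))
}

#' Resample a pre-expansion image onto the post-expansion grid
#'
#' Applies a fitted similarity transform to the pre-expansion image,
#' resampling it by linear interpolation onto the target (post) grid.
#' Voxels mapping outside the pre-image support are set to 0. For 3D
#' volumes the output is cropped along z to the axial extent that overlaps
#' the pre-image support.
#'
#' @param pre A pre-expansion [image_volume()].
#' @param transform `similarity_transform` mapping pre to post physical
#'   coordinates.
#' @param target Target grid: a post [image_volume()] or a list with
#'   `shape` and `voxel_size_nm`.
#' @return An [image_volume()] on the target grid (z-cropped if 3D), with
#'   attribute `z_range` giving the retained slice indices.
#' @export
apply_similarity <- function(pre, transform, target) {
  stopifnot(inherits(pre, "image_volume"),
            inherits(transform, "similarity_transform"))
  if (inherits(target, "image_volume")) {
    shape <- dim(target$data); vox_t <- target$voxel_size_nm
    exf_t <- target$expansion_factor
  } else {
    shape <- target$shape; vox_t <- rep_len(target$voxel_size_nm, length(shape))
    exf_t <- NA_real_
  }
  d <- length(shape)
  if (d != transform$dim || length(dim(pre$data)) != d)
    abort("Dimensionality of image, transform and target must agree.",
          class = "exmqc_validation_error")
  vox_pre <- pre$voxel_size_nm
  s <- transform$scale; R <- transform$rotation; t_nm <- transform$translation_nm
  # inverse map: pre = R^T (p - t) / s; with row-vector points this is
  # (p - t) %*% R / s

  # 0-based target indices -> physical nm -> pre physical -> pre 1-based px
  grids <- lapply(seq_len(d), function(i) (seq_len(shape[i]) - 1) * vox_t[i])
  if (d == 2) {
    Yg <- matrix(grids[[1]], shape[1], shape[2])
    Xg <- matrix(grids[[2]], shape[1], shape[2], byrow = TRUE)
    P <- cbind(as.vector(Yg) - t_nm[1], as.vector(Xg) - t_nm[2]) %*% R / s
    py <- P[, 1] / vox_pre[1] + 1; px <- P[, 2] / vox_pre[2] + 1
    vals <- interp_bilinear(pre$data, py, px, fill = 0)
    out <- matrix(vals, shape[1], shape[2])
    inside <- matrix(py >= 1 & py <= nrow(pre$data) &
                       px >= 1 & px <= ncol(pre$data), shape[1], shape[2])
    if (!any(inside))
      abort("Transform maps the target grid entirely outside the pre image.",
            class = "exmqc_validation_error")
    vol <- image_volume(out, voxel_size_nm = vox_t,
                        expansion_factor = exf_t %||% NA_real_,
                        channel = pre$channel)
    attr(vol, "z_range") <- NULL
    return(vol)
  }
  # 3D
  zg <- grids[[1]]; yg <- grids[[2]]; xg <- grids[[3]]
  ny <- shape[2]; nx <- shape[3]
  Yg <- matrix(yg, ny, nx); Xg <- matrix(xg, ny, nx, byrow = TRUE)
  out <- array(0, shape)
  any_inside <- logical(shape[1])
  dp <- dim(pre$data)
  for (zi in seq_len(shape[1])) {
    P <- cbind(zg[zi] - t_nm[1], as.vector(Yg) - t_nm[2],
               as.vector(Xg) - t_nm[3]) %*% R / s
    pz <- P[, 1] / vox_pre[1] + 1
    py <- P[, 2] / vox_pre[2] + 1
    px <- P[, 3] / vox_pre[3] + 1
    inside <- pz >= 1 & pz <= dp[1] & py >= 1 & py <= dp[2] & px >= 1 & px <= dp[3]
    any_inside[zi] <- any(inside)
    if (any_inside[zi])
      out[zi, , ] <- matrix(interp_trilinear(pre$data, pz, py, px, fill = 0), ny, nx)
  }
  if (!any(any_inside))
    abort("Transform maps the target grid entirely outside the pre image.",
          class = "exmqc_validation_error")
  z_keep <- range(which(any_inside))
  out <- out[z_keep[1]:z_keep[2], , , drop = FALSE]
  vol <- image_volume(out, voxel_size_nm = vox_t,
                      expansion_factor = exf_t %||% NA_real_,
                      channel = pre$channel)
  attr(vol, "z_range") <- z_keep
  vol
}
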