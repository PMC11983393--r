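# High-level pipeline wrappers. Every stage logs its parameter set (and
# seed, when randomness is involved) so analyses leave a provenance trail;
# silence with options(exmqc.verbose = FALSE).

exmqc_log <- function(stage, params) {
  if (!isTRUE(getOption("exmqc.verbose", TRUE))) return(invisible())
  kv <- paste(names(params), vapply(params, function(p)
    paste(format(p, digits = 6), collapse = ","), character(1)),
    sep = "=", collapse = " ")
  message("[exmqc] ", stage, ": ", kv)
  invisible()
}

#' Full distortion analysis of a pre-/post-expansion pair
#'
#' Runs the complete validation chain: similarity fit on landmarks
#' (physical units), resampling of the pre image onto the post grid (3D
#' inputs are maximum-projected after alignment), preprocessing,
#' foreground masking, demons displacement-field estimation, and the
#' measurement-error curve.
#'
#' @param pre,post [image_volume()]s (2D planes or 3D stacks).
#' @param landmarks Landmark tibble (0-based px, see [read_landmarks()]).
#' @param expansion_factor Optional override; defaults to the fitted scale.
#' @param threshold Optional manual foreground threshold (otherwise Otsu).
#' @param closing_radius Morphological closing radius (px).
#' @param sigma_pre,sigma_post,sigma_bg Preprocessing sigmas (px).
#' @param n_levels,n_iterations,smooth_sigma Demons parameters.
#' @param n_pairs,bin_width_um,seed Measurement-error sampling parameters.
#' @return A `distortion_analysis` list: `transform`, `pre_aligned`,
#'   `preprocessed`, `mask`, `field`, `curve`. Supports [tidy()] (the
#'   curve) and [glance()].
#' @export
distortion_pipeline <- function(pre, post, landmarks,
                                expansion_factor = NULL,
                                threshold = NULL, closing_radius = 2,
                                sigma_pre = 1, sigma_post = 6, sigma_bg = 80,
                                n_levels = 3, n_iterations = 100,
                                smooth_sigma = 3,
                                n_pairs = 200000, bin_width_um = 1,
                                seed = NULL) {
  exmqc_log("distortion_pipeline",
            list(n_pairs = n_pairs, bin_width_um = bin_width_um,
                 seed = seed %||% NA, sigma_pre = sigma_pre,
                 sigma_post = sigma_post, sigma_bg = sigma_bg))
  fit <- estimate_similarity(landmarks,
                             voxel_size_pre_nm = pre$voxel_size_nm,
                             voxel_size_post_nm = post$voxel_size_nm)
  exf <- expansion_factor %||% fit$scale
  pre_aligned <- apply_similarity(pre, fit, post)
  post_used <- post
  if (length(dim(post$data)) == 3) {
    pre_aligned <- max_intensity_projection(pre_aligned)
    post_used <- max_intensity_projection(post)
  }
  post_used$expansion_factor <- exf
  pre_aligned$expansion_factor <- exf
  pp <- preprocess_pair(pre_aligned, post_used, sigma_pre = sigma_pre,
                        sigma_post = sigma_post, sigma_bg = sigma_bg)
  mask <- foreground_mask(pp$pre, pp$post,
                          method = if (is.null(threshold)) "otsu" else "manual",
                          threshold = threshold,
                          closing_radius = closing_radius)
  field <- estimate_displacement_field(pp$pre, pp$post, n_levels = n_levels,
                                       n_iterations = n_iterations,
                                       smooth_sigma = smooth_sigma,
                                       expansion_factor = exf)
  curve <- measurement_error_curve(field, mask, n_pairs = n_pairs,
                                   bin_width_um = bin_width_um, seed = seed)
  structure(list(transform = fit, pre_aligned = pre_aligned,
                 preprocessed = pp, mask = mask, field = field, curve = curve),
            class = "distortion_analysis")
}

#' Detect, fit and summarize puncta in a super-resolution image
#'
#' Full FWHM quantification chain with the standard parameterizations:
#' 2D mode (single STED plane, 30 nm pixels): smoothing sigma 3.3 px
#' (~100 nm expanded), brightness cutoff 25% of the smoothed maximum,
#' isolation 30 px (900 nm), fit window 41 px. 3D mode (volumetric z-STED,
#' 100 nm voxels): smoothing 1 voxel, cutoff 25%, isolation 18 voxels
#' (1.8 µm), window 21 voxels. Thresholds may equivalently be given in
#' expanded-sample nm via `*_nm` arguments, converted with the voxel size.
#'
#' @param vol Raw [image_volume()] (2D plane or 3D volume).
#' @param mode `"2d"` or `"3d"`; defaults to the image dimensionality.
#' @param anisotropic Fit per-axis sigmas (5/7 dof) instead of isotropic
#'   (4/5 dof).
#' @param voxel_size_nm,expansion_factor Physical metadata overrides
#'   (default: taken from `vol`).
#' @param sigma_smooth_px,min_rel_brightness,isolation_px,window_px
#'   Detection/fit parameters in pixels.
#' @param sigma_smooth_nm,isolation_nm Alternative physical (expanded nm)
#'   parameterization; overrides the pixel values when given.
#' @param r_max QC limit on the relative fit residual.
#' @return A `puncta_analysis` list: `puncta` tibble (one row per fitted
#'   punctum with QC columns), `summary` ([summarize_puncta()]),
#'   `n_detected`, `n_isolated`, `params`. Supports [tidy()]/[glance()].
#' @export
puncta_pipeline <- function(vol, mode = NULL, anisotropic = FALSE,
                            voxel_size_nm = NULL, expansion_factor = NULL,
                            sigma_smooth_px = NULL,
                            min_rel_brightness = 0.25,
                            isolation_px = NULL, window_px = NULL,
                            sigma_smooth_nm = NULL, isolation_nm = NULL,
                            r_max = 0.5) {
  nd <- length(dim(vol$data))
  mode <- mode %||% if (nd == 3) "3d" else "2d"
  if ((mode == "3d") != (nd == 3))
    abort("`mode` does not match the image dimensionality.",
          class = "exmqc_validation_error")
  voxel_size_nm <- rep_len(voxel_size_nm %||% vol$voxel_size_nm, nd)
  expansion_factor <- expansion_factor %||% vol$expansion_factor
  if (is.null(expansion_factor) || is.na(expansion_factor))
    abort("An expansion factor is required for native-scale FWHM.",
          class = "exmqc_validation_error")
  defaults <- if (mode == "2d")
    list(sigma = 3.3, iso = 30, win = 41) else list(sigma = 1, iso = 18, win = 21)
  vox_iso <- mean(voxel_size_nm[(nd - 1):nd])
  sigma_smooth_px <- sigma_smooth_px %||%
    (if (!is.null(sigma_smooth_nm)) sigma_smooth_nm / vox_iso else defaults$sigma)
  isolation_px <- isolation_px %||%
    (if (!is.null(isolation_nm)) isolation_nm / vox_iso else defaults$iso)
  window_px <- window_px %||% defaults$win
  model <- paste0(if (anisotropic) "aniso" else "iso", if (mode == "2d") "2d" else "3d")
  exmqc_log("puncta_pipeline",
            list(mode = mode, model = model, sigma_smooth_px = sigma_smooth_px,
                 min_rel_brightness = min_rel_brightness,
                 isolation_px = isolation_px, window_px = window_px,
                 voxel_size_nm = voxel_size_nm,
                 expansion_factor = expansion_factor))
  norm <- normalize_image(vol)
  cand <- detect_local_maxima(norm, sigma_smooth = sigma_smooth_px,
                              min_rel_brightness = min_rel_brightness)
  iso <- select_isolated(cand, isolation_px)
  fits <- fit_puncta(norm, iso, window_px = window_px, model = model,
                     sigma_init = max(sigma_smooth_px, 1),
                     voxel_size_nm = voxel_size_nm,
                     expansion_factor = expansion_factor)
  fits <- qc_filter(fits, window_px = window_px, r_max = r_max)
  summary <- if (any(fits$qc_pass %||% FALSE)) summarize_puncta(fits) else NULL
  structure(list(puncta = fits, summary = summary,
                 n_detected = nrow(cand), n_isolated = nrow(iso),
                 params = list(mode = mode, model = model,
                               sigma_smooth_px = sigma_smooth_px,
                               min_rel_brightness = min_rel_brightness,
                               isolation_px = isolation_px,
                               window_px = window_px,
                               voxel_size_nm = voxel_size_nm,
                               expansion_factor = expansion_factor,
                               r_max = r_max)),
            class = "puncta_analysis")
}

#' Detect and cluster puncta in a volume
#'
#' Chains [detect_cluster_puncta()] and [cluster_puncta()].
#'
#' @param vol Raw [image_volume()].
#' @param min_cluster_size Minimum puncta per cluster.
#' @param xi Steepness parameter of the cluster extraction.
#' @return A `cluster_result`.
#' @export
cluster_pipeline <- function(vol, min_cluster_size = 10, xi = 0.05) {
  exmqc_log("cluster_pipeline",
            list(min_cluster_size = min_cluster_size, xi = xi))
  pts <- detect_cluster_puncta(vol)
  cluster_puncta(pts, min_cluster_size = min_cluster_size, xi = xi,
                 voxel_size_nm = vol$voxel_size_nm)
}
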