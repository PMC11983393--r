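#' Tidy a fitted similarity transform
#'
#' @param x A `similarity_transform`.
#' @param ... Unused.
#' @return One row per parameter (`term`, `estimate`).
#' @method tidy similarity_transform
#' @export
tidy.similarity_transform <- function(x, ...) {
  terms <- c("scale", "rotation_deg",
             paste0("translation_px_", c("z", "y", "x")[seq_len(x$dim) + (3 - x$dim)]))
  tibble::tibble(
    term = terms,
    estimate = c(x$scale, rotation_angle_deg(x$rotation), x$translation_px))
}

#' Glance at a fitted similarity transform
#'
#' @param x A `similarity_transform`.
#' @param ... Unused.
#' @return One-row tibble: `scale` (expansion factor), `rotation_deg`,
#'   `rmse_px`, `rmse_nm`, `n_landmarks`, `dim`.
#' @method glance similarity_transform
#' @export
glance.similarity_transform <- function(x, ...) {
  tibble::tibble(scale = x$scale,
                 rotation_deg = rotation_angle_deg(x$rotation),
                 rmse_px = x$rmse_px, rmse_nm = x$rmse_nm,
                 n_landmarks = x$n, dim = x$dim)
}

#' @method tidy cluster_result
#' @export
tidy.cluster_result <- function(x, ...) x$points

#' @method glance cluster_result
#' @export
glance.cluster_result <- function(x, ...) {
  tibble::tibble(n_points = nrow(x$points), n_clusters = x$n_clusters,
                 n_noise = sum(x$points$cluster_label == -1L),
                 min_cluster_size = x$parameters$min_cluster_size,
                 xi = x$parameters$xi)
}

#' @method tidy distortion_analysis
#' @export
tidy.distortion_analysis <- function(x, ...) tibble::as_tibble(x$curve)

#' @method glance distortion_analysis
#' @export
glance.distortion_analysis <- function(x, ...) {
  tibble::tibble(expansion_factor = x$transform$scale,
                 landmark_rmse_px = x$transform$rmse_px,
                 n_landmarks = x$transform$n,
                 n_bins = nrow(x$curve),
                 max_length_um = max(x$curve$bin_center_um),
                 demons_converged = x$field$metadata$converged)
}

#' @method tidy puncta_analysis
#' @export
tidy.puncta_analysis <- function(x, ...) x$puncta

#' @method glance puncta_analysis
#' @export
glance.puncta_analysis <- function(x, ...) {
  s <- x$summary
  tibble::tibble(n_detected = x$n_detected, n_isolated = x$n_isolated,
                 n_qc_pass = s$n, median_nm = s$median_nm,
                 q25_nm = s$q25_nm, q75_nm = s$q75_nm)
}

#' Plot a distortion curve
#'
#' Mean (solid), standard deviation (dashed) and RMS measurement error
#' versus measurement length, pre-expansion scale.
#'
#' @param object A `distortion_curve`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot distortion_curve
#' @export
autoplot.distortion_curve <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_center_um)) +
    ggplot2::geom_line(ggplot2::aes(y = .data$mean_err_um, linetype = "mean")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$sd_err_um, linetype = "sd")) +
    ggplot2::geom_line(ggplot2::aes(y = .data$rms_err_um, linetype = "rms")) +
    ggplot2::scale_linetype_manual(NULL,
      values = c(mean = "solid", sd = "dashed", rms = "dotdash")) +
    ggplot2::labs(x = "measurement length (µm, pre-expansion)",
                  y = "measurement error (µm, pre-expansion)") +
    ggplot2::theme_classic()
}

#' Plot a displacement field as a sparse quiver
#'
#' Vectors are subsampled on a regular grid; `arrow_scale` magnifies them
#' for display only (the underlying statistics are never scaled).
#'
#' @param object A [displacement_field()].
#' @param step Grid stride (px) between displayed vectors.
#' @param arrow_scale Display-only magnification of vector length.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot displacement_field
#' @export
autoplot.displacement_field <- function(object, step = 16, arrow_scale = 2.5, ...) {
  d <- dim(object$field)
  ys <- seq(1, d[1], by = step); xs <- seq(1, d[2], by = step)
  df <- tidyr::expand_grid(y = ys, x = xs) |>
    dplyr::mutate(dy = object$field[, , 1][cbind(.data$y, .data$x)],
                  dx = object$field[, , 2][cbind(.data$y, .data$x)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_segment(ggplot2::aes(xend = .data$x + arrow_scale * .data$dx,
                                       yend = .data$y + arrow_scale * .data$dy),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "pt"))) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (px)", y = "y (px)",
                  caption = paste0("vectors scaled ×", arrow_scale,
                                   " for display")) +
    ggplot2::theme_classic()
}

#' Plot the FWHM distribution of fitted puncta
#'
#' @param object Punctum tibble from [fit_puncta()] (QC-passing rows are
#'   shown when a `qc_pass` column is present).
#' @param binwidth_nm Histogram bin width (nm).
#' @param ... Unused.
#' @return A ggplot.
#' @export
plot_fwhm_distribution <- function(object, binwidth_nm = 5, ...) {
  df <- if ("qc_pass" %in% names(object)) dplyr::filter(object, .data$qc_pass)
  else object
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fwhm_native_nm)) +
    ggplot2::geom_histogram(binwidth = binwidth_nm, boundary = 0,
                            fill = "grey70", color = "grey30") +
    ggplot2::geom_vline(xintercept = median(df$fwhm_native_nm),
                        linetype = "dashed") +
    ggplot2::labs(x = "FWHM (nm, native tissue scale)", y = "puncta") +
    ggplot2::theme_classic()
}

#' Plot an OPTICS reachability profile
#'
#' @param object A `cluster_result`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cluster_result
#' @export
autoplot.cluster_result <- function(object, ...) {
  if (is.null(object$reachability))
    abort("No reachability profile (all points were noise).",
          class = "exmqc_validation_error")
  df <- object$reachability |>
    dplyr::mutate(pos = dplyr::row_number(),
                  cluster = factor(.data$cluster_label))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$pos, y = .data$reachability,
                                   fill = .data$cluster)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::labs(x = "OPTICS order", y = "reachability distance (px)") +
    ggplot2::theme_classic()
}
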