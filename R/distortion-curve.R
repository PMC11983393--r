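#' Measurement error versus measurement length
#'
#' Samples `n_pairs` pairs of feature points uniformly (with replacement)
#' from the foreground mask, evaluates the distortion field at both points,
#' and reports the measurement error `||d(p) - d(q)||` as a function of the
#' measurement length `L = ||p - q||`, binned in `bin_width_um` bins. All
#' lengths and errors are at the pre-expansion scale (expanded distances
#' divided by the expansion factor).
#'
#' @param field A [displacement_field()] (carries voxel size and expansion
#'   factor for the physical conversion).
#' @param mask A `foreground_mask` (see [foreground_mask()]) or logical
#'   matrix on the same grid.
#' @param n_pairs Number of sampled pairs (> 0); degenerate pairs `p == q`
#'   are discarded and resampled.
#' @param bin_width_um Bin width for the measurement length (pre-expansion
#'   um).
#' @param seed Integer RNG seed for pair sampling.
#' @param min_pairs_per_bin Bins with fewer pairs are suppressed.
#' @param max_length_quantile Bins are kept up to this quantile of the
#'   sampled pair lengths (curbs unstable outermost bins).
#' @return A `distortion_curve` tibble with `bin_center_um`, `mean_err_um`,
#'   `sd_err_um`, `rms_err_um`, `mean_len_um` and `n_pairs`.
#' @export
measurement_error_curve <- function(field, mask, n_pairs = 200000,
                                    bin_width_um = 1, seed = NULL,
                                    min_pairs_per_bin = 50,
                                    max_length_quantile = 0.95) {
  stopifnot(inherits(field, "displacement_field"))
  m <- if (inherits(mask, "foreground_mask")) mask$mask else mask
  if (!is.logical(m)) abort("`mask` must be logical.", class = "exmqc_validation_error")
  if (!all(dim(m) == dim(field$field)[1:2]))
    abort("Mask and field grids differ.", class = "exmqc_validation_error")
  if (n_pairs <= 0) abort("`n_pairs` must be > 0.", class = "exmqc_validation_error")
  idx <- which(m)
  if (length(idx) < 2)
    abort("Mask must contain at least 2 pixels.", class = "exmqc_empty_foreground_error")
  ny <- nrow(m)
  um_px <- pre_um_per_px(field)
  dy <- field$field[, , 1]; dx <- field$field[, , 2]
  samp <- with_seed(seed, {
    i <- sample(idx, n_pairs, replace = TRUE)
    j <- sample(idx, n_pairs, replace = TRUE)
    for (rep in 1:100) {
      deg <- i == j
      if (!any(deg)) break
      j[deg] <- sample(idx, sum(deg), replace = TRUE)
    }
    keep <- i != j
    list(i = i[keep], j = j[keep])
  })
  i <- samp$i; j <- samp$j
  yi <- (i - 1) %% ny; xi <- (i - 1) %/% ny
  yj <- (j - 1) %% ny; xj <- (j - 1) %/% ny
  L_um <- sqrt((yi - yj)^2 + (xi - xj)^2) * um_px
  err_um <- sqrt((dy[i] - dy[j])^2 + (dx[i] - dx[j])^2) * um_px
  max_len <- quantile(L_um, max_length_quantile, names = FALSE, type = 7)
  bin <- floor(L_um / bin_width_um)
  keep <- L_um <= max_len
  df <- tibble::tibble(bin = bin[keep], L = L_um[keep], e = err_um[keep])
  curve <- df |>
    dplyr::group_by(.data$bin) |>
    dplyr::summarise(
      bin_center_um = (.data$bin[1] + 0.5) * bin_width_um,
      mean_err_um = mean(.data$e),
      sd_err_um = if (dplyr::n() > 1) stats::sd(.data$e) else 0,
      rms_err_um = sqrt(mean(.data$e^2)),
      mean_len_um = mean(.data$L),
      n_pairs = dplyr::n(),
      .groups = "drop") |>
    dplyr::filter(.data$n_pairs >= min_pairs_per_bin) |>
    dplyr::arrange(.data$bin_center_um) |>
    dplyr::select(-"bin")
  new_distortion_curve(curve, bin_width_um = bin_width_um,
                       n_pairs_total = n_pairs, seed = seed)
}

new_distortion_curve <- function(df, bin_width_um, n_pairs_total = NA,
                                 seed = NULL) {
  structure(df, class = c("distortion_curve", class(tibble::tibble()))) |>
    (\(x) { attr(x, "bin_width_um") <- bin_width_um
            attr(x, "n_pairs_total") <- n_pairs_total
            attr(x, "seed") <- seed; x })()
}

#' Pool distortion curves across specimens by RMS
#'
#' Combines per-specimen measurement-error curves into a single curve whose
#' per-bin RMS pools the squared errors of all specimens (weighted by the
#' per-specimen pair counts). Pooling squared errors gives the RMS over all
#' sampled pairs, the natural cross-specimen summary; per-bin means and SDs
#' are recovered from the pooled first and second moments.
#'
#' @param curves List of `distortion_curve` tibbles sharing the same bin
#'   width.
#' @return A pooled `distortion_curve` tibble.
#' @export
rms_across_samples <- function(curves) {
  if (inherits(curves, "distortion_curve")) curves <- list(curves)
  if (length(curves) == 0)
    abort("Need at least one curve.", class = "exmqc_validation_error")
  bw <- unique(vapply(curves, function(cv) attr(cv, "bin_width_um"), numeric(1)))
  if (length(bw) != 1 || any(is.na(bw)))
    abort("Curves have inconsistent binning.", class = "exmqc_validation_error")
  pooled <- purrr::map_dfr(curves, tibble::as_tibble) |>
    dplyr::group_by(.data$bin_center_um) |>
    dplyr::summarise(
      mean_err_um = sum(.data$n_pairs * .data$mean_err_um) / sum(.data$n_pairs),
      ex2 = sum(.data$n_pairs * .data$rms_err_um^2) / sum(.data$n_pairs),
      mean_len_um = sum(.data$n_pairs * .data$mean_len_um) / sum(.data$n_pairs),
      n_pairs = sum(.data$n_pairs),
      .groups = "drop") |>
    dplyr::mutate(
      rms_err_um = sqrt(.data$ex2),
      sd_err_um = sqrt(pmax(.data$ex2 - .data$mean_err_um^2, 0))) |>
    dplyr::select("bin_center_um", "mean_err_um", "sd_err_um", "rms_err_um",
                  "mean_len_um", "n_pairs") |>
    dplyr::arrange(.data$bin_center_um)
  new_distortion_curve(pooled, bin_width_um = bw,
                       n_pairs_total = sum(vapply(curves, function(cv)
                         sum(cv$n_pairs), numeric(1))))
}
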