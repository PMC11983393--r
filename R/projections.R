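#' Maximum intensity projection
#'
#' Projects a 3D stack to a 2D plane by taking, for each output pixel, the
#' maximum over the selected slices along `axis`.
#'
#' @param vol A 3D [image_volume()].
#' @param axis Axis to project over: 1 (z, default), 2 (y) or 3 (x).
#' @param slice_range Optional integer vector of 1-based slice indices along
#'   `axis`; defaults to all slices.
#' @return A 2D [image_volume()] inheriting the remaining voxel sizes and
#'   metadata.
#' @export
max_intensity_projection <- function(vol, axis = 1L, slice_range = NULL) {
  stopifnot(inherits(vol, "image_volume"))
  d <- dim(vol$data)
  if (length(d) != 3) abort("`vol` must be 3D.", class = "exmqc_validation_error")
  if (!axis %in% 1:3) abort("`axis` must be 1, 2 or 3.", class = "exmqc_validation_error")
  slice_range <- slice_range %||% seq_len(d[axis])
  if (length(slice_range) == 0)
    abort("`slice_range` must select at least one slice.",
          class = "exmqc_validation_error")
  if (any(slice_range < 1 | slice_range > d[axis]))
    abort("`slice_range` out of bounds.", class = "exmqc_validation_error")
  sub <- switch(axis,
                vol$data[slice_range, , , drop = FALSE],
                vol$data[, slice_range, , drop = FALSE],
                vol$data[, , slice_range, drop = FALSE])
  proj <- apply(sub, setdiff(1:3, axis), max)
  image_volume(proj, voxel_size_nm = vol$voxel_size_nm[setdiff(1:3, axis)],
               expansion_factor = vol$expansion_factor, channel = vol$channel)
}

#' Intensity profile along a line segment
#'
#' Samples image intensity along the segment from `p0` to `p1` at 1-pixel
#' spacing, averaging over `width` parallel samples taken perpendicular to
#' the segment for noise reduction (bilinear interpolation at each sample
#' point). The distance axis is reported in expanded-sample nm and, when the
#' volume carries an expansion factor, at native tissue scale.
#'
#' @param img A 2D [image_volume()] (a single confocal or STED plane).
#' @param p0,p1 Numeric `(y, x)` endpoints in 0-based pixel coordinates.
#' @param width Odd integer >= 1; number of perpendicular samples averaged.
#' @return A tibble with `distance_px`, `distance_nm_expanded`,
#'   `distance_nm_native` (NA when the expansion factor is unknown) and
#'   `intensity`.
#' @export
line_profile <- function(img, p0, p1, width = 3L) {
  stopifnot(inherits(img, "image_volume"))
  if (length(dim(img$data)) != 2)
    abort("`img` must be a 2D plane.", class = "exmqc_validation_error")
  if (width < 1 || width %% 2 == 0)
    abort("`width` must be an odd integer >= 1.", class = "exmqc_validation_error")
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  if (all(p0 == p1)) abort("`p0` and `p1` must differ.", class = "exmqc_validation_error")
  d <- dim(img$data)
  # to 1-based continuous coordinates
  a <- p0 + 1; b <- p1 + 1
  len_px <- sqrt(sum((b - a)^2))
  n <- floor(len_px) + 1L
  t <- seq(0, len_px, by = 1)
  dir <- (b - a) / len_px            # (dy, dx)
  perp <- c(-dir[2], dir[1])
  offs <- seq(-(width - 1) / 2, (width - 1) / 2)
  ys <- outer(a[1] + t * dir[1], offs * perp[1], `+`)
  xs <- outer(a[2] + t * dir[2], offs * perp[2], `+`)
  if (any(ys < 1 | ys > d[1] | xs < 1 | xs > d[2]))
    abort("Line profile (including its width) leaves the image bounds.",
          class = "exmqc_validation_error")
  vals <- matrix(interp_bilinear(img$data, as.vector(ys), as.vector(xs)),
                 nrow = length(t))
  inten <- rowMeans(vals)
  vox <- mean(tail(img$voxel_size_nm, 2))
  tibble::tibble(
    distance_px = t,
    distance_nm_expanded = t * vox,
    distance_nm_native = if (is.na(img$expansion_factor)) NA_real_ else
      t * vox / img$expansion_factor,
    intensity = inten
  )
}
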