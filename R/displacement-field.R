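#' Displacement field on an image grid
#'
#' A per-pixel 2D vector field, stored as an array `(y, x, 2)` with
#' components `(dy, dx)` in pixels of its grid, together with the physical
#' metadata needed to convert to pre-expansion micrometres: the grid voxel
#' size (nm, expanded scale) and the expansion factor. One pre-expansion
#' micrometre corresponds to `expansion_factor * 1000 / voxel_size_nm`
#' grid pixels.
#'
#' @param field Numeric array `(ny, nx, 2)`, components `(dy, dx)` in px.
#' @param voxel_size_nm Grid pixel size in nm (expanded-sample scale);
#'   scalar or `(y, x)` pair (the mean is used for conversions).
#' @param expansion_factor Linear expansion factor (> 0).
#' @param metadata Optional list of provenance (iterations, smoothing, ...).
#' @return A `displacement_field` object.
#' @export
displacement_field <- function(field, voxel_size_nm, expansion_factor,
                               metadata = list()) {
  if (length(dim(field)) != 3 || dim(field)[3] != 2)
    abort("`field` must be an (ny, nx, 2) array.", class = "exmqc_validation_error")
  if (any(!is.finite(field)))
    abort("`field` must be finite everywhere.", class = "exmqc_validation_error")
  if (expansion_factor <= 0)
    abort("`expansion_factor` must be > 0.", class = "exmqc_validation_error")
  structure(
    list(field = field, voxel_size_nm = rep_len(voxel_size_nm, 2),
         expansion_factor = expansion_factor, metadata = metadata),
    class = "displacement_field"
  )
}

#' @export
print.displacement_field <- function(x, ...) {
  d <- dim(x$field)
  mag <- sqrt(x$field[, , 1]^2 + x$field[, , 2]^2)
  cat("<displacement_field> ", d[1], " x ", d[2], " px\n", sep = "")
  cat("  |d|: median ", signif(median(mag), 3), " px, max ",
      signif(max(mag), 3), " px\n", sep = "")
  cat("  pre-scale unit: 1 px = ",
      signif(pre_um_per_px(x), 4), " um (pre-expansion)\n", sep = "")
  invisible(x)
}

# micrometres at pre-expansion scale per grid pixel
pre_um_per_px <- function(field) {
  mean(field$voxel_size_nm) / 1000 / field$expansion_factor
}

#' Sample a displacement field at fractional positions
#'
#' @param field A [displacement_field()].
#' @param y,x 0-based fractional pixel positions.
#' @return A two-column matrix `(dy, dx)` in grid pixels.
#' @export
sample_field <- function(field, y, x) {
  cbind(dy = interp_bilinear(field$field[, , 1], y + 1, x + 1),
        dx = interp_bilinear(field$field[, , 2], y + 1, x + 1))
}
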