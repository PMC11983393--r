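#' Image volume with physical metadata
#'
#' Container for a 2D plane or 3D stack of fluorescence intensities together
#' with its per-axis voxel size (nm, at the *expanded-sample* scale) and,
#' when known, the expansion factor relating the expanded sample to the
#' native tissue. Axis order is `(y, x)` for planes and `(z, y, x)` for
#' volumes; all public coordinate tables in the package are 0-based in these
#' axes.
#'
#' @param data Numeric matrix `(y, x)` or 3D array `(z, y, x)` of
#'   nonnegative photon counts or normalized floats.
#' @param voxel_size_nm Per-axis voxel size in nm (expanded-sample scale);
#'   a scalar is recycled across axes.
#' @param expansion_factor Dimensionless linear expansion factor (> 0), or
#'   `NA` while not yet measured. Distances at native tissue scale are
#'   expanded distances divided by this factor.
#' @param channel Optional free-text channel label.
#'
#' @return An object of class `image_volume`.
#' @export
#' @examples
#' vol <- image_volume(matrix(0:3, 2, 2), voxel_size_nm = 30)
#' vol
image_volume <- function(data, voxel_size_nm, expansion_factor = NA_real_,
                         channel = NULL) {
  if (is.null(dim(data))) abort("`data` must be a matrix or 3D array.",
                                class = "exmqc_validation_error")
  nd <- length(dim(data))
  if (!nd %in% 2:3) abort("`data` must be 2D (y, x) or 3D (z, y, x).",
                          class = "exmqc_validation_error")
  voxel_size_nm <- rep_len(as.numeric(voxel_size_nm), nd)
  if (any(!is.finite(voxel_size_nm)) || any(voxel_size_nm <= 0))
    abort("All voxel sizes must be finite and > 0.",
          class = "exmqc_validation_error")
  if (!is.na(expansion_factor) && expansion_factor <= 0)
    abort("`expansion_factor` must be > 0.", class = "exmqc_validation_error")
  if (min(data, na.rm = TRUE) < 0 && is.integer(data[1]))
    abort("Raw counts must be nonnegative.", class = "exmqc_validation_error")
  structure(
    list(data = data, voxel_size_nm = voxel_size_nm,
         expansion_factor = as.numeric(expansion_factor),
         channel = channel),
    class = "image_volume"
  )
}

#' @export
print.image_volume <- function(x, ...) {
  d <- dim(x$data)
  axes <- if (length(d) == 2) c("y", "x") else c("z", "y", "x")
  cat("<image_volume> ", paste(d, collapse = " x "), " (", paste(axes, collapse = ","), ")\n",
      sep = "")
  cat("  voxel size (nm, expanded): ", paste(signif(x$voxel_size_nm, 6), collapse = " x "), "\n", sep = "")
  cat("  expansion factor: ", ifelse(is.na(x$expansion_factor), "unknown",
                                     signif(x$expansion_factor, 4)), "\n", sep = "")
  if (!is.null(x$channel)) cat("  channel: ", x$channel, "\n", sep = "")
  invisible(x)
}

#' @export
dim.image_volume <- function(x) dim(x$data)

#' Read an image volume from TIFF
#'
#' Reads a single- or multi-page TIFF into an [image_volume()]. Physical
#' metadata (voxel size, expansion factor, channel) is taken from a JSON
#' sidecar `<path>.json` written by [write_image_volume()]; when the sidecar
#' is absent a warning is raised and the voxel size is marked unknown
#' (`NA` replaced by 1 nm with a `voxel_size_known = FALSE` note).
#'
#' @param path Path to a TIFF file.
#' @return An [image_volume()]. Multi-page files become 3D `(z, y, x)` data.
#' @export
read_image_volume <- function(path) {
  if (!file.exists(path))
    abort(paste0("File not found: ", path), class = "exmqc_not_found_error")
  sidecar <- paste0(path, ".json")
  meta <- NULL
  if (file.exists(sidecar))
    meta <- jsonlite::read_json(sidecar, simplifyVector = TRUE)
  as_float <- identical(meta$stored_as %||% "", "float32")
  pages <- tryCatch(tiff::readTIFF(path, all = TRUE, as.is = !as_float),
                    error = function(e)
                      abort(paste0("Not a readable TIFF: ", path),
                            class = "exmqc_format_error", parent = e))
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3) p <- p[, , 1]  # drop redundant channels
    p
  })
  data <- if (length(pages) == 1) pages[[1]] else {
    arr <- array(0, c(length(pages), nrow(pages[[1]]), ncol(pages[[1]])))
    for (i in seq_along(pages)) arr[i, , ] <- pages[[i]]
    arr
  }
  if (as_float)
    data <- data * (meta$float_scale %||% 1) + (meta$float_offset %||% 0)
  if (is.null(meta)) {
    warn("No metadata sidecar found; voxel size unknown (set to 1 nm).")
    vol <- image_volume(data, voxel_size_nm = 1)
    vol$voxel_size_known <- FALSE
    return(vol)
  }
  vol <- image_volume(data,
                      voxel_size_nm = meta$voxel_size_nm,
                      expansion_factor = meta$expansion_factor %||% NA_real_,
                      channel = meta$channel)
  vol$voxel_size_known <- TRUE
  vol
}

#' Write an image volume to TIFF
#'
#' Writes the intensity grid as a single- or multi-page TIFF (pages along
#' `z`) and its physical metadata to a JSON sidecar `<path>.json`. Integer
#' data are stored losslessly as 16-bit unsigned samples; floating-point
#' data as 32-bit floats rescaled into the unit interval (the affine map is
#' recorded in the sidecar). The sidecar is authoritative for physical
#' metadata, since TIFF tags cannot carry z spacing portably.
#'
#' @param vol An [image_volume()].
#' @param path Output TIFF path.
#' @return `path`, invisibly.
#' @export
write_image_volume <- function(vol, path) {
  stopifnot(inherits(vol, "image_volume"))
  d <- dim(vol$data)
  pages <- if (length(d) == 2) list(vol$data) else
    lapply(seq_len(d[1]), function(z) vol$data[z, , ])
  is_int <- all(vol$data == round(vol$data)) && max(vol$data) <= 65535 &&
    min(vol$data) >= 0
  offset <- 0; scale <- 1
  if (is_int) {
    pages <- lapply(pages, function(p) p / 65535)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L, compression = "none")
  } else {
    # float samples must be stored in [0, 1]; record the affine map in the
    # sidecar and invert it on read
    rng <- range(vol$data)
    offset <- rng[1]
    scale <- if (diff(rng) > 0) diff(rng) else 1
    pages <- lapply(pages, function(p) (p - offset) / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 32L, compression = "none")
  }
  meta <- list(voxel_size_nm = vol$voxel_size_nm,
               expansion_factor = if (is.na(vol$expansion_factor)) NULL else
                 vol$expansion_factor,
               channel = vol$channel,
               stored_as = if (is_int) "uint16" else "float32",
               float_offset = offset, float_scale = scale)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, null = "null")
  invisible(path)
}

#' Convert an expanded-scale distance to native tissue scale
#'
#' @param distance Distance(s) at the expanded-sample scale.
#' @param expansion_factor Linear expansion factor (> 0).
#' @return `distance / expansion_factor`.
#' @export
to_native_scale <- function(distance, expansion_factor) {
  if (is.na(expansion_factor) || expansion_factor <= 0)
    abort("`expansion_factor` must be a positive number.",
          class = "exmqc_validation_error")
  distance / expansion_factor
}
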