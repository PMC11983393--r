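#' Read a paired landmark table
#'
#' Landmark tables pair ~20 manually placed corresponding features between a
#' pre-expansion and a post-expansion image. The CSV schema is
#' `pre_z,pre_y,pre_x,post_z,post_y,post_x` (the `*_z` columns are absent
#' for 2D landmarks), with coordinates in 0-based pixel units of the
#' respective image.
#'
#' @param path Path to a landmark CSV.
#' @return A tibble with the landmark columns, one row per pair.
#' @export
read_landmarks <- function(path) {
  if (!file.exists(path))
    abort(paste0("File not found: ", path), class = "exmqc_not_found_error")
  lm <- readr::read_csv(path, show_col_types = FALSE)
  validate_landmarks(lm)
}

#' Write a paired landmark table
#'
#' @param landmarks Tibble as returned by [read_landmarks()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_landmarks <- function(landmarks, path) {
  validate_landmarks(landmarks)
  readr::write_csv(landmarks, path)
  invisible(path)
}

#' Validate a landmark table
#'
#' Checks the column schema (matched `pre_*`/`post_*` sets, 2D or 3D) and
#' that at least 3 pairs are present.
#'
#' @param landmarks A data frame of paired landmarks.
#' @return The validated table as a tibble.
#' @export
validate_landmarks <- function(landmarks) {
  lm <- tibble::as_tibble(landmarks)
  cols2 <- c("pre_y", "pre_x", "post_y", "post_x")
  cols3 <- c("pre_z", cols2[1:2], "post_z", cols2[3:4])
  if (all(cols3 %in% names(lm))) {
    lm <- lm[, cols3]
  } else if (all(cols2 %in% names(lm)) &&
             !any(c("pre_z", "post_z") %in% names(lm))) {
    lm <- lm[, cols2]
  } else {
    abort("Landmark columns must be pre_[zyx]/post_[zyx] with matching dimensionality.",
          class = "exmqc_format_error")
  }
  if (nrow(lm) < 3)
    abort("At least 3 landmark pairs are required.",
          class = "exmqc_validation_error")
  if (any(!vapply(lm, is.numeric, logical(1))))
    abort("Landmark coordinates must be numeric.",
          class = "exmqc_format_error")
  lm
}

# Split a validated landmark tibble into pre/post coordinate matrices,
# columns ordered (z,)y,x; values 0-based pixels.
landmark_matrices <- function(landmarks) {
  lm <- validate_landmarks(landmarks)
  is3d <- "pre_z" %in% names(lm)
  pre_cols <- if (is3d) c("pre_z", "pre_y", "pre_x") else c("pre_y", "pre_x")
  post_cols <- sub("^pre", "post", pre_cols)
  list(pre = as.matrix(lm[, pre_cols]), post = as.matrix(lm[, post_cols]))
}
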