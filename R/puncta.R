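#' Normalize raw photon counts by a high percentile
#'
#' Divides the raw intensities by their 99.9th percentile (linear
#' interpolation between order statistics), turning integer photon counts
#' into floating-point values on a comparable brightness scale; values may
#' exceed 1.
#'
#' @param vol An [image_volume()] of nonnegative counts.
#' @param probs Percentile used for normalization (default 0.999).
#' @return The normalized [image_volume()].
#' @export
normalize_image <- function(vol, probs = 0.999) {
  stopifnot(inherits(vol, "image_volume"))
  p <- quantile(vol$data, probs, names = FALSE, type = 7)
  if (p <= 0)
    abort("Normalization percentile is 0; image carries no signal.",
          class = "exmqc_validation_error")
  out <- vol
  out$data <- vol$data / p
  out
}

# neighbor offsets for full (8/26) connectivity
neighbor_offsets <- function(nd) {
  grid <- do.call(expand.grid, rep(list(-1:1), nd))
  as.matrix(grid[rowSums(abs(grid)) > 0, , drop = FALSE])
}

# shift array by integer offset, padding with `fill`
shift_pad <- function(x, off, fill = -Inf) {
  d <- dim(x)
  out <- array(fill, d)
  src <- dst <- vector("list", length(d))
  for (i in seq_along(d)) {
    o <- off[i]
    src[[i]] <- max(1, 1 - o):min(d[i], d[i] - o)
    dst[[i]] <- src[[i]] + o
  }
  if (length(d) == 2) out[dst[[1]], dst[[2]]] <- x[src[[1]], src[[2]]]
  else out[dst[[1]], dst[[2]], dst[[3]]] <- x[src[[1]], src[[2]], src[[3]]]
  out
}

#' Detect punctum candidates as smoothed local intensity maxima
#'
#' Smooths the normalized image with an isotropic Gaussian, finds strict
#' local maxima under full (8- or 26-) connectivity, discards maxima whose
#' smoothed brightness is not greater than `min_rel_brightness` times the
#' smoothed-image maximum, and enforces a minimum separation by greedily
#' keeping the brighter member of any violating pair.
#'
#' @param vol Normalized [image_volume()] (2D or 3D), see
#'   [normalize_image()].
#' @param sigma_smooth Isotropic smoothing sigma (px); >= 0.
#' @param min_rel_brightness Brightness cutoff relative to the smoothed
#'   image maximum (0..1).
#' @param min_separation_px Optional minimum distance between detections;
#'   of two closer maxima the brighter one is kept.
#' @return Tibble of candidates with 0-based integer coordinates (`z`,)
#'   `y`, `x` and smoothed `brightness`, ordered brightest first.
#' @export
detect_local_maxima <- function(vol, sigma_smooth, min_rel_brightness = 0.25,
                                min_separation_px = NULL) {
  stopifnot(inherits(vol, "image_volume"))
  if (sigma_smooth < 0) abort("`sigma_smooth` must be >= 0.", class = "exmqc_validation_error")
  if (min_rel_brightness < 0 || min_rel_brightness > 1)
    abort("`min_rel_brightness` must be in [0, 1].", class = "exmqc_validation_error")
  sm <- if (sigma_smooth > 0) gaussian_blur(vol$data, sigma_smooth) else vol$data
  nd <- length(dim(sm))
  offs <- neighbor_offsets(nd)
  # a maximum is >= every neighbor and > at least one (plateau interiors and
  # flat regions yield nothing; equal twin peaks survive until the
  # separation rule keeps the brighter/first)
  nb_max <- array(-Inf, dim(sm))
  nb_min <- array(Inf, dim(sm))
  for (k in seq_len(nrow(offs))) {
    nb_max <- pmax(nb_max, shift_pad(sm, offs[k, ], fill = -Inf))
    nb_min <- pmin(nb_min, shift_pad(sm, offs[k, ], fill = Inf))
  }
  is_max <- (sm >= nb_max) & (sm > nb_min)
  cutoff <- min_rel_brightness * max(sm)
  is_max <- is_max & (sm > cutoff)
  idx <- which(is_max)
  coord_cols <- if (nd == 3) c("z", "y", "x") else c("y", "x")
  if (length(idx) == 0) {
    out <- tibble::as_tibble(setNames(rep(list(numeric(0)), nd), coord_cols))
    out$brightness <- numeric(0)
    return(out)
  }
  pos <- arrayInd(idx, dim(sm)) - 1  # 0-based
  br <- sm[idx]
  ord <- order(-br, idx)  # brightness-descending, stable
  pos <- pos[ord, , drop = FALSE]; br <- br[ord]
  if (!is.null(min_separation_px) && nrow(pos) > 1) {
    keep <- logical(nrow(pos))
    kept <- matrix(numeric(0), 0, nd)
    for (i in seq_len(nrow(pos))) {
      if (nrow(kept) == 0 ||
          min(sqrt(rowSums((kept - matrix(pos[i, ], nrow(kept), nd,
                                          byrow = TRUE))^2))) >= min_separation_px) {
        keep[i] <- TRUE
        kept <- rbind(kept, pos[i, ])
      }
    }
    pos <- pos[keep, , drop = FALSE]; br <- br[keep]
  }
  out <- tibble::as_tibble(setNames(as.data.frame(pos), coord_cols))
  out$brightness <- br
  out
}

#' Select isolated candidates
#'
#' Keeps exactly those candidates whose nearest other candidate is at least
#' `min_distance_px` away (Euclidean). The criterion is symmetric: both
#' members of a too-close pair are excluded. Isolation protects the
#' subsequent single-spot Gaussian fits from overlapping neighbors.
#'
#' @param candidates Tibble with coordinate columns (`z`,) `y`, `x`.
#' @param min_distance_px Minimum allowed nearest-neighbor distance (> 0).
#' @return The isolated subset of `candidates`.
#' @export
select_isolated <- function(candidates, min_distance_px) {
  if (min_distance_px <= 0)
    abort("`min_distance_px` must be > 0.", class = "exmqc_validation_error")
  n <- nrow(candidates)
  if (n <= 1) return(candidates)
  coords <- as.matrix(candidates[, intersect(c("z", "y", "x"), names(candidates))])
  dm <- as.matrix(stats::dist(coords))
  diag(dm) <- Inf
  candidates[apply(dm, 1, min) >= min_distance_px, , drop = FALSE]
}

gauss_model_info <- function(model) {
  switch(model,
         iso2d = list(nd = 2L, iso = TRUE, dof = 4L),
         aniso2d = list(nd = 2L, iso = FALSE, dof = 5L),
         iso3d = list(nd = 3L, iso = TRUE, dof = 5L),
         aniso3d = list(nd = 3L, iso = FALSE, dof = 7L),
         abort("Unknown model; use iso2d, aniso2d, iso3d or aniso3d.",
               class = "exmqc_validation_error"))
}

#' Fit a Gaussian to one punctum
#'
#' Nonlinear least-squares fit (Levenberg–Marquardt) of a Gaussian without
#' constant offset to a square/cubic window of the normalized raw image
#' centered on a candidate. Models: `iso2d` (amplitude, sigma, y, x; 4
#' dof), `aniso2d` (5 dof), `iso3d` (5 dof), `aniso3d` (7 dof).
#' Initialization: amplitude = window maximum, sigma = `sigma_init`, center
#' = candidate. Non-convergence is reported in the returned row, never as
#' an error.
#'
#' @param vol Normalized [image_volume()].
#' @param center Candidate center, 0-based (`z`,) `y`, `x` (integer px).
#' @param window_px Odd window edge length (px); the window must lie fully
#'   inside the image.
#' @param model One of `"iso2d"`, `"aniso2d"`, `"iso3d"`, `"aniso3d"`.
#' @param sigma_init Initial sigma (px).
#' @return One-row tibble: fitted 0-based subpixel center, per-axis
#'   `sigma_*_px`, `amplitude`, `converged`, `relative_residual`,
#'   `n_iterations`, plus the candidate coordinates (`cand_*`).
#' @export
fit_gaussian <- function(vol, center, window_px = 41, model = "iso2d",
                         sigma_init = 2) {
  stopifnot(inherits(vol, "image_volume"))
  info <- gauss_model_info(model)
  d <- dim(vol$data)
  if (length(d) != info$nd)
    abort("Model dimensionality does not match the image.",
          class = "exmqc_validation_error")
  half <- (window_px - 1) / 2
  c1 <- round(center) + 1  # 1-based integer
  lo <- c1 - half; hi <- c1 + half
  if (any(lo < 1) || any(hi > d))
    abort("Fit window crosses the image boundary.",
          class = "exmqc_window_error")
  sub <- if (info$nd == 2) vol$data[lo[1]:hi[1], lo[2]:hi[2]]
  else vol$data[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  axes <- lapply(seq_len(info$nd), function(i) seq(0, window_px - 1))
  # expand.grid cycles its first factor fastest, matching column-major
  # array order, so column i is the coordinate along array axis i
  G <- as.matrix(do.call(expand.grid, axes))
  yvec <- as.vector(sub)
  n_sigma <- if (info$iso) 1L else info$nd
  par0 <- c(max(sub), rep(sigma_init, n_sigma), rep(half, info$nd))
  lower <- c(1e-8, rep(0.1, n_sigma), rep(0, info$nd))
  upper <- c(Inf, rep(window_px, n_sigma), rep(window_px - 1, info$nd))
  resid_fn <- function(p) {
    A <- p[1]
    sig <- p[1 + seq_len(n_sigma)]
    mu <- p[1 + n_sigma + seq_len(info$nd)]
    sig_full <- rep_len(sig, info$nd)
    q <- rep(0, length(yvec))
    for (i in seq_len(info$nd))
      q <- q + (G[, i] - mu[i])^2 / (2 * sig_full[i]^2)
    A * exp(-q) - yvec
  }
  fit <- tryCatch(
    minpack.lm::nls.lm(par0, lower = lower, upper = upper, fn = resid_fn,
                       control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  coord_cols <- if (info$nd == 3) c("z", "y", "x") else c("y", "x")
  if (is.null(fit)) {
    row <- setNames(as.list(rep(NA_real_, info$nd)), coord_cols)
    row <- c(row, setNames(as.list(rep(NA_real_, info$nd)),
                           paste0("sigma_", coord_cols, "_px")))
    row$amplitude <- NA_real_
    row$converged <- FALSE
    row$relative_residual <- NA_real_
    row$n_iterations <- NA_integer_
  } else {
    p <- fit$par
    sig_full <- rep_len(p[1 + seq_len(n_sigma)], info$nd)
    mu_global <- p[1 + n_sigma + seq_len(info$nd)] + (lo - 1)  # 0-based global
    # info 1-3: ftol/xtol convergence; 4: gradient orthogonal to residual
    # (reached at an exact zero-residual optimum)
    converged <- fit$info %in% 1:4 &&
      all(sig_full > lower[2] * 1.0001) && all(sig_full < window_px * 0.9999)
    rel_res <- sqrt(sum(fit$fvec^2)) / max(sqrt(sum(yvec^2)), .Machine$double.eps)
    row <- setNames(as.list(mu_global), coord_cols)
    row <- c(row, setNames(as.list(sig_full), paste0("sigma_", coord_cols, "_px")))
    row$amplitude <- p[1]
    row$converged <- converged
    row$relative_residual <- rel_res
    row$n_iterations <- fit$niter
  }
  row <- c(row, setNames(as.list(as.numeric(round(center))),
                         paste0("cand_", coord_cols)))
  tibble::as_tibble(row)
}

#' Convert a fitted sigma to FWHM at expanded and native scale
#'
#' `FWHM_expanded = 2 sqrt(2 ln 2) * sigma_px * voxel_nm` and
#' `FWHM_native = FWHM_expanded / expansion_factor`.
#'
#' @param sigma_px Fitted Gaussian sigma(s), px (>= 0).
#' @param voxel_nm Pixel size (nm, expanded scale, > 0).
#' @param expansion_factor Linear expansion factor (> 0).
#' @return Tibble with `fwhm_expanded_nm` and `fwhm_native_nm`.
#' @export
#' @examples
#' sigma_to_fwhm(2, voxel_nm = 30, expansion_factor = 3.9)
sigma_to_fwhm <- function(sigma_px, voxel_nm, expansion_factor) {
  if (any(sigma_px < 0)) abort("`sigma_px` must be >= 0.", class = "exmqc_validation_error")
  if (voxel_nm <= 0 || expansion_factor <= 0)
    abort("`voxel_nm` and `expansion_factor` must be > 0.",
          class = "exmqc_validation_error")
  fe <- fwhm_factor() * sigma_px * voxel_nm
  tibble::tibble(fwhm_expanded_nm = fe, fwhm_native_nm = fe / expansion_factor)
}

#' Fit all candidates and attach FWHM columns
#'
#' Runs [fit_gaussian()] for every candidate; candidates whose window
#' crosses the image boundary are skipped (counted in the `n_edge_skipped`
#' attribute) rather than padded, since padding biases the fitted sigma.
#'
#' @param vol Normalized [image_volume()].
#' @param candidates Candidate tibble from [detect_local_maxima()] /
#'   [select_isolated()].
#' @param window_px,model,sigma_init See [fit_gaussian()].
#' @param voxel_size_nm Pixel size (nm, expanded scale; scalar or per-axis).
#' @param expansion_factor Linear expansion factor.
#' @return Punctum tibble: fitted centers and sigmas, per-axis and
#'   geometric-mean `fwhm_expanded_nm` / `fwhm_native_nm`, fit diagnostics.
#' @export
fit_puncta <- function(vol, candidates, window_px = 41, model = "iso2d",
                       sigma_init = 2, voxel_size_nm = NULL,
                       expansion_factor = NULL) {
  info <- gauss_model_info(model)
  voxel_size_nm <- rep_len(voxel_size_nm %||% vol$voxel_size_nm, info$nd)
  expansion_factor <- expansion_factor %||% vol$expansion_factor
  coord_cols <- if (info$nd == 3) c("z", "y", "x") else c("y", "x")
  n_edge <- 0L
  rows <- purrr::map(seq_len(nrow(candidates)), function(i) {
    ctr <- as.numeric(candidates[i, coord_cols])
    tryCatch(fit_gaussian(vol, ctr, window_px, model, sigma_init),
             exmqc_window_error = function(e) { n_edge <<- n_edge + 1L; NULL })
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) > 0) {
    sig_cols <- paste0("sigma_", coord_cols, "_px")
    fw_ax <- purrr::map(seq_len(info$nd), function(i)
      fwhm_factor() * out[[sig_cols[i]]] * voxel_size_nm[i])
    fwhm_exp <- exp(Reduce(`+`, purrr::map(fw_ax, log)) / info$nd)  # geometric mean
    for (i in seq_len(info$nd))
      out[[paste0("fwhm_", coord_cols[i], "_expanded_nm")]] <- fw_ax[[i]]
    out$fwhm_expanded_nm <- fwhm_exp
    out$fwhm_native_nm <- fwhm_exp / expansion_factor
  }
  attr(out, "n_edge_skipped") <- n_edge
  attr(out, "window_px") <- window_px
  attr(out, "model") <- model
  out
}

#' Automated fit-quality filter
#'
#' Deterministic surrogate for manual rejection of failed fits (background
#' noise, overlapping peaks, out-of-focus signal): a punctum passes when
#' the fit converged, every sigma lies in `[sigma_min, window_px / 4]`, the
#' fitted center stays within the central third of the window, the relative
#' residual is below `r_max` and the amplitude is positive.
#'
#' @param puncta Punctum tibble from [fit_puncta()].
#' @param window_px Fit window used (defaults to the tibble attribute).
#' @param r_max Maximum relative residual.
#' @param sigma_min Minimum plausible sigma (px).
#' @return `puncta` with `qc_pass` and `reject_reason` columns; rejection
#'   counts in the `qc_counts` attribute.
#' @export
qc_filter <- function(puncta, window_px = NULL, r_max = 0.5, sigma_min = 0.5) {
  window_px <- window_px %||% attr(puncta, "window_px")
  if (is.null(window_px))
    abort("`window_px` must be given (or present as attribute).",
          class = "exmqc_validation_error")
  coord_cols <- intersect(c("z", "y", "x"), names(puncta))
  sig_cols <- paste0("sigma_", coord_cols, "_px")
  cand_cols <- paste0("cand_", coord_cols)
  reason <- character(nrow(puncta))
  for (i in seq_len(max(nrow(puncta), 0))) {
    sig <- as.numeric(puncta[i, sig_cols])
    off <- abs(as.numeric(puncta[i, coord_cols]) - as.numeric(puncta[i, cand_cols]))
    reason[i] <- if (!isTRUE(puncta$converged[i])) "not_converged"
    else if (any(is.na(sig)) || any(sig < sigma_min) || any(sig > window_px / 4)) "sigma_bounds"
    else if (any(off > window_px / 6)) "center_offset"
    else if (!is.finite(puncta$relative_residual[i]) ||
             puncta$relative_residual[i] >= r_max) "residual"
    else if (!isTRUE(puncta$amplitude[i] > 0)) "amplitude"
    else ""
  }
  puncta$qc_pass <- reason == ""
  puncta$reject_reason <- dplyr::na_if(reason, "")
  attr(puncta, "qc_counts") <- table(reason[reason != ""])
  attr(puncta, "window_px") <- window_px
  puncta
}

#' Summarize punctum sizes
#'
#' Median and quartiles (linear-interpolation quantile convention) of the
#' native-scale FWHM over QC-passing puncta.
#'
#' @param puncta Punctum tibble (after [qc_filter()]; if no `qc_pass`
#'   column is present all rows are used).
#' @return A `puncta_summary` tibble: `n`, `median_nm`, `q25_nm`, `q75_nm`.
#' @export
summarize_puncta <- function(puncta) {
  vals <- if ("qc_pass" %in% names(puncta))
    puncta$fwhm_native_nm[puncta$qc_pass] else puncta$fwhm_native_nm
  vals <- vals[is.finite(vals)]
  if (length(vals) < 1)
    abort("No QC-passing puncta to summarize.", class = "exmqc_validation_error")
  q <- quantile(vals, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
  structure(tibble::tibble(n = length(vals), median_nm = q[2],
                           q25_nm = q[1], q75_nm = q[3]),
            class = c("puncta_summary", class(tibble::tibble())))
}
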