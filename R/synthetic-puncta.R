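# Synthetic punctate (vesicle-like) volumes with known spot parameters.

# Evaluate an isotropic/anisotropic Gaussian spot (peak = amplitude) into
# `img` (2D or 3D array), within a +/- 4 sigma box around `center`
# (0-based, subpixel).
add_gaussian_spot <- function(img, center, sigma, amplitude) {
  d <- dim(img); nd <- length(d)
  sigma <- rep_len(sigma, nd)
  c1 <- center + 1  # 1-based
  lo <- pmax(1L, floor(c1 - 4 * sigma))
  hi <- pmin(d, ceiling(c1 + 4 * sigma))
  if (any(lo > hi)) return(img)
  ax <- lapply(seq_len(nd), function(i)
    exp(-(seq(lo[i], hi[i]) - c1[i])^2 / (2 * sigma[i]^2)))
  if (nd == 2) {
    patch <- amplitude * (ax[[1]] %o% ax[[2]])
    img[lo[1]:hi[1], lo[2]:hi[2]] <-
      img[lo[1]:hi[1], lo[2]:hi[2]] + patch
  } else {
    patch <- amplitude * (ax[[1]] %o% ax[[2]] %o% ax[[3]])
    img[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <-
      img[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] + patch
  }
  img
}

# Draw `n` centers with pairwise min separation by rejection sampling.
# Cluster spec: list(k, spread_px, fraction_unclustered).
place_centers <- function(n, shape, min_separation_px, margin, clusters,
                          max_tries_per_point = 500) {
  nd <- length(shape)
  if (n == 0) return(list(centers = matrix(0, 0, nd), label = integer(0)))
  lo <- rep_len(margin, nd); hi <- shape - 1 - lo
  if (any(hi <= lo))
    abort("Image too small for the requested margin.",
          class = "exmqc_validation_error")
  cluster_centers <- NULL
  labels_plan <- rep(-1L, n)
  if (!is.null(clusters)) {
    k <- clusters$k
    cluster_centers <- sapply(seq_len(nd), function(i) runif(k, lo[i], hi[i]))
    cluster_centers <- matrix(cluster_centers, k, nd)
    n_noise <- round(n * (clusters$fraction_unclustered %||% 0))
    assign_n <- n - n_noise
    labels_plan <- c(rep(seq_len(k), length.out = assign_n)[sample(assign_n)],
                     rep(-1L, n_noise))
  }
  centers <- matrix(NA_real_, n, nd)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in seq_len(max_tries_per_point)) {
      cand <- if (labels_plan[i] > 0) {
        cc <- cluster_centers[labels_plan[i], ]
        pmin(pmax(cc + rnorm(nd, 0, clusters$spread_px), lo), hi)
      } else {
        sapply(seq_len(nd), function(j) runif(1, lo[j], hi[j]))
      }
      if (i == 1 ||
          min(sqrt(rowSums((centers[seq_len(i - 1), , drop = FALSE] -
                              matrix(cand, i - 1, nd, byrow = TRUE))^2))) >=
          min_separation_px) {
        centers[i, ] <- cand
        placed <- TRUE
        break
      }
    }
    if (!placed)
      abort(paste0("Cannot place ", n, " puncta at min separation ",
                   min_separation_px, " px (packing failure at point ", i, ")."),
            class = "exmqc_packing_error")
  }
  list(centers = centers, label = labels_plan)
}

#' Simulate a punctate super-resolution volume with known spot parameters
#'
#' Renders `n_puncta` Gaussian spots (peak value = amplitude) of per-spot
#' sigma onto a flat background, optionally grouped into clusters, and
#' applies Poisson noise last — emulating photon-counting STED images of
#' labeled vesicles. The returned truth table carries exact subpixel
#' centers, sigmas, amplitudes and planted cluster labels.
#'
#' @param shape Volume shape `(z, y, x)` (or `(y, x)` for a single plane).
#' @param n_puncta Number of spots.
#' @param sigma_range Range (px) of per-spot isotropic sigma, drawn
#'   uniformly; pass a single value for fixed sigma.
#' @param amplitude_range Range (counts) of per-spot peak amplitude.
#' @param min_separation_px Minimum pairwise center distance (px).
#' @param background Flat background level (counts).
#' @param clusters Optional cluster spec:
#'   `list(k =, spread_px =, fraction_unclustered =)`. Clustered spots are
#'   drawn around `k` random cluster centers with isotropic Gaussian spread;
#'   the unclustered fraction is uniform and labeled `-1`.
#' @param poisson Apply Poisson noise to signal + background.
#' @param margin_px Keep-out margin from the volume faces; defaults to
#'   `ceiling(4 * max(sigma_range))`.
#' @param voxel_size_nm,expansion_factor Physical metadata attached to the
#'   returned volume.
#' @param seed Integer RNG seed (bit-identical regeneration).
#' @return A list with `vol` ([image_volume()]) and `truth`, a tibble with
#'   0-based subpixel `z`, `y`, `x` (2D: `y`, `x`), `sigma_px`,
#'   `amplitude`, `cluster_label` (`-1` = unclustered; `NA` when no cluster
#'   spec was given).
#' @export
make_puncta_volume <- function(shape = c(48, 96, 96), n_puncta = 50,
                               sigma_range = c(1.5, 2.5),
                               amplitude_range = c(80, 150),
                               min_separation_px = 8, background = 2,
                               clusters = NULL, poisson = TRUE,
                               margin_px = NULL,
                               voxel_size_nm = 100, expansion_factor = 3.9,
                               seed = NULL) {
  shape <- as.integer(shape)
  nd <- length(shape)
  if (!nd %in% 2:3) abort("`shape` must be 2D or 3D.", class = "exmqc_validation_error")
  if (n_puncta < 0) abort("`n_puncta` must be >= 0.", class = "exmqc_validation_error")
  sigma_range <- range(sigma_range)
  amplitude_range <- range(amplitude_range)
  if (any(amplitude_range <= 0) && n_puncta > 0)
    abort("Amplitudes must be > 0.", class = "exmqc_validation_error")
  margin_px <- margin_px %||% ceiling(4 * max(sigma_range))
  res <- with_seed(seed, {
    pl <- place_centers(n_puncta, shape, min_separation_px, margin_px, clusters)
    sig <- runif(n_puncta, sigma_range[1], sigma_range[2])
    amp <- runif(n_puncta, amplitude_range[1], amplitude_range[2])
    img <- array(background, shape)
    if (nd == 2) img <- matrix(background, shape[1], shape[2])
    for (i in seq_len(n_puncta))
      img <- add_gaussian_spot(img, pl$centers[i, ], sig[i], amp[i])
    if (poisson) {
      noisy <- rpois(length(img), img)
      img <- if (nd == 2) matrix(noisy, shape[1], shape[2]) else array(noisy, shape)
    }
    list(img = img, centers = pl$centers, label = pl$label, sig = sig, amp = amp)
  })
  coord_cols <- if (nd == 3) c("z", "y", "x") else c("y", "x")
  truth <- tibble::as_tibble(setNames(
    as.data.frame(res$centers), coord_cols))
  truth$sigma_px <- res$sig
  truth$amplitude <- res$amp
  truth$cluster_label <- if (is.null(clusters)) NA_integer_ else res$label
  vol <- image_volume(res$img, voxel_size_nm = voxel_size_nm,
                      expansion_factor = expansion_factor, channel = "puncta")
  list(vol = vol, truth = truth)
}
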