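# Density-based clustering of detected puncta: OPTICS reachability ordering
# (Ankerst et al.) with xi-steep automatic cluster extraction, including the
# predecessor correction of Schubert & Gertz. Unassigned points are noise
# (label -1). O(n^2) distance computations; punctum counts here are small.

optics_order <- function(coords, min_samples) {
  n <- nrow(coords)
  dm <- as.matrix(stats::dist(coords))
  core <- apply(dm, 1, function(r) sort(r)[min_samples])  # includes self (0)
  reach <- rep(Inf, n)
  pred <- rep(NA_integer_, n)
  processed <- rep(FALSE, n)
  ordering <- integer(n)
  for (k in seq_len(n)) {
    un <- which(!processed)
    p <- un[which.min(reach[un])]
    processed[p] <- TRUE
    ordering[k] <- p
    un <- which(!processed)
    if (length(un)) {
      rd <- pmax(core[p], dm[p, un])
      better <- rd < reach[un]
      reach[un[better]] <- rd[better]
      pred[un[better]] <- p
    }
  }
  list(ordering = ordering, reachability = reach[ordering],
       predecessor = pred[ordering], core = core)
}

# maximal steep region per the xi method; vectors are 0-based conceptually
# but 1-based here. Returns inclusive end index.
extend_region <- function(steep, xward, start, min_samples) {
  n <- length(steep)
  non_xward <- 0L
  index <- start
  end <- start
  while (index <= n) {
    if (steep[index]) {
      non_xward <- 0L
      end <- index
    } else if (!xward[index]) {
      non_xward <- non_xward + 1L
      if (non_xward > min_samples) break
    } else return(end)
    index <- index + 1L
  }
  end
}

correct_predecessor <- function(r, pred, ordering, s, e) {
  while (s < e) {
    if (r[s] > r[e]) return(c(s, e))
    p_e <- pred[e]
    if (!is.na(p_e) && p_e %in% ordering[s:(e - 1)]) return(c(s, e))
    e <- e - 1L
  }
  c(NA_integer_, NA_integer_)
}

xi_clusters <- function(r, pred, ordering, xi, min_samples, min_cluster_size) {
  n <- length(r)
  r <- c(r, Inf)  # sentinel so trailing clusters close
  xc <- 1 - xi
  ratio <- r[seq_len(n)] / r[seq_len(n) + 1]
  ratio[is.nan(ratio)] <- 1
  steep_up <- ratio <= xc
  steep_down <- ratio >= 1 / xc
  up <- ratio < 1
  down <- ratio > 1
  sdas <- list()
  clusters <- list()
  index <- 1L
  mib <- 0
  update_sdas <- function(sdas, mib) {
    if (is.infinite(mib)) return(list())
    keep <- Filter(function(sda) mib <= r[sda$start] * xc, sdas)
    lapply(keep, function(sda) { sda$mib <- max(sda$mib, mib); sda })
  }
  for (si in which(steep_up | steep_down)) {
    if (si < index) next
    mib <- max(mib, max(r[index:si]))
    if (steep_down[si]) {
      sdas <- update_sdas(sdas, mib)
      d_end <- extend_region(steep_down, up, si, min_samples)
      sdas[[length(sdas) + 1]] <- list(start = si, end = d_end, mib = 0)
      index <- d_end + 1L
      mib <- r[index]
    } else {
      sdas <- update_sdas(sdas, mib)
      u_end <- extend_region(steep_up, down, si, min_samples)
      index <- u_end + 1L
      mib <- r[index]
      u_clusters <- list()
      for (D in sdas) {
        c_start <- D$start; c_end <- u_end
        if (r[c_end + 1] * xc < D$mib) next
        d_max <- r[D$start]
        if (d_max * xc >= r[c_end + 1]) {
          while (c_start < D$end && r[c_start + 1] > r[c_end + 1])
            c_start <- c_start + 1L
        } else if (r[c_end + 1] * xc >= d_max) {
          while (c_end > si && r[c_end - 1] > d_max)
            c_end <- c_end - 1L
        }
        ce <- correct_predecessor(r, pred, ordering, c_start, c_end)
        if (is.na(ce[1])) next
        c_start <- ce[1]; c_end <- ce[2]
        if (c_end - c_start + 1 < min_cluster_size) next
        if (c_start > D$end) next
        if (c_end < si) next
        u_clusters[[length(u_clusters) + 1]] <- c(c_start, c_end)
      }
      clusters <- c(clusters, rev(u_clusters))  # smaller clusters first
    }
  }
  clusters
}

#' Detect puncta for cluster analysis
#'
#' Detection parameterization used ahead of clustering (lighter smoothing
#' and a lower brightness cutoff than for FWHM fitting): normalization by
#' the 99.9th percentile, isotropic Gaussian smoothing with sigma 0.7 px,
#' 3D local maxima with a minimum separation of 2 voxels (the brighter
#' maximum of a closer pair is kept), brightness cutoff 10% of the
#' smoothed-image maximum.
#'
#' @param vol A raw [image_volume()] (3D; 2D accepted).
#' @param sigma_smooth,min_rel_brightness,min_separation_px Overridable
#'   detection parameters (defaults 0.7, 0.10, 2).
#' @return Candidate tibble as from [detect_local_maxima()].
#' @export
detect_cluster_puncta <- function(vol, sigma_smooth = 0.7,
                                  min_rel_brightness = 0.10,
                                  min_separation_px = 2) {
  detect_local_maxima(normalize_image(vol), sigma_smooth = sigma_smooth,
                      min_rel_brightness = min_rel_brightness,
                      min_separation_px = min_separation_px)
}

#' Cluster puncta with OPTICS
#'
#' Orders points by density reachability (OPTICS, `min_samples =
#' min_cluster_size`, unbounded reachability) and extracts clusters with
#' the xi-steep method; points not assigned to any cluster are labeled
#' noise (`-1`). Clustering operates in pixel coordinates; anisotropic
#' voxels should be rescaled to physical units first (done automatically
#' when `voxel_size_nm` is passed).
#'
#' @param points Tibble with coordinate columns (`z`,) `y`, `x` (0-based
#'   px), e.g. from [detect_cluster_puncta()].
#' @param min_cluster_size Minimum number of puncta forming a cluster
#'   (>= 2).
#' @param min_samples OPTICS density parameter (neighbors defining the
#'   core distance); defaults to `min_cluster_size`, which makes the two
#'   the single tunable the procedure exposes.
#' @param xi Minimum relative steepness of a cluster boundary on the
#'   reachability plot.
#' @param voxel_size_nm Optional per-axis voxel size; when given and
#'   anisotropic, coordinates are rescaled to physical units before
#'   clustering.
#' @return A `cluster_result`: list with `points` (input plus
#'   `cluster_label`), `n_clusters`, `reachability` tibble (`order`,
#'   `reachability`, `cluster_label`) and `parameters`. Fewer points than
#'   `min_cluster_size` yields all noise.
#' @export
cluster_puncta <- function(points, min_cluster_size = 10, xi = 0.05,
                           min_samples = NULL, voxel_size_nm = NULL) {
  if (min_cluster_size < 2)
    abort("`min_cluster_size` must be >= 2.", class = "exmqc_validation_error")
  min_samples <- min_samples %||% min_cluster_size
  coord_cols <- intersect(c("z", "y", "x"), names(points))
  coords <- as.matrix(points[, coord_cols])
  if (any(!is.finite(coords)))
    abort("Point coordinates must be finite.", class = "exmqc_validation_error")
  n <- nrow(coords)
  if (!is.null(voxel_size_nm)) {
    v <- rep_len(voxel_size_nm, length(coord_cols))
    coords <- sweep(coords, 2, v, `*`)
  }
  labels <- rep(-1L, n)
  reach_tbl <- NULL
  n_clusters <- 0L
  if (n >= max(min_cluster_size, min_samples)) {
    oo <- optics_order(coords, min_samples)
    cl <- xi_clusters(oo$reachability, oo$predecessor, oo$ordering,
                      xi, min_samples, min_cluster_size)
    lab_ord <- rep(-1L, n)
    lab <- 0L
    for (cc in cl) {
      rng <- cc[1]:cc[2]
      if (all(lab_ord[rng] == -1L)) {
        lab <- lab + 1L
        lab_ord[rng] <- lab
      }
    }
    labels[oo$ordering] <- lab_ord
    n_clusters <- lab
    reach_tbl <- tibble::tibble(order = oo$ordering - 1L,
                                reachability = oo$reachability,
                                cluster_label = lab_ord)
  }
  pts <- tibble::as_tibble(points)
  pts$cluster_label <- labels
  structure(
    list(points = pts, n_clusters = n_clusters, reachability = reach_tbl,
         parameters = list(min_cluster_size = min_cluster_size,
                           min_samples = min_samples, xi = xi)),
    class = "cluster_result")
}

#' @export
print.cluster_result <- function(x, ...) {
  cat("<cluster_result> ", nrow(x$points), " puncta, ", x$n_clusters,
      " clusters, ", sum(x$points$cluster_label == -1L), " noise\n", sep = "")
  invisible(x)
}

#' Export a clustered point cloud
#'
#' Writes one row per punctum with 0-based pixel coordinates, physical
#' coordinates (nm, expanded scale) and cluster label (`-1` = noise /
#' unassigned, shown gray by downstream viewers). Round-trips losslessly
#' through [readr::read_csv()].
#'
#' @param result A `cluster_result` from [cluster_puncta()].
#' @param path Output CSV path.
#' @param voxel_size_nm Per-axis voxel size (nm) used for the physical
#'   columns.
#' @return `path`, invisibly.
#' @export
export_point_cloud <- function(result, path, voxel_size_nm = 100) {
  stopifnot(inherits(result, "cluster_result"))
  pts <- result$points
  coord_cols <- intersect(c("z", "y", "x"), names(pts))
  v <- rep_len(voxel_size_nm, length(coord_cols))
  out <- pts[, c(coord_cols, "cluster_label")]
  for (i in seq_along(coord_cols))
    out[[paste0(coord_cols[i], "_nm")]] <- pts[[coord_cols[i]]] * v[i]
  out <- out[, c(coord_cols, paste0(coord_cols, "_nm"), "cluster_label")]
  readr::write_csv(out, path)
  invisible(path)
}
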