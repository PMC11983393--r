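# Independent oracles used across the suite. These deliberately avoid the
# package's internal code paths: direct loops, sorting, dense grids.

options(exmqc.verbose = FALSE)

# dense 2D Gaussian kernel (same truncation as a 4-sigma kernel)
oracle_gauss_kernel2d <- function(sigma, radius = ceiling(4 * sigma)) {
  x <- seq(-radius, radius)
  k1 <- exp(-x^2 / (2 * sigma^2))
  k <- outer(k1, k1)
  k / sum(k)
}

# brute-force percentile with linear interpolation between order statistics
oracle_percentile <- function(x, p) {
  s <- sort(x)
  h <- (length(s) - 1) * p + 1
  lo <- floor(h); hi <- ceiling(h)
  s[lo] + (h - lo) * (s[hi] - s[lo])
}

# exhaustive all-pairs measurement-error curve on a small mask
oracle_exhaustive_curve <- function(field_px, mask, um_per_px, bin_width_um) {
  idx <- which(mask)
  ny <- nrow(mask)
  yy <- (idx - 1) %% ny; xx <- (idx - 1) %/% ny
  dy <- field_px[, , 1][idx]; dx <- field_px[, , 2][idx]
  n <- length(idx)
  pairs <- utils::combn(n, 2)
  i <- pairs[1, ]; j <- pairs[2, ]
  L <- sqrt((yy[i] - yy[j])^2 + (xx[i] - xx[j])^2) * um_per_px
  e <- sqrt((dy[i] - dy[j])^2 + (dx[i] - dx[j])^2) * um_per_px
  bin <- floor(L / bin_width_um)
  out <- do.call(rbind, lapply(sort(unique(bin)), function(b) {
    sel <- bin == b
    data.frame(bin_center_um = (b + 0.5) * bin_width_um,
               mean_err_um = mean(e[sel]),
               rms_err_um = sqrt(mean(e[sel]^2)),
               n_pairs = sum(sel))
  }))
  out
}

# dense grid search minimizing the same least-squares objective as the
# Gaussian fit (iso 2D, no offset), refined around the best coarse node
oracle_grid_fit_iso2d <- function(sub, sigma_range, n_grid = 24) {
  w <- nrow(sub)
  g <- as.matrix(expand.grid(seq(0, w - 1), seq(0, w - 1)))
  yv <- as.vector(sub)
  best <- NULL
  sweep_once <- function(sig_seq, cy_seq, cx_seq) {
    for (sig in sig_seq) for (cy in cy_seq) for (cx in cx_seq) {
      m <- exp(-((g[, 1] - cy)^2 + (g[, 2] - cx)^2) / (2 * sig^2))
      a <- sum(m * yv) / sum(m * m)  # optimal amplitude in closed form
      ss <- sum((a * m - yv)^2)
      if (is.null(best) || ss < best$ss)
        best <<- list(ss = ss, sigma = sig, cy = cy, cx = cx, amplitude = a)
    }
  }
  ctr <- (w - 1) / 2
  sweep_once(seq(sigma_range[1], sigma_range[2], length.out = n_grid),
             seq(ctr - 2, ctr + 2, length.out = n_grid),
             seq(ctr - 2, ctr + 2, length.out = n_grid))
  for (halving in 1:4) {
    span_s <- diff(sigma_range) / n_grid * 2^(1 - halving)
    span_c <- 4 / n_grid * 2^(1 - halving)
    sweep_once(seq(best$sigma - span_s, best$sigma + span_s, length.out = 9),
               seq(best$cy - span_c, best$cy + span_c, length.out = 9),
               seq(best$cx - span_c, best$cx + span_c, length.out = 9))
  }
  best
}

# coarse-to-fine grid search over (scale, angle) for the 2D similarity
# objective, translation solved in closed form for each node
oracle_grid_similarity2d <- function(pre, post, scale_range, angle_range_deg) {
  obj <- function(s, th) {
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2, byrow = TRUE)
    M <- s * pre %*% t(R)
    t0 <- colMeans(post) - colMeans(M)
    sum((post - sweep(M, 2, t0, `+`))^2)
  }
  ss <- seq(scale_range[1], scale_range[2], length.out = 41)
  aa <- seq(angle_range_deg[1], angle_range_deg[2], length.out = 41) * pi / 180
  best <- list(ss = Inf)
  for (s in ss) for (th in aa) {
    v <- obj(s, th)
    if (v < best$ss) best <- list(ss = v, scale = s, theta = th)
  }
  for (halving in 1:6) {
    ds <- diff(scale_range) / 40 * 2^(1 - halving)
    da <- diff(angle_range_deg) / 40 * 2^(1 - halving) * pi / 180
    for (s in seq(best$scale - ds, best$scale + ds, length.out = 9))
      for (th in seq(best$theta - da, best$theta + da, length.out = 9)) {
        v <- obj(s, th)
        if (v < best$ss) best <- list(ss = v, scale = s, theta = th)
      }
  }
  best
}

# single-linkage connected components at a distance threshold; the oracle
# for planted-cluster recovery
oracle_single_linkage <- function(coords, h, min_size) {
  hc <- stats::hclust(stats::dist(coords), method = "single")
  comp <- stats::cutree(hc, h = h)
  sizes <- table(comp)
  lab <- ifelse(sizes[as.character(comp)] >= min_size, comp, -1L)
  as.integer(lab)
}

# noiseless rendered 2D image of a single filament-free Gaussian spot
oracle_render_spot2d <- function(w, cy, cx, sigma, amplitude) {
  g <- outer(seq(0, w - 1), seq(0, w - 1), function(y, x)
    exp(-((y - cy)^2 + (x - cx)^2) / (2 * sigma^2)))
  amplitude * g
}
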