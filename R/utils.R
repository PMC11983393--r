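# Internal numeric helpers shared across modules: separable Gaussian
# filtering for 2D/3D arrays and bilinear/trilinear interpolation.
# Edge handling is replicate ("nearest") padding throughout, the common
# convention of image-processing toolkits.

gaussian_kernel_1d <- function(sigma, radius = NULL) {
  if (sigma < 0) abort("`sigma` must be >= 0.", class = "exmqc_validation_error")
  if (sigma == 0) return(1)
  if (is.null(radius)) radius <- max(1L, ceiling(4 * sigma))
  x <- seq(-radius, radius)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

# Convolve along one margin of a 2D/3D array with replicate padding.
convolve_axis <- function(x, kernel, axis) {
  radius <- (length(kernel) - 1L) / 2L
  if (radius == 0) return(x * kernel)
  d <- dim(x)
  n <- d[axis]
  # index vector with replicate padding for each kernel tap
  out <- array(0, d)
  for (j in seq_along(kernel)) {
    off <- j - 1L - radius
    idx <- pmin(pmax(seq_len(n) + off, 1L), n)
    shifted <- switch(as.character(length(d)),
      "2" = if (axis == 1L) x[idx, , drop = FALSE] else x[, idx, drop = FALSE],
      "3" = switch(axis, x[idx, , , drop = FALSE], x[, idx, , drop = FALSE],
                   x[, , idx, drop = FALSE]),
      abort("convolve_axis supports 2D/3D arrays only.")
    )
    out <- out + kernel[j] * shifted
  }
  out
}

# Separable Gaussian blur of a 2D matrix or 3D array. `sigma` is recycled
# per axis. sigma = 0 returns the input unchanged.
gaussian_blur <- function(x, sigma) {
  d <- dim(x)
  nd <- length(d)
  sigma <- rep_len(sigma, nd)
  for (axis in seq_len(nd)) {
    if (sigma[axis] > 0) {
      k <- gaussian_kernel_1d(sigma[axis], radius = min(ceiling(4 * sigma[axis]), d[axis] - 1L))
      x <- convolve_axis(x, k, axis)
    }
  }
  x
}

# Bilinear sampling of matrix `img` at fractional 1-based (y, x) positions.
# Out-of-bounds positions return `fill`.
interp_bilinear <- function(img, y, x, fill = 0) {
  ny <- nrow(img); nx <- ncol(img)
  y0 <- floor(y); x0 <- floor(x)
  fy <- y - y0; fx <- x - x0
  inside <- y >= 1 & y <= ny & x >= 1 & x <= nx
  y0c <- pmin(pmax(y0, 1), ny); y1c <- pmin(y0c + 1, ny)
  x0c <- pmin(pmax(x0, 1), nx); x1c <- pmin(x0c + 1, nx)
  v00 <- img[cbind(y0c, x0c)]; v01 <- img[cbind(y0c, x1c)]
  v10 <- img[cbind(y1c, x0c)]; v11 <- img[cbind(y1c, x1c)]
  v <- (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
  v[!inside] <- fill
  v
}

# Trilinear sampling of 3D array at fractional 1-based (z, y, x) positions.
interp_trilinear <- function(vol, z, y, x, fill = 0) {
  d <- dim(vol)
  z0 <- floor(z); y0 <- floor(y); x0 <- floor(x)
  fz <- z - z0; fy <- y - y0; fx <- x - x0
  inside <- z >= 1 & z <= d[1] & y >= 1 & y <= d[2] & x >= 1 & x <= d[3]
  c0 <- function(i, n) pmin(pmax(i, 1), n)
  z0c <- c0(z0, d[1]); z1c <- pmin(z0c + 1, d[1])
  y0c <- c0(y0, d[2]); y1c <- pmin(y0c + 1, d[2])
  x0c <- c0(x0, d[3]); x1c <- pmin(x0c + 1, d[3])
  g <- function(zi, yi, xi) vol[cbind(zi, yi, xi)]
  v <-
    (1 - fz) * ((1 - fy) * ((1 - fx) * g(z0c, y0c, x0c) + fx * g(z0c, y0c, x1c)) +
                  fy * ((1 - fx) * g(z0c, y1c, x0c) + fx * g(z0c, y1c, x1c))) +
    fz * ((1 - fy) * ((1 - fx) * g(z1c, y0c, x0c) + fx * g(z1c, y0c, x1c)) +
            fy * ((1 - fx) * g(z1c, y1c, x0c) + fx * g(z1c, y1c, x1c)))
  v[!inside] <- fill
  v
}

# Deterministic seed scoping: run `expr` under a seed without disturbing the
# caller's RNG state.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(force(expr))
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
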