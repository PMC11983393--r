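# helpers for building small displacement fields in physical context:
# voxel 1000 nm and expansion factor 1 make 1 px == 1 um, so pixel-space
# constructions read directly in micrometres.
px_field <- function(fy, fx, voxel_nm = 1000, exf = 1) {
  f <- array(0, c(dim(fy), 2))
  f[, , 1] <- fy; f[, , 2] <- fx
  displacement_field(f, voxel_size_nm = voxel_nm, expansion_factor = exf)
}

textured_image <- function(n = 256, seed = 1, sigma = 4) {
  set.seed(seed)
  base <- matrix(0, n, n)
  pts <- cbind(sample(15:(n - 15), 350, TRUE), sample(15:(n - 15), 350, TRUE))
  base[pts] <- runif(350, 0.4, 1)
  exmqc:::gaussian_blur(base, sigma)
}

test_that("preprocessing removes constant background and clips negatives", {
  const <- image_volume(matrix(5, 64, 64), 100, expansion_factor = 4)
  pp <- preprocess_pair(const, const, sigma_bg = 10)
  expect_true(all(pp$pre$data == 0))
  expect_true(all(pp$post$data == 0))
  # clipping: any would-be negative value is exactly 0
  spot <- image_volume(matrix(0, 64, 64), 100, expansion_factor = 4)
  spot$data[32, 32] <- 100
  pp2 <- preprocess_pair(spot, spot, sigma_pre = 1, sigma_post = 1, sigma_bg = 8)
  expect_gte(min(pp2$pre$data), 0)
  expect_true(any(pp2$pre$data == 0))
  expect_error(preprocess_pair(const, const, sigma_pre = 0),
               class = "exmqc_validation_error")
})

test_that("single bright pixel preprocessing matches a dense convolution oracle", {
  img <- image_volume(matrix(0, 64, 64), 100, expansion_factor = 4)
  img$data[33, 33] <- 1000
  pp <- preprocess_pair(img, img, sigma_pre = 1.5, sigma_post = 1.5, sigma_bg = 20)
  # oracle: direct dense convolution for the smoothing step, evaluated away
  # from the borders where padding cannot matter
  k <- oracle_gauss_kernel2d(1.5, radius = 6)
  sm_oracle <- matrix(0, 64, 64)
  for (dy in -6:6) for (dx in -6:6)
    sm_oracle[33 + dy, 33 + dx] <- 1000 * k[7 + dy, 7 + dx]
  bg <- exmqc:::gaussian_blur(sm_oracle, 20)
  ref <- pmax(sm_oracle - bg, 0)
  inner <- 20:45
  expect_lt(max(abs(pp$pre$data[inner, inner] - ref[inner, inner])), 1e-6)
  # background is locally negligible: peak survives nearly unchanged
  expect_gt(max(pp$pre$data), 0.95 * max(sm_oracle))
})

test_that("foreground masking: OR combination, closing, failure on empty input", {
  a <- image_volume(matrix(0, 32, 32), 100, expansion_factor = 4)
  b <- image_volume(matrix(0, 32, 32), 100, expansion_factor = 4)
  expect_error(foreground_mask(a, b), class = "exmqc_empty_foreground_error")

  a$data[5:10, 5:10] <- 10
  b$data[20:26, 20:26] <- 10
  m_or <- foreground_mask(a, b, closing_radius = 0)
  m_pre <- foreground_mask(a, b, combine = "pre", closing_radius = 0)
  m_post <- foreground_mask(a, b, combine = "post", closing_radius = 0)
  expect_true(all(m_or$mask[m_pre$mask]))
  expect_true(all(m_or$mask[m_post$mask]))

  # closing removes a small interior hole
  c1 <- image_volume(matrix(0, 32, 32), 100, expansion_factor = 4)
  c1$data[10:20, 10:20] <- 10
  c1$data[15, 15] <- 0
  m <- foreground_mask(c1, c1, combine = "pre", closing_radius = 2)
  expect_true(m$mask[15, 15])
})

test_that("mask covers the rendered filament support", {
  pair <- make_expansion_pair(seed = 21, residual_rms_um = 0, poisson = FALSE)
  fit <- estimate_similarity(pair$landmarks, 300, 300)
  pre_al <- apply_similarity(pair$pre, fit, pair$post)
  pre_al$expansion_factor <- fit$scale
  post <- pair$post
  pp <- preprocess_pair(pre_al, post)
  m <- foreground_mask(pp$pre, pp$post)
  # support: post pixels within the rendered structure (bright in the
  # noiseless image)
  support <- pair$post$data > 0.25 * max(pair$post$data)
  expect_gte(mean(m$mask[support]), 0.95)
})

test_that("demons field vanishes for identical images", {
  img <- image_volume(textured_image(128, seed = 2), 100, expansion_factor = 4)
  fld <- estimate_displacement_field(img, img)
  expect_lt(max(abs(fld$field)), 0.05)
})

test_that("demons recovers a planted global translation", {
  base <- textured_image(256, seed = 3)
  shifted <- matrix(0, 256, 256)
  shifted[3:256, ] <- base[1:254, ]  # structure moved +2 px in y
  mv <- image_volume(base, 100, expansion_factor = 4)
  fx <- image_volume(shifted, 100, expansion_factor = 4)
  fld <- estimate_displacement_field(mv, fx)
  fg <- base > 0.1 * max(base)
  expect_lt(abs(mean(fld$field[, , 1][fg]) - 2), 0.2)
  expect_lt(abs(mean(fld$field[, , 2][fg])), 0.2)
})

test_that("demons recovers a planted smooth warp", {
  n <- 256
  fld_t <- make_residual_field(c(n, n), 1, 30, seed = 31, voxel_size_nm = 1000,
                               expansion_factor = 1, calibration_length_um = 60)
  # rescale so the absolute per-component amplitude is ~3 px
  f <- fld_t$field * (3 / max(sd(fld_t$field[, , 1]), sd(fld_t$field[, , 2])))
  set.seed(32)
  pts <- cbind(runif(400, 15, n - 15), runif(400, 15, n - 15))
  render <- function(p) {
    img <- matrix(0, n, n)
    ij <- round(p)
    ok <- ij[, 1] >= 1 & ij[, 1] <= n & ij[, 2] >= 1 & ij[, 2] <= n
    img[ij[ok, , drop = FALSE]] <- 1
    exmqc:::gaussian_blur(img, 4)
  }
  moving <- render(pts)
  disp <- cbind(exmqc:::interp_bilinear(f[, , 1], pts[, 1], pts[, 2]),
                exmqc:::interp_bilinear(f[, , 2], pts[, 1], pts[, 2]))
  fixed <- render(pts + disp)
  rec <- estimate_displacement_field(
    image_volume(moving, 100, expansion_factor = 4),
    image_volume(fixed, 100, expansion_factor = 4))
  # the recovered field lives on the fixed grid: at a displaced structure
  # position it should report that structure's planted displacement
  q <- pts + disp
  rdy <- exmqc:::interp_bilinear(rec$field[, , 1], q[, 1], q[, 2])
  rdx <- exmqc:::interp_bilinear(rec$field[, , 2], q[, 1], q[, 2])
  epe <- sqrt((rdy - disp[, 1])^2 + (rdx - disp[, 2])^2)
  expect_lt(median(epe), 0.5)
})

test_that("measurement error curve: zero and constant fields give zero error", {
  m <- matrix(TRUE, 12, 12)
  zero <- px_field(matrix(0, 12, 12), matrix(0, 12, 12))
  cv <- measurement_error_curve(zero, m, n_pairs = 5000, bin_width_um = 2,
                                seed = 1, min_pairs_per_bin = 1,
                                max_length_quantile = 1)
  expect_true(all(cv$mean_err_um == 0))
  expect_true(all(cv$sd_err_um == 0))
  const <- px_field(matrix(1.7, 12, 12), matrix(-0.4, 12, 12))
  cv2 <- measurement_error_curve(const, m, n_pairs = 5000, bin_width_um = 2,
                                 seed = 1, min_pairs_per_bin = 1,
                                 max_length_quantile = 1)
  expect_true(all(cv2$mean_err_um == 0))
})

test_that("linear field gives errors exactly proportional to length", {
  n <- 40
  yy <- matrix(0:(n - 1), n, n); xx <- t(yy)
  lin <- px_field(0.03 * yy, 0.03 * xx)
  m <- matrix(TRUE, n, n)
  cv <- measurement_error_curve(lin, m, n_pairs = 50000, bin_width_um = 5,
                                seed = 2, min_pairs_per_bin = 1,
                                max_length_quantile = 1)
  expect_lt(max(abs(cv$mean_err_um - 0.03 * cv$mean_len_um) /
                  (0.03 * cv$mean_len_um)), 1e-9)
  # per-pair identity err = 0.03 * L means the SD reflects within-bin
  # length spread only
  expect_true(all(cv$sd_err_um <= 0.03 * 5))
})

test_that("sampled curve converges to the exhaustive all-pairs curve", {
  set.seed(5)
  f <- array(rnorm(12 * 12 * 2), c(12, 12, 2))
  fld <- px_field(f[, , 1], f[, , 2])
  m <- matrix(TRUE, 12, 12)
  sampled <- measurement_error_curve(fld, m, n_pairs = 1e6, bin_width_um = 4,
                                     seed = 3, min_pairs_per_bin = 1,
                                     max_length_quantile = 1)
  exact <- oracle_exhaustive_curve(f, m, um_per_px = 1, bin_width_um = 4)
  merged <- merge(as.data.frame(sampled), exact, by = "bin_center_um",
                  suffixes = c("_s", "_e"))
  expect_equal(nrow(merged), nrow(exact))
  expect_lt(max(abs(merged$mean_err_um_s - merged$mean_err_um_e) /
                  merged$mean_err_um_e), 0.01)
  expect_lt(max(abs(merged$rms_err_um_s - merged$rms_err_um_e) /
                  merged$rms_err_um_e), 0.01)
})

test_that("adding a constant vector to the field leaves the curve unchanged", {
  set.seed(6)
  f <- array(rnorm(20 * 20 * 2), c(20, 20, 2))
  m <- matrix(TRUE, 20, 20)
  cv1 <- measurement_error_curve(px_field(f[, , 1], f[, , 2]), m,
                                 n_pairs = 20000, bin_width_um = 4, seed = 7,
                                 min_pairs_per_bin = 1, max_length_quantile = 1)
  cv2 <- measurement_error_curve(px_field(f[, , 1] + 5.3, f[, , 2] - 2.1), m,
                                 n_pairs = 20000, bin_width_um = 4, seed = 7,
                                 min_pairs_per_bin = 1, max_length_quantile = 1)
  expect_equal(as.data.frame(cv1), as.data.frame(cv2))
})

test_that("doubling the expansion factor halves all pre-scale lengths and errors", {
  set.seed(8)
  f <- array(rnorm(24 * 24 * 2), c(24, 24, 2))
  m <- matrix(TRUE, 24, 24)
  cv4 <- measurement_error_curve(px_field(f[, , 1], f[, , 2], 1000, 4), m,
                                 n_pairs = 20000, bin_width_um = 1, seed = 9,
                                 min_pairs_per_bin = 1, max_length_quantile = 1)
  cv8 <- measurement_error_curve(px_field(f[, , 1], f[, , 2], 1000, 8), m,
                                 n_pairs = 20000, bin_width_um = 0.5, seed = 9,
                                 min_pairs_per_bin = 1, max_length_quantile = 1)
  expect_equal(cv8$bin_center_um, cv4$bin_center_um / 2)
  expect_equal(cv8$mean_err_um, cv4$mean_err_um / 2)
  expect_equal(cv8$rms_err_um, cv4$rms_err_um / 2)
  expect_equal(cv8$n_pairs, cv4$n_pairs)
})

test_that("pooling curves across specimens takes the weighted RMS", {
  mk <- function(rms, n) {
    df <- tibble::tibble(bin_center_um = c(0.5, 1.5),
                         mean_err_um = rms * 0.9, sd_err_um = rms * 0.1,
                         rms_err_um = rep(rms, 2), mean_len_um = c(0.5, 1.5),
                         n_pairs = rep(n, 2))
    exmqc:::new_distortion_curve(df, bin_width_um = 1)
  }
  one <- rms_across_samples(list(mk(3, 100)))
  expect_equal(one$rms_err_um, c(3, 3))
  pooled <- rms_across_samples(list(mk(3, 100), mk(4, 100)))
  expect_equal(pooled$rms_err_um, rep(sqrt((9 + 16) / 2), 2), tolerance = 1e-12)
  expect_equal(pooled$n_pairs, c(200, 200))
  # inconsistent binning is rejected
  bad <- mk(3, 100); attr(bad, "bin_width_um") <- 2
  expect_error(rms_across_samples(list(mk(3, 100), bad)),
               class = "exmqc_validation_error")
})

test_that("curve sampling validates its inputs", {
  m <- matrix(TRUE, 8, 8)
  fld <- px_field(matrix(0, 8, 8), matrix(0, 8, 8))
  expect_error(measurement_error_curve(fld, m, n_pairs = 0),
               class = "exmqc_validation_error")
  expect_error(measurement_error_curve(fld, matrix(FALSE, 8, 8)),
               class = "exmqc_empty_foreground_error")
  expect_error(measurement_error_curve(fld, matrix(TRUE, 9, 9)),
               class = "exmqc_validation_error")
})
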