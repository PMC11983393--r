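test_that("percentile normalization matches a sort-based oracle and validates", {
  const <- image_volume(matrix(10, 16, 16), 30, expansion_factor = 3.9)
  expect_true(all(normalize_image(const)$data == 1))
  zero <- image_volume(matrix(0, 16, 16), 30)
  expect_error(normalize_image(zero), class = "exmqc_validation_error")
  set.seed(1)
  raw <- array(sample(0:65535, 20 * 20 * 10, TRUE), c(10, 20, 20))
  vol <- image_volume(raw, 100, expansion_factor = 3.9)
  p <- oracle_percentile(as.vector(raw), 0.999)
  expect_equal(normalize_image(vol)$data, raw / p)
})

test_that("local maxima detection finds planted spots and ignores flat images", {
  one <- make_puncta_volume(shape = c(64, 64), n_puncta = 1,
                            sigma_range = c(2, 2), amplitude_range = c(100, 100),
                            background = 0, poisson = FALSE, seed = 2)
  cand <- detect_local_maxima(normalize_image(one$vol), sigma_smooth = 2,
                              min_rel_brightness = 0.25)
  expect_equal(nrow(cand), 1)
  expect_lt(sqrt((cand$y - one$truth$y)^2 + (cand$x - one$truth$x)^2), 1)

  flat <- image_volume(matrix(5, 32, 32), 30, expansion_factor = 3.9)
  expect_equal(nrow(detect_local_maxima(normalize_image(flat), 0, 0.25)), 0)
})

test_that("of two nearby maxima the brighter one is kept", {
  vol <- image_volume(array(0, c(9, 9, 9)), 100, expansion_factor = 3.9)
  vol$data[5, 5, 3] <- 0.10 * 100
  vol$data[5, 5, 5] <- 0.12 * 100
  # separation 2: both are legitimate maxima and survive
  both <- detect_local_maxima(normalize_image(vol), sigma_smooth = 0,
                              min_rel_brightness = 0.1, min_separation_px = 2)
  expect_equal(nrow(both), 2)
  # tighter separation: only the brighter of the pair remains
  kept <- detect_local_maxima(normalize_image(vol), sigma_smooth = 0,
                              min_rel_brightness = 0.1, min_separation_px = 3)
  expect_equal(nrow(kept), 1)
  expect_equal(c(kept$z, kept$y, kept$x), c(4, 4, 4))  # 0-based, brighter voxel
})

test_that("a planted 50-spot field is detected 1:1 against the truth table", {
  pv <- make_puncta_volume(shape = c(256, 256), n_puncta = 50,
                           sigma_range = c(1.5, 2.5), amplitude_range = c(80, 150),
                           min_separation_px = 12, background = 1,
                           poisson = TRUE, seed = 3)
  cand <- detect_local_maxima(normalize_image(pv$vol), sigma_smooth = 2,
                              min_rel_brightness = 0.10)
  expect_equal(nrow(cand), 50)
  # greedy 1:1 matching within 2 px
  used <- rep(FALSE, 50)
  for (i in seq_len(nrow(cand))) {
    d <- sqrt((pv$truth$y - cand$y[i])^2 + (pv$truth$x - cand$x[i])^2)
    j <- which.min(ifelse(used, Inf, d))
    expect_lt(d[j], 2)
    used[j] <- TRUE
  }
  expect_true(all(used))
})

test_that("isolation keeps exactly the mutually distant candidates", {
  two_close <- tibble::tibble(y = c(0, 25), x = c(0, 0))
  expect_equal(nrow(select_isolated(two_close, 30)), 0)
  two_far <- tibble::tibble(y = c(0, 31), x = c(0, 0))
  expect_equal(nrow(select_isolated(two_far, 30)), 2)
  # collinear A, B, C with A-B = 40, B-C = 20, A-C = 60: B and C exclude
  # each other, only A survives
  cand <- tibble::tibble(y = c(0, 40, 60), x = c(0, 0, 0))
  kept <- select_isolated(cand, 30)
  expect_equal(nrow(kept), 1)
  expect_equal(c(kept$y, kept$x), c(0, 0))
})

test_that("noiseless Gaussian fits recover the planted parameters", {
  sub <- oracle_render_spot2d(41, 20.3, 19.6, 2.0, 1)
  vol <- image_volume(sub, 30, expansion_factor = 3.9)
  fit <- fit_gaussian(vol, c(20, 20), window_px = 41, model = "iso2d",
                      sigma_init = 3.3)
  expect_true(fit$converged)
  expect_lt(abs(fit$sigma_y_px - 2), 1e-6)
  expect_lt(abs(fit$y - 20.3), 1e-6)
  expect_lt(abs(fit$x - 19.6), 1e-6)
  expect_lt(abs(fit$amplitude - 1), 1e-6)

  # anisotropic 3D: all three sigmas recovered
  w <- 21; ctr <- c(10.2, 9.8, 10.5); sig <- c(1.5, 1.5, 3.0)
  g <- array(0, c(w, w, w))
  for (z in 1:w) for (y in 1:w) for (x in 1:w)
    g[z, y, x] <- exp(-((z - 1 - ctr[1])^2 / (2 * sig[1]^2) +
                          (y - 1 - ctr[2])^2 / (2 * sig[2]^2) +
                          (x - 1 - ctr[3])^2 / (2 * sig[3]^2)))
  vol3 <- image_volume(g, 100, expansion_factor = 3.9)
  fit3 <- fit_gaussian(vol3, c(10, 10, 10), window_px = 21, model = "aniso3d",
                       sigma_init = 1.5)
  expect_true(fit3$converged)
  expect_lt(abs(fit3$sigma_z_px - 1.5), 1e-6)
  expect_lt(abs(fit3$sigma_y_px - 1.5), 1e-6)
  expect_lt(abs(fit3$sigma_x_px - 3.0), 1e-6)
})

test_that("fits under Poisson noise stay near truth and match a grid-search oracle", {
  set.seed(4)
  sighats <- vapply(1:50, function(i) {
    spot <- oracle_render_spot2d(41, 20, 20, 1.8, 100)
    noisy <- matrix(rpois(41 * 41, spot + 1), 41, 41)
    vol <- image_volume(noisy / max(noisy), 30, expansion_factor = 3.9)
    fit_gaussian(vol, c(20, 20), 41, "iso2d", sigma_init = 3.3)$sigma_y_px
  }, numeric(1))
  expect_lt(abs(median(sighats) - 1.8) / 1.8, 0.05)

  # one instance against the dense grid-search minimizer of the same objective
  set.seed(5)
  spot <- oracle_render_spot2d(41, 20.4, 19.7, 1.8, 100)
  noisy <- matrix(rpois(41 * 41, spot + 1), 41, 41) / 100
  vol <- image_volume(noisy, 30, expansion_factor = 3.9)
  fit <- fit_gaussian(vol, c(20, 20), 41, "iso2d", sigma_init = 3.3)
  gs <- oracle_grid_fit_iso2d(noisy, c(1, 3))
  expect_equal(signif(fit$sigma_y_px, 3), signif(gs$sigma, 3))
  expect_equal(signif(fit$amplitude, 3), signif(gs$amplitude, 3))
})

test_that("sigma-to-FWHM conversion applies the Gaussian constant and exF", {
  expect_equal(round(fwhm_factor(), 3), 2.355)
  one <- sigma_to_fwhm(1, 1, 1)
  expect_equal(one$fwhm_expanded_nm, 2 * sqrt(2 * log(2)))
  expect_equal(sigma_to_fwhm(0, 30, 3.9)$fwhm_expanded_nm, 0)
  conv <- sigma_to_fwhm(2, 30, 3.9)
  expect_equal(conv$fwhm_expanded_nm, 2 * sqrt(2 * log(2)) * 2 * 30)
  expect_equal(conv$fwhm_expanded_nm, 141.29, tolerance = 1e-4)
  expect_equal(conv$fwhm_native_nm, 36.23, tolerance = 1e-3)
  expect_error(sigma_to_fwhm(-1, 30, 3.9), class = "exmqc_validation_error")
  expect_error(sigma_to_fwhm(1, 0, 3.9), class = "exmqc_validation_error")
})

test_that("QC rules pass clean fits and name the failure reason otherwise", {
  mk_row <- function(sigma, off = 0, resid = 0.1, conv = TRUE, amp = 1) {
    tibble::tibble(y = 20 + off, x = 20, sigma_y_px = sigma, sigma_x_px = sigma,
                   amplitude = amp, converged = conv,
                   relative_residual = resid, n_iterations = 10L,
                   cand_y = 20, cand_x = 20)
  }
  ok <- qc_filter(mk_row(3), window_px = 41)
  expect_true(ok$qc_pass)
  big <- qc_filter(mk_row(15), window_px = 41)
  expect_false(big$qc_pass)
  expect_equal(big$reject_reason, "sigma_bounds")
  off <- qc_filter(mk_row(3, off = 10), window_px = 41)
  expect_equal(off$reject_reason, "center_offset")
  bad <- qc_filter(mk_row(3, resid = 0.8), window_px = 41)
  expect_equal(bad$reject_reason, "residual")
  nc <- qc_filter(mk_row(3, conv = FALSE), window_px = 41)
  expect_equal(nc$reject_reason, "not_converged")
})

test_that("an overlapping spot pair is rejected by the residual rule", {
  # two spots 8 px apart inside one fit window: the single-Gaussian model
  # cannot absorb the second peak
  sub <- oracle_render_spot2d(41, 20, 16, 2, 1) + oracle_render_spot2d(41, 20, 24, 2, 1)
  vol <- image_volume(sub, 30, expansion_factor = 3.9)
  fit <- fit_gaussian(vol, c(20, 20), 41, "iso2d", sigma_init = 2)
  fit <- qc_filter(fit, window_px = 41, r_max = 0.3)
  expect_false(fit$qc_pass)

  clean <- oracle_render_spot2d(41, 20, 20, 2, 1)
  cfit <- qc_filter(fit_gaussian(image_volume(clean, 30, expansion_factor = 3.9),
                                 c(20, 20), 41, "iso2d", 2), window_px = 41,
                    r_max = 0.3)
  expect_true(cfit$qc_pass)
})

test_that("summaries use linear-interpolation quantiles over passing puncta", {
  p <- tibble::tibble(fwhm_native_nm = c(1, 2, 3), qc_pass = TRUE)
  s <- summarize_puncta(p)
  expect_equal(s$median_nm, 2)
  expect_equal(s$n, 3)

  set.seed(6)
  vals <- rlnorm(74, log(52), 0.25)
  p2 <- tibble::tibble(fwhm_native_nm = vals, qc_pass = TRUE)
  s2 <- summarize_puncta(p2)
  expect_equal(s2$median_nm, oracle_percentile(vals, 0.5))
  expect_equal(s2$q25_nm, oracle_percentile(vals, 0.25))
  expect_equal(s2$q75_nm, oracle_percentile(vals, 0.75))
  expect_true(s2$q25_nm <= s2$median_nm && s2$median_nm <= s2$q75_nm)

  expect_error(summarize_puncta(tibble::tibble(fwhm_native_nm = numeric(0))),
               class = "exmqc_validation_error")
})

test_that("the punctum pipeline is deterministic and intensity-scale invariant", {
  pv <- make_puncta_volume(shape = c(256, 256), n_puncta = 20,
                           sigma_range = c(1.5, 2.5), amplitude_range = c(80, 150),
                           min_separation_px = 35, background = 1,
                           voxel_size_nm = 30, expansion_factor = 3.9, seed = 7)
  r1 <- puncta_pipeline(pv$vol, mode = "2d")
  r2 <- puncta_pipeline(pv$vol, mode = "2d")
  expect_identical(r1$puncta, r2$puncta)

  scaled <- pv$vol
  scaled$data <- scaled$data * 7.3
  r3 <- puncta_pipeline(scaled, mode = "2d")
  expect_equal(r3$puncta$sigma_y_px, r1$puncta$sigma_y_px, tolerance = 1e-8)
  expect_equal(r3$puncta$fwhm_native_nm, r1$puncta$fwhm_native_nm,
               tolerance = 1e-8)
  expect_equal(nrow(r3$puncta), nrow(r1$puncta))

  # native-scale identity holds row by row
  expect_equal(r1$puncta$fwhm_native_nm * 3.9, r1$puncta$fwhm_expanded_nm)
})

test_that("physical-unit parameterization converts thresholds via the voxel size", {
  pv <- make_puncta_volume(shape = c(128, 128), n_puncta = 5,
                           sigma_range = c(2, 2), amplitude_range = c(100, 100),
                           min_separation_px = 40, background = 0,
                           poisson = FALSE, voxel_size_nm = 30,
                           expansion_factor = 3.9, seed = 8)
  # 99 nm at 30 nm pixels is the default 3.3 px smoothing
  r_nm <- puncta_pipeline(pv$vol, mode = "2d", sigma_smooth_nm = 99,
                          isolation_nm = 900)
  expect_equal(r_nm$params$sigma_smooth_px, 3.3)
  expect_equal(r_nm$params$isolation_px, 30)
  r_px <- puncta_pipeline(pv$vol, mode = "2d")
  expect_identical(r_nm$puncta, r_px$puncta)
})

test_that("edge candidates are skipped, not padded", {
  img <- oracle_render_spot2d(64, 5, 5, 2, 1) + oracle_render_spot2d(64, 32, 32, 2, 1)
  vol <- image_volume(img, 30, expansion_factor = 3.9)
  cand <- tibble::tibble(y = c(5, 32), x = c(5, 32), brightness = c(1, 1))
  fits <- fit_puncta(vol, cand, window_px = 41, model = "iso2d", sigma_init = 2)
  expect_equal(nrow(fits), 1)
  expect_equal(attr(fits, "n_edge_skipped"), 1L)
})
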