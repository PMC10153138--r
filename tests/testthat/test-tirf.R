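test_that("rolling-ball subtraction flattens backgrounds, keeps thin structures", {
  flat <- image2d(matrix(8, 24, 24), 0.143)
  out <- subtract_background(flat, 5)
  expect_equal(max(abs(out$pixels)), 0)

  # impulse on flat background: preserved within 5% (opening oracle)
  img <- image2d(matrix(5, 30, 30), 0.143)
  img$pixels[15, 15] <- 105
  sub <- subtract_background(img, 5)
  expect_gt(sub$pixels[15, 15], 0.95 * 100)
  # oracle: opening = min-then-max over the disc; the impulse cannot survive
  # an erosion with a radius-5 disc, so the background there is the flat level
  disc_min <- min(img$pixels)  # erosion at the impulse
  expect_equal(sub$pixels[15, 15], 105 - disc_min)

  # filament on a smooth gradient: residual background RMS well below peak
  nr <- 60
  grad <- outer(seq_len(nr), seq_len(nr), function(r, c) 10 + 0.2 * r + 0.1 * c)
  fil <- grad
  fil[, 30:31] <- fil[, 30:31] + 100
  sub2 <- subtract_background(image2d(fil, 0.143), 5)
  bgmask <- matrix(TRUE, nr, nr); bgmask[, 24:37] <- FALSE
  bg_inner <- sub2$pixels[7:(nr - 6), 7:(nr - 6)][bgmask[7:(nr - 6), 7:(nr - 6)]]
  expect_lt(sqrt(mean(bg_inner^2)), 0.1 * 100)

  expect_error(subtract_background(flat, 30), "exceeds")
})

test_that("profile extraction is exact bilinear sampling", {
  # image equal to its column index: horizontal segment gives a linear ramp
  m <- outer(rep(1, 20), seq_len(20))
  img <- image2d(m, 0.143)
  pr <- extract_profile(img, c(2, 10), c(18, 10), n_samples = 17)
  expect_equal(pr$intensities, seq(2, 18, length.out = 17))

  # constant row: constant profile
  m2 <- outer(seq_len(20), rep(1, 20))
  pr2 <- extract_profile(image2d(m2, 0.143), c(2, 7), c(18, 7), n_samples = 9)
  expect_equal(pr2$intensities, rep(7, 9))

  # arbitrary oblique segment against per-sample bilinear oracle
  set.seed(12)
  rmat <- matrix(runif(400), 20, 20)
  img3 <- image2d(rmat, 0.143)
  p0 <- c(2.3, 4.7); p1 <- c(17.2, 15.4); n <- 23
  pr3 <- extract_profile(img3, p0, p1, n)
  t <- seq(0, 1, length.out = n)
  want <- vapply(t, function(ti)
    oracle_bilinear(rmat, p0[1] + ti * (p1[1] - p0[1]),
                    p0[2] + ti * (p1[2] - p0[2])), numeric(1))
  expect_equal(pr3$intensities, want, tolerance = 1e-9)
  expect_equal(pr3$pixel_size_nm, 143)

  expect_error(extract_profile(img3, c(1, 1), c(1, 1)), "coincide")
  expect_error(extract_profile(img3, c(0, 1), c(5, 5)), "inside")
})

test_that("gaussian fits recover parameters and the FWHM identity", {
  x <- seq(-10, 10, by = 0.5)
  y <- 100 * exp(-x^2 / (2 * 2^2))
  fit <- fit_gaussian(line_profile(x, y))
  expect_equal(fit$amplitude, 100, tolerance = 1e-6)
  expect_equal(fit$sigma, 2, tolerance = 1e-6)
  expect_equal(fit$fwhm, 2 * sqrt(2 * log(2)) * 2, tolerance = 1e-6)
  expect_equal(fit$offset, 0, tolerance = 1e-6)

  # constant shift moves only the offset
  fit10 <- fit_gaussian(line_profile(x, y + 10))
  expect_equal(fit10$offset, 10, tolerance = 1e-6)
  expect_equal(fit10$amplitude, fit$amplitude, tolerance = 1e-6)
  expect_equal(fit10$sigma, fit$sigma, tolerance = 1e-6)

  expect_error(fit_gaussian(line_profile(x, rep(2, length(x)))), "flat")
  expect_error(fit_gaussian(line_profile(1:5, 1:5)), "short")

  # Monte-Carlo at SNR 10: median amplitude error below 5%
  set.seed(77)
  errs <- replicate(200, {
    yn <- y + rnorm(length(x), 0, 10)
    abs(fit_gaussian(line_profile(x, yn))$amplitude - 100) / 100
  })
  expect_lt(median(errs), 0.05)
})

test_that("bundle metrics scale with filament count in both modes", {
  x <- seq(-7, 7)
  mk <- function(count) fit_gaussian(line_profile(x, count * 100 *
                                                    exp(-x^2 / (2 * 1.5^2))))
  f1 <- mk(1); f3 <- mk(3)
  expect_equal(bundle_intensity_metric(f3, "amplitude") /
                 bundle_intensity_metric(f1, "amplitude"), 3, tolerance = 1e-6)
  expect_equal(bundle_intensity_metric(f3, "fwhm_mean") /
                 bundle_intensity_metric(f1, "fwhm_mean"), 3, tolerance = 1e-6)
  # fwhm_mean lies between half-max and peak
  expect_gt(bundle_intensity_metric(f1, "fwhm_mean"), 50)
  expect_lt(bundle_intensity_metric(f1, "fwhm_mean"), 100)

  # monotone in count on noiseless generator data
  sp <- tirf_field_spec(n_filaments = 4, n_bundles = 8,
                        filaments_per_bundle_mean = 3, noise_sd = 0, seed = 5)
  g <- generate_tirf_profiles(sp)
  m <- vapply(g$profiles, function(p) bundle_intensity_metric(fit_gaussian(p)),
              numeric(1))
  expect_equal(cor(m, g$true_counts, method = "spearman"), 1)
})

test_that("normalization to the control mean", {
  expect_equal(normalize_to_control(6, c(2, 4)), 2)
  ctrl <- c(3, 5, 7)
  expect_equal(mean(normalize_to_control(ctrl, ctrl)), 1)
  expect_error(normalize_to_control(1, numeric(0)), "empty")
  expect_error(normalize_to_control(1, c(-2, 2)), "positive")

  # affine equivariance: scaling the signal leaves normalized metrics unchanged
  x <- seq(-7, 7)
  y <- 10 + 100 * exp(-x^2 / (2 * 1.5^2))
  a1 <- fit_gaussian(line_profile(x, y))$amplitude
  a2 <- fit_gaussian(line_profile(x, 3 * y))$amplitude
  expect_equal(a2 / a1, 3, tolerance = 1e-6)
  expect_equal(normalize_to_control(a2, 3 * a1), normalize_to_control(a1, a1))

  # generator bundles of mean 3 filaments normalize to ~3 vs filament control
  sp <- tirf_field_spec(n_filaments = 40, n_bundles = 40,
                        filaments_per_bundle_mean = 3, noise_sd = 3, seed = 13)
  g <- generate_tirf_profiles(sp)
  m <- vapply(g$profiles, function(p) bundle_intensity_metric(fit_gaussian(p)),
              numeric(1))
  ctrl_idx <- g$true_counts == 1
  norm <- normalize_to_control(m[!ctrl_idx], m[ctrl_idx])
  se <- sd(norm / (g$true_counts[!ctrl_idx] / 1)) / sqrt(sum(!ctrl_idx))
  expect_lt(abs(mean(norm) - mean(g$true_counts[!ctrl_idx])), 3 * se + 0.05)
})
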