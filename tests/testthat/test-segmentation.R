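test_that("ridge enhancement behaves like a vesselness filter", {
  p <- segmentation_params()
  # constant image: zero Hessian, zero response
  flat <- image2d(matrix(3, 48, 48), 0.2)
  expect_equal(max(enhance_ridges(flat, p)$pixels), 0)

  # bright line ~2 px wide: on-line response at least 10x the response 5 px away
  m <- matrix(0, 48, 48)
  m[, 24:25] <- 1
  v <- enhance_ridges(image2d(m, 0.2), p)$pixels
  on_line <- max(v[24, 24:25])
  off_line <- max(v[24, c(19, 30)])
  expect_gte(on_line, 10 * off_line)
  expect_true(all(v >= 0 & v <= 1))

  # large bright disk: interior suppressed, boundary ring elevated
  yy <- row(matrix(0, 96, 96)) - 48.5; xx <- col(matrix(0, 96, 96)) - 48.5
  disk <- image2d((sqrt(yy^2 + xx^2) <= 35) * 1.0, 0.2)
  vd <- enhance_ridges(disk, p)$pixels
  interior <- vd[44:52, 44:52]
  ring <- vd[abs(sqrt(yy^2 + xx^2) - 35) < 1.5]
  expect_lt(max(interior), 0.05 * max(ring))

  expect_error(segmentation_params(frangi_scales_px = numeric(0)), "scales")
})

test_that("regional minima seeds agree with the exhaustive plateau oracle", {
  # two strict minima separated by a ridge
  m <- matrix(5, 9, 9)
  m[3, 3] <- 1; m[7, 7] <- 2
  s <- find_seeds(image2d(m, 0.2))
  expect_equal(s$n_seeds, 2)

  # constant image is a single plateau seed
  s1 <- find_seeds(image2d(matrix(4, 8, 8), 0.2))
  expect_equal(s1$n_seeds, 1)
  expect_true(all(s1$labels == 1L))

  # random integer images against the brute-force oracle
  for (seed in 1:8) {
    set.seed(seed)
    m <- matrix(sample(0:5, 144, TRUE), 12, 12)
    got <- find_seeds(image2d(m, 0.2))$labels
    want <- oracle_regional_minima(m)
    expect_identical(got > 0, want > 0)
    # same plateaus, same partition (labels assigned in the same scan order)
    expect_identical(got, want)
  }
})

test_that("marker watershed agrees with the plain-R flooding oracle", {
  for (seed in 1:10) {
    set.seed(seed)
    nr <- sample(6:16, 1); nc <- sample(6:16, 1)
    m <- matrix(sample(0:6, nr * nc, TRUE), nr, nc)
    seeds <- matrix(0L, nr, nc)
    k <- sample(2:4, 1)
    pos <- sample(nr * nc, k)
    seeds[pos] <- seq_len(k)
    got <- watershed_from_seeds(image2d(m, 0.2), seeds)$labels
    want <- oracle_watershed(m, seeds)
    expect_identical(got, want)
  }
  # continuous-valued surfaces (no ties) agree too
  for (seed in 11:13) {
    set.seed(seed)
    m <- matrix(runif(12 * 12), 12, 12)
    seeds <- matrix(0L, 12, 12); seeds[c(3, 140)] <- 1:2
    expect_identical(watershed_from_seeds(image2d(m, 0.2), seeds)$labels,
                     oracle_watershed(m, seeds))
  }
})

test_that("segmentation partitions the raster with one seed per region", {
  f <- generate_cap_field(cap_field_spec(n_caps = 25, field_size_px = c(176, 176),
                                         noise_sd = 0.05, seed = 4))
  img <- f$image
  p <- segmentation_params()
  lm <- segment_caps(img, p)
  lab <- lm$labels
  # partition: all pixels labelled or boundary
  expect_true(all(lab >= 0))
  # seed-region bijection: number of regions equals number of seeds
  ridge <- enhance_ridges(scale_intensity(img, p$intensity_scale), p)
  seeds <- find_seeds(blur(ridge, p$gauss_sigma_px), p)
  expect_equal(length(unique(lab[lab > 0])), seeds$n_seeds)
  # regions are connected (each positive label one connected component)
  for (k in sample(unique(lab[lab > 0]), 5)) {
    mask <- matrix(as.numeric(lab != k), nrow(lab), ncol(lab))
    comp <- syncap:::cpp_regional_minima(mask)  # plateaus of 0 = components
    expect_equal(length(unique(comp[lab == k])), 1)
  }
})

test_that("noiseless two-cap field is recovered with accurate areas", {
  spec <- cap_field_spec(field_size_px = c(96, 96), pixel_size_um = 0.35,
                         n_caps = 2, cap_area_mean_um2 = 150,
                         cap_area_sd_um2 = 20, noise_sd = 0, seed = 7)
  f <- generate_cap_field(spec)
  lm <- segment_caps(f$image)
  tab <- cap_table(lm)
  # keep regions overlapping the caps (a border sliver may also appear)
  mm <- match_caps(f$truth$table, tab, spec$pixel_size_um)
  expect_true(all(mm$matched))
  expect_true(all(mm$rel_area_err < 0.05))
})

test_that("degenerate constant input yields a single field-spanning region", {
  flat <- image2d(matrix(2, 64, 64), 0.35)
  lm <- segment_caps(flat)
  expect_equal(length(unique(lm$labels[lm$labels > 0])), 1)
  expect_true(mean(lm$labels > 0) > 0.99)
})

test_that("small regions merge into their largest neighbour when enabled", {
  f <- generate_cap_field(cap_field_spec(n_caps = 25, field_size_px = c(176, 176),
                                         noise_sd = 0.05, seed = 4))
  p0 <- segmentation_params()
  lm0 <- segment_caps(f$image, p0)
  a0 <- cap_table(lm0)$area_um2
  thr <- 30
  p1 <- segmentation_params(min_region_area_um2 = thr)
  lm1 <- segment_caps(f$image, p1)
  tab1 <- cap_table(lm1)
  if (any(a0 < thr)) expect_lt(nrow(tab1), length(a0))
  expect_true(all(tab1$area_um2 >= thr))
  ids <- sort(unique(lm1$labels[lm1$labels > 0]))
  expect_identical(ids, seq_along(ids))  # consecutive relabelling
})

test_that("accuracy does not degrade as noise shrinks to zero", {
  errs <- vapply(c(0.10, 0.05, 0), function(ns) {
    f <- generate_cap_field(cap_field_spec(n_caps = 49, field_size_px = c(224, 224),
                                           noise_sd = ns, seed = 21))
    mm <- match_caps(f$truth$table, cap_table(segment_caps(f$image)), 0.35)
    median(mm$rel_area_err[mm$matched])
  }, numeric(1))
  # non-increasing within a small numerical slop
  expect_true(all(diff(errs) <= 0.01))
  expect_lt(errs[3], 0.05)
})
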