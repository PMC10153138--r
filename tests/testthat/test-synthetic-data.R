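test_that("cap field spec enforces its invariants", {
  expect_error(cap_field_spec(ridge_intensity = 0.4), "ridge_intensity >")
  expect_error(cap_field_spec(small_cap_fraction = 1.2), "small_cap_fraction")
  expect_error(cap_field_spec(fallout_fraction = -0.1), "fallout_fraction")
  # area budget: caps must fit in the field
  expect_error(cap_field_spec(field_size_px = c(64, 64), n_caps = 100),
               "exceeds the field area")
})

test_that("generator is deterministic and ground truth matches the painting", {
  spec <- cap_field_spec(n_caps = 30, field_size_px = c(192, 192),
                         noise_sd = 0.05, seed = 123)
  a <- generate_cap_field(spec)
  b <- generate_cap_field(spec)
  expect_identical(a$image$pixels, b$image$pixels)
  expect_identical(a$truth$label_map$labels, b$truth$label_map$labels)
  expect_identical(a$truth$table, b$truth$table)

  # labels consecutive from 1; recorded areas equal the label map exactly
  lab <- a$truth$label_map$labels
  ids <- sort(unique(lab[lab > 0]))
  expect_identical(ids, seq_len(a$truth$n_caps))
  counts <- tabulate(lab[lab > 0], nbins = a$truth$n_caps)
  expect_equal(a$truth$table$area_um2, counts * spec$pixel_size_um^2)
})

test_that("noiseless two-cap field paints exactly what ground truth records", {
  spec <- cap_field_spec(field_size_px = c(64, 64), n_caps = 2,
                         cap_area_mean_um2 = 30, cap_area_sd_um2 = 5,
                         noise_sd = 0, seed = 5)
  f <- generate_cap_field(spec)
  expect_equal(f$truth$n_caps, 2)
  # noiseless: every labelled pixel is at interior or ridge intensity
  vals <- unique(f$image$pixels[f$truth$label_map$labels > 0])
  expect_true(all(vals %in% c(spec$interior_intensity, spec$ridge_intensity)))
  counts <- tabulate(f$truth$label_map$labels[f$truth$label_map$labels > 0], 2)
  expect_equal(f$truth$table$area_um2, counts * spec$pixel_size_um^2)
})

test_that("full fallout yields a uniform background field with no caps", {
  f <- generate_cap_field(cap_field_spec(n_caps = 10, fallout_fraction = 1,
                                         noise_sd = 0, seed = 2))
  expect_equal(f$truth$n_caps, 0)
  expect_equal(unique(as.vector(f$image$pixels)), 0.15)
})

test_that("bimodal specs produce bimodal recorded areas (KDE oracle)", {
  spec <- cap_field_spec(field_size_px = c(456, 456), n_caps = 200,
                         small_cap_fraction = 0.4, noise_sd = 0, seed = 11)
  f <- generate_cap_field(spec)
  a <- f$truth$table$area_um2
  expect_gte(oracle_kde_modes(a, bw = 12), 2)
  # and a unimodal spec is unimodal under the same oracle
  u <- generate_cap_field(cap_field_spec(n_caps = 100, noise_sd = 0, seed = 11))
  expect_equal(oracle_kde_modes(u$truth$table$area_um2, bw = 12), 1)
})

test_that("binding tables follow the Hill model exactly when noiseless", {
  # zero ligand leaves only nonspecific pelleting
  spec <- binding_sim_spec(noise_sd = 0, nonspecific_pellet_fraction = 0.08,
                           n_replicates = 2, seed = 3)
  ds <- generate_binding_table(spec)
  z <- ds[ds$actin_conc_um == 0, ]
  expect_equal(z$pellet_intensity / (z$pellet_intensity + z$supernatant_intensity),
               rep(0.08, 2))

  # at the dissociation constant the specific fraction is one half
  spec2 <- binding_sim_spec(true_kd_um = 0.45, concentrations_um = c(0, 0.45),
                            nonspecific_pellet_fraction = 0, noise_sd = 0,
                            n_replicates = 1)
  ds2 <- generate_binding_table(spec2)
  r <- ds2[ds2$actin_conc_um == 0.45, ]
  expect_equal(r$pellet_intensity / (r$pellet_intensity + r$supernatant_intensity),
               0.5)

  # direct scalar evaluation of the Hill formula as oracle
  spec3 <- binding_sim_spec(true_kd_um = 0.45, true_h = 2.9, true_plateau = 1,
                            nonspecific_pellet_fraction = 0, noise_sd = 0,
                            n_replicates = 1)
  ds3 <- generate_binding_table(spec3)
  a4 <- ds3[ds3$actin_conc_um == 4, ]
  expect_equal(a4$pellet_intensity / 1000, 4^2.9 / (0.45^2.9 + 4^2.9))

  expect_error(binding_sim_spec(concentrations_um = c(0.1, 1)), "include 0")
  expect_error(binding_sim_spec(noise_sd = 0.3), "noise_sd")
})

test_that("tirf profiles encode filament count linearly and recover under noise", {
  sp <- tirf_field_spec(n_filaments = 1, n_bundles = 1,
                        filaments_per_bundle_mean = 2, noise_sd = 0, seed = 1)
  g <- generate_tirf_profiles(sp)
  f1 <- fit_gaussian(g$profiles[[1]])
  expect_equal(f1$amplitude, 100, tolerance = 1e-6)
  expect_equal(f1$sigma, 1.5, tolerance = 1e-6)

  # amplitude ratio equals the count ratio by construction: a 3-filament
  # bundle profile vs a single filament, same PSF and background
  x <- seq(-7, 7)
  shape <- exp(-x^2 / (2 * 1.5^2))
  one <- fit_gaussian(line_profile(x, 10 + 100 * shape))
  three <- fit_gaussian(line_profile(x, 10 + 3 * 100 * shape))
  expect_equal(three$amplitude / one$amplitude, 3, tolerance = 1e-6)

  # Monte-Carlo: mean fitted amplitude within 2 SE of truth at 5% noise
  spn <- tirf_field_spec(n_filaments = 100, n_bundles = 0, noise_sd = 5, seed = 9)
  gn <- generate_tirf_profiles(spn)
  amps <- vapply(gn$profiles, function(p) fit_gaussian(p)$amplitude, numeric(1))
  se <- sd(amps) / sqrt(length(amps))
  expect_lt(abs(mean(amps) - 100), 2 * se + 1e-9)
})

test_that("point geometry hits requested angle and separation", {
  g0 <- generate_point_geometry(4, separation_um = 5, angle_deg = 180,
                                jitter_um = 0, seed = 1)
  m <- centrosome_metrics_table(g0)
  expect_equal(m$angle_deg, rep(180, 4), tolerance = 1e-6)
  expect_equal(m$distance_um, rep(5, 4), tolerance = 1e-9)

  g1 <- generate_point_geometry(500, separation_um = 5, angle_deg = 120,
                                jitter_um = 0.3, seed = 2)
  m1 <- centrosome_metrics_table(g1)
  se <- sd(m1$angle_deg) / sqrt(500)
  expect_lt(abs(mean(m1$angle_deg) - 120), 2 * se + 0.2)
})

test_that("cap field files round trip through TIFF + CSV", {
  dir <- withr::local_tempdir()
  f <- generate_cap_field(cap_field_spec(n_caps = 12, field_size_px = c(128, 128),
                                         noise_sd = 0.05, seed = 8))
  paths <- write_cap_field(f, dir)
  expect_true(all(file.exists(paths)))
  img <- read_image_tiff(paths[["image"]])
  expect_equal(img$pixels, f$image$pixels, tolerance = 1e-6)
  lab <- read_image_tiff(paths[["labels"]])
  expect_identical(lab$labels, f$truth$label_map$labels)
  tab <- read.csv(paths[["table"]])
  expect_equal(tab$area_um2, f$truth$table$area_um2)
})
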