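#' 1D intensity line profile
#'
#' An intensity trace sampled along a line segment drawn perpendicular to an
#' actin filament or bundle.
#'
#' @param positions monotonically increasing sample positions (px).
#' @param intensities nonnegative intensities, same length.
#' @param pixel_size_nm physical pixel size (default 143 nm).
#' @param condition,time_s optional annotation tags carried through to
#'   outputs.
#' @return object of class \code{line_profile}.
#' @export
line_profile <- function(positions, intensities, pixel_size_nm = 143,
                         condition = NA_character_, time_s = NA_real_) {
  if (length(positions) != length(intensities))
    stop("positions and intensities must have equal length")
  if (is.unsorted(positions, strictly = TRUE))
    stop("positions must be strictly increasing")
  if (pixel_size_nm <= 0) stop("pixel_size_nm must be > 0")
  structure(list(positions = as.numeric(positions),
                 intensities = as.numeric(intensities),
                 pixel_size_nm = pixel_size_nm,
                 condition = condition, time_s = time_s),
            class = "line_profile")
}

#' Specification of synthetic TIRF bundle profiles
#'
#' Each profile is a Gaussian of width \code{psf_sigma_px} (the imaging
#' point-spread function) whose amplitude is the filament count times
#' \code{single_filament_amplitude}, on a constant background with additive
#' Gaussian noise. Bundle filament counts are 2 plus a Poisson draw so that
#' their mean is \code{filaments_per_bundle_mean}.
#'
#' @param n_filaments number of single-filament profiles.
#' @param n_bundles number of bundle profiles.
#' @param filaments_per_bundle_mean mean bundle size (>= 2).
#' @param psf_sigma_px Gaussian PSF sigma in pixels (default 1.5).
#' @param single_filament_amplitude fluorescence amplitude of one filament.
#' @param background_level constant offset.
#' @param noise_sd additive noise SD.
#' @param pixel_size_nm pixel size (default 143 nm).
#' @param profile_halfwidth_px samples extend from -halfwidth to +halfwidth.
#' @param seed integer RNG seed.
#' @return list of class \code{tirf_field_spec}.
#' @export
tirf_field_spec <- function(n_filaments = 20, n_bundles = 10,
                            filaments_per_bundle_mean = 3,
                            psf_sigma_px = 1.5,
                            single_filament_amplitude = 100,
                            background_level = 10, noise_sd = 0,
                            pixel_size_nm = 143,
                            profile_halfwidth_px = 7, seed = 1L) {
  if (n_filaments < 1) stop("n_filaments must be >= 1")
  if (n_bundles < 0) stop("n_bundles must be >= 0")
  if (filaments_per_bundle_mean < 2) stop("filaments_per_bundle_mean must be >= 2")
  if (psf_sigma_px <= 0 || single_filament_amplitude <= 0)
    stop("psf_sigma_px and single_filament_amplitude must be > 0")
  if (background_level < 0 || noise_sd < 0)
    stop("background_level and noise_sd must be >= 0")
  if (profile_halfwidth_px < 3) stop("profile_halfwidth_px must be >= 3")
  structure(list(n_filaments = as.integer(n_filaments),
                 n_bundles = as.integer(n_bundles),
                 filaments_per_bundle_mean = filaments_per_bundle_mean,
                 psf_sigma_px = psf_sigma_px,
                 single_filament_amplitude = single_filament_amplitude,
                 background_level = background_level, noise_sd = noise_sd,
                 pixel_size_nm = pixel_size_nm,
                 profile_halfwidth_px = as.integer(profile_halfwidth_px),
                 seed = as.integer(seed)),
            class = "tirf_field_spec")
}

#' Generate synthetic TIRF line profiles with known filament counts
#'
#' Each profile is offset + count * A1 * exp(-(x - c)^2 / (2 sigma^2)) plus
#' noise, with the centre jittered by up to half a pixel. The true filament
#' count of each profile is recorded.
#'
#' @param spec \code{tirf_field_spec}.
#' @return list with \code{profiles} (list of \code{line_profile}) and
#'   \code{true_counts} (integer vector).
#' @export
generate_tirf_profiles <- function(spec) {
  stopifnot(inherits(spec, "tirf_field_spec"))
  withr::with_seed(spec$seed, {
    counts <- c(rep(1L, spec$n_filaments),
                if (spec$n_bundles > 0)
                  2L + rpois(spec$n_bundles, spec$filaments_per_bundle_mean - 2))
    x <- seq(-spec$profile_halfwidth_px, spec$profile_halfwidth_px)
    profiles <- lapply(seq_along(counts), function(i) {
      centre <- runif(1, -0.5, 0.5)
      y <- spec$background_level +
        counts[i] * spec$single_filament_amplitude *
          exp(-(x - centre)^2 / (2 * spec$psf_sigma_px^2))
      if (spec$noise_sd > 0) y <- pmax(y + rnorm(length(x), 0, spec$noise_sd), 0)
      line_profile(x, y, spec$pixel_size_nm,
                   condition = if (counts[i] == 1L) "filament" else "bundle",
                   time_s = 300)
    })
    list(profiles = profiles, true_counts = counts)
  })
}
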