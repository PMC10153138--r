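#' Rolling-ball background subtraction
#'
#' Estimates a slowly varying background as the grayscale morphological
#' opening of the image with a flat disc of the given radius (erosion then
#' dilation) and subtracts it. Structures narrower than the disc survive
#' untouched; flat regions map to ~0. The output is nonnegative because the
#' opening never exceeds the image.
#'
#' @param img \code{image2d}.
#' @param radius_px ball radius in pixels (default 5, the radius used for
#'   TIRF frames).
#' @return background-subtracted \code{image2d}.
#' @export
subtract_background <- function(img, radius_px = 5) {
  stopifnot(inherits(img, "image2d"))
  if (radius_px < 1) stop("radius_px must be >= 1")
  if (radius_px >= min(dim(img$pixels)))
    stop("ball radius exceeds the image extent")
  bg <- cpp_disc_dilate(cpp_disc_erode(img$pixels, radius_px), radius_px)
  image2d(img$pixels - bg, img$pixel_size_um, img$channel_name)
}

#' Extract an intensity profile along a line segment
#'
#' Samples the image by bilinear interpolation at \code{n_samples} evenly
#' spaced points from \code{p0} to \code{p1}. Coordinates are in pixels,
#' (x, y) = (column, row), with pixel centres at integer coordinates.
#'
#' @param img \code{image2d}.
#' @param p0,p1 numeric pairs c(x, y); both endpoints must lie inside the
#'   image and be distinct.
#' @param n_samples number of samples (>= 7 for downstream fitting).
#' @param condition,time_s optional annotation tags.
#' @return \code{line_profile}; positions are distances from \code{p0} in
#'   pixels.
#' @export
extract_profile <- function(img, p0, p1, n_samples = 25,
                            condition = NA_character_, time_s = NA_real_) {
  stopifnot(inherits(img, "image2d"))
  px <- img$pixels
  nr <- nrow(px); nc <- ncol(px)
  inside <- function(p) p[1] >= 1 && p[1] <= nc && p[2] >= 1 && p[2] <= nr
  if (!inside(p0) || !inside(p1)) stop("segment endpoints must lie inside the image")
  if (all(p0 == p1)) stop("segment endpoints coincide")
  if (n_samples < 2) stop("n_samples must be >= 2")
  t <- seq(0, 1, length.out = n_samples)
  xs <- p0[1] + t * (p1[1] - p0[1])
  ys <- p0[2] + t * (p1[2] - p0[2])
  x0 <- pmin(pmax(floor(xs), 1), nc - 1); y0 <- pmin(pmax(floor(ys), 1), nr - 1)
  fx <- xs - x0; fy <- ys - y0
  v <- (1 - fy) * (1 - fx) * px[cbind(y0, x0)] +
       (1 - fy) * fx       * px[cbind(y0, x0 + 1)] +
       fy       * (1 - fx) * px[cbind(y0 + 1, x0)] +
       fy       * fx       * px[cbind(y0 + 1, x0 + 1)]
  dist <- sqrt(sum((p1 - p0)^2))
  line_profile(t * dist, v, img$pixel_size_um * 1000,
               condition = condition, time_s = time_s)
}

#' Fit a Gaussian with offset to a line profile
#'
#' Least-squares fit of offset + A * exp(-(x - c)^2 / (2 sigma^2)),
#' initialised from the profile maximum, intensity-weighted centroid and
#' second moment, with a small multi-start fallback on sigma. Reports the
#' full width at half maximum, fwhm = 2 sqrt(2 ln 2) sigma.
#'
#' @param profile \code{line_profile} with at least 7 samples.
#' @return object of class \code{gaussian_fit}: \code{amplitude},
#'   \code{center}, \code{sigma}, \code{offset}, \code{fwhm}, \code{rss},
#'   \code{converged}.
#' @export
fit_gaussian <- function(profile) {
  stopifnot(inherits(profile, "line_profile"))
  x <- profile$positions; y <- profile$intensities
  if (length(x) < 7) stop("profile too short to fit (need >= 7 samples)")
  if (max(y) == min(y)) stop("flat profile: nothing to fit")
  off0 <- min(y)
  a0 <- max(y) - off0
  w <- pmax(y - off0, 0)
  c0 <- sum(x * w) / sum(w)
  s0 <- sqrt(sum((x - c0)^2 * w) / sum(w))
  if (!is.finite(s0) || s0 <= 0) s0 <- diff(range(x)) / 6
  dx <- diff(range(x))
  model <- function(p) p["offset"] + p["A"] * exp(-(x - p["ctr"])^2 /
                                                    (2 * p["sigma"]^2))
  best <- NULL
  for (s_try in unique(c(s0, s0 / 2, s0 * 2, dx / 10))) {
    fit <- tryCatch(suppressWarnings(
      minpack.lm::nls.lm(
        par = c(offset = off0, A = a0, ctr = c0, sigma = s_try),
        lower = c(offset = -Inf, A = 1e-12, ctr = min(x) - dx,
                  sigma = dx / 1e4),
        upper = c(offset = Inf, A = Inf, ctr = max(x) + dx, sigma = 10 * dx),
        fn = function(p) y - model(p),
        control = minpack.lm::nls.lm.control(maxiter = 200))),
      error = function(e) NULL)
    if (is.null(fit) || !fit$info %in% 1:4) next
    rss <- sum(fit$fvec^2)
    if (is.null(best) || rss < best$rss)
      best <- list(coef = fit$par, rss = rss)
  }
  if (is.null(best)) stop("Gaussian fit did not converge")
  cf <- best$coef
  structure(list(amplitude = unname(cf["A"]), center = unname(cf["ctr"]),
                 sigma = unname(cf["sigma"]), offset = unname(cf["offset"]),
                 fwhm = 2 * sqrt(2 * log(2)) * unname(cf["sigma"]),
                 rss = best$rss, converged = TRUE),
            class = "gaussian_fit")
}

#' @export
print.gaussian_fit <- function(x, ...) {
  cat(sprintf("<gaussian_fit> A = %.4g, center = %.4g, sigma = %.4g, fwhm = %.4g, offset = %.4g\n",
              x$amplitude, x$center, x$sigma, x$fwhm, x$offset))
  invisible(x)
}

#' Bundle intensity metric from a Gaussian fit
#'
#' Two readings of "intensity at FWHM", both background-corrected (the
#' fitted offset is excluded) and both linear in the number of filaments in
#' a bundle: \code{"amplitude"} (default) returns the fitted peak height A;
#' \code{"fwhm_mean"} returns the mean of the fitted Gaussian component over
#' the FWHM window [center - fwhm/2, center + fwhm/2], which is
#' A * sigma * sqrt(2 pi) * (2 pnorm(fwhm / (2 sigma)) - 1) / fwhm.
#'
#' @param fit \code{gaussian_fit}.
#' @param mode \code{"amplitude"} or \code{"fwhm_mean"}.
#' @return numeric metric.
#' @export
bundle_intensity_metric <- function(fit, mode = c("amplitude", "fwhm_mean")) {
  stopifnot(inherits(fit, "gaussian_fit"))
  mode <- match.arg(mode)
  if (mode == "amplitude") return(fit$amplitude)
  w <- fit$fwhm
  fit$amplitude * fit$sigma * sqrt(2 * pi) *
    (2 * pnorm(w / (2 * fit$sigma)) - 1) / w
}

#' Normalize intensity metrics to the control mean
#'
#' Divides every measurement by the mean of the control-reaction
#' measurements, so the control set itself has mean exactly 1.
#'
#' @param values metrics to normalize.
#' @param control_values metrics of the control reaction.
#' @return normalized values.
#' @export
normalize_to_control <- function(values, control_values) {
  if (length(control_values) == 0) stop("empty control set")
  m <- mean(control_values)
  if (!is.finite(m) || m <= 0) stop("control mean must be positive")
  values / m
}
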