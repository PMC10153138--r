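#' Parameters of the actin-cap segmentation pipeline
#'
#' The pipeline mirrors a five-step MATLAB workflow: (1) multiply every
#' pixel by \code{intensity_scale}; (2) enhance ridge-like structures with a
#' multiscale Frangi vesselness filter; (3) blur the ridge response with a
#' Gaussian of \code{gauss_sigma_px}; (4) detect watershed seeds as the
#' regional minima of the blurred (optionally background-subtracted)
#' response; (5) median-filter the ridge response (window
#' \code{median_size_px}), impose the seeds as minima and run a
#' marker-controlled watershed whose lines separate neighbouring caps.
#'
#' @param intensity_scale pre-scaling factor applied to raw intensities
#'   (default 1.25).
#' @param frangi_scales_px Hessian scales (sigma, px) for the vesselness
#'   filter; defaults to the canonical range 1-10 px in steps of 2.
#' @param frangi_beta blob-ness sensitivity (default 0.5).
#' @param frangi_c structure-ness sensitivity (default 15, on the scale of
#'   the Hessian norm of the input).
#' @param ridge_polarity \code{"bright"} enhances bright ridges on a dark
#'   background (actin furrows), \code{"dark"} the opposite.
#' @param gauss_sigma_px blur applied before seed detection; the workflow
#'   uses values in 4-10 depending on the image (default 6). Values outside
#'   that range are accepted but flagged with a warning.
#' @param seed_background_subtract_radius_px rolling-ball radius (px) for
#'   background subtraction before seed detection; \code{0} (default)
#'   disables the subtraction, which synthetic flat-background images do not
#'   need.
#' @param median_size_px median-filter window (odd, default 11) applied to
#'   the ridge response before the watershed.
#' @param min_region_area_um2 regions smaller than this are merged into
#'   their largest neighbour after the watershed; 0 (default) disables the
#'   merge. A reproducible surrogate for manual cleanup.
#' @return A list of class \code{segmentation_params}.
#' @export
segmentation_params <- function(intensity_scale = 1.25,
                                frangi_scales_px = c(1, 3, 5, 7, 9),
                                frangi_beta = 0.5,
                                frangi_c = 15,
                                ridge_polarity = c("bright", "dark"),
                                gauss_sigma_px = 6,
                                seed_background_subtract_radius_px = 0,
                                median_size_px = 11,
                                min_region_area_um2 = 0) {
  ridge_polarity <- match.arg(ridge_polarity)
  if (length(frangi_scales_px) < 1 || any(frangi_scales_px <= 0))
    stop("frangi_scales_px must be a non-empty vector of positive scales")
  if (frangi_beta <= 0 || frangi_c <= 0) stop("frangi_beta and frangi_c must be > 0")
  if (gauss_sigma_px <= 0) stop("gauss_sigma_px must be > 0")
  if (gauss_sigma_px < 4 || gauss_sigma_px > 10)
    warning("gauss_sigma_px outside the usual 4-10 range")
  if (median_size_px < 1 || median_size_px %% 2 == 0)
    stop("median_size_px must be odd")
  if (min_region_area_um2 < 0) stop("min_region_area_um2 must be >= 0")
  structure(list(
    intensity_scale = intensity_scale,
    frangi_scales_px = sort(frangi_scales_px),
    frangi_beta = frangi_beta, frangi_c = frangi_c,
    ridge_polarity = ridge_polarity,
    gauss_sigma_px = gauss_sigma_px,
    seed_background_subtract_radius_px = seed_background_subtract_radius_px,
    median_size_px = as.integer(median_size_px),
    min_region_area_um2 = min_region_area_um2
  ), class = "segmentation_params")
}

#' Multiscale Frangi ridge enhancement
#'
#' Hessian-eigenvalue vesselness. At each scale sigma the image is convolved
#' with scale-normalised (sigma^2) Gaussian second-derivative kernels; with
#' eigenvalues |l1| <= |l2| the response is
#' exp(-(l1/l2)^2 / (2 beta^2)) * (1 - exp(-(l1^2 + l2^2) / (2 c^2))),
#' zeroed where l2 has the wrong sign for the requested polarity (bright
#' ridges require l2 < 0). The returned image is the maximum response over
#' scales, bounded in [0, 1].
#'
#' @param img \code{image2d}.
#' @param params \code{segmentation_params} (scales, beta, c, polarity).
#' @return \code{image2d} of vesselness values in [0, 1].
#' @export
enhance_ridges <- function(img, params = segmentation_params()) {
  stopifnot(inherits(img, "image2d"))
  scales <- params$frangi_scales_px
  if (length(scales) == 0) stop("empty Frangi scale list")
  if (min(dim(img$pixels)) < max(ceiling(2 * max(scales)), 3))
    stop("image smaller than the largest Frangi scale support")
  px <- img$pixels
  beta2 <- 2 * params$frangi_beta^2
  c2 <- 2 * params$frangi_c^2
  best <- matrix(0, nrow(px), ncol(px))
  for (s in scales) {
    g0 <- gauss_kernel(s, 0L)
    g1 <- gauss_kernel(s, 1L)
    g2 <- gauss_kernel(s, 2L)
    # x = columns (axis 2), y = rows (axis 1); scale-normalise by s^2
    dxx <- s^2 * conv_sep(px, g0, g2)
    dyy <- s^2 * conv_sep(px, g2, g0)
    dxy <- s^2 * conv_sep(px, g1, g1)
    tmp <- sqrt((dxx - dyy)^2 + 4 * dxy^2)
    mu1 <- (dxx + dyy + tmp) / 2
    mu2 <- (dxx + dyy - tmp) / 2
    swap <- abs(mu1) > abs(mu2)
    l1 <- ifelse(swap, mu2, mu1)   # smaller magnitude
    l2 <- ifelse(swap, mu1, mu2)   # larger magnitude
    rb2 <- ifelse(l2 == 0, 0, (l1 / l2)^2)
    s2 <- l1^2 + l2^2
    v <- exp(-rb2 / beta2) * (1 - exp(-s2 / c2))
    keep <- if (params$ridge_polarity == "bright") l2 < 0 else l2 > 0
    v[!keep] <- 0
    best <- pmax(best, v)
  }
  # flush responses at floating-point noise level so constant inputs give an
  # exactly zero (single-plateau) response
  best[best < 1e-12] <- 0
  image2d(best, img$pixel_size_um, img$channel_name)
}

#' Watershed seeds from regional minima
#'
#' Finds all regional minima of the image: 8-connected plateaus of equal
#' value strictly below every neighbouring pixel. Each plateau becomes one
#' seed marker. A constant image is a single plateau covering the field.
#'
#' @param img \code{image2d}, normally the blurred (and optionally
#'   background-subtracted) ridge response.
#' @param params \code{segmentation_params}; if
#'   \code{seed_background_subtract_radius_px > 0} a rolling-ball background
#'   is removed before minima detection.
#' @return A list of class \code{seed_set}: \code{labels} (integer matrix,
#'   one positive id per plateau), \code{coords} (data frame with one
#'   representative pixel per seed: seed, row, col), \code{n_seeds}.
#' @export
find_seeds <- function(img, params = segmentation_params()) {
  stopifnot(inherits(img, "image2d"))
  work <- img
  r <- params$seed_background_subtract_radius_px
  if (!is.null(r) && r > 0) work <- subtract_background(work, r)
  lab <- cpp_regional_minima(work$pixels)
  ids <- sort(unique(lab[lab > 0]))
  coords <- do.call(rbind, lapply(ids, function(k) {
    w <- which(lab == k, arr.ind = TRUE)
    w <- w[order(w[, 1], w[, 2]), , drop = FALSE]
    data.frame(seed = k, row = w[1, 1], col = w[1, 2])
  }))
  if (is.null(coords)) coords <- data.frame(seed = integer(), row = integer(), col = integer())
  structure(list(labels = lab, coords = coords, n_seeds = length(ids)),
            class = "seed_set")
}

#' Marker-controlled watershed
#'
#' Meyer flooding from integer seed markers on a topographic surface.
#' Flooding is 8-connected and deterministic: the queue is ordered by
#' (pixel value, row-major index). Pixels first reached from two or more
#' distinct labels become watershed lines (label 0).
#'
#' @param img \code{image2d}, the surface to flood (low = basin interior).
#' @param seeds integer matrix of seed markers (same size as the image) or a
#'   \code{seed_set}.
#' @return \code{label_map}; 0 marks watershed lines.
#' @export
watershed_from_seeds <- function(img, seeds) {
  stopifnot(inherits(img, "image2d"))
  if (inherits(seeds, "seed_set")) seeds <- seeds$labels
  seeds <- as.matrix(seeds)
  storage.mode(seeds) <- "integer"
  label_map(cpp_watershed(img$pixels, seeds), img$pixel_size_um)
}

#' Segment actin caps
#'
#' Runs the full five-step pipeline (see \code{\link{segmentation_params}}):
#' intensity scaling, Frangi ridge enhancement, Gaussian blur, regional-
#' minimum seed detection, then marker-controlled watershed on the
#' median-filtered ridge response with the seeds imposed as minima.
#' Boundary pixels get label 0; every interior pixel belongs to the basin
#' grown from exactly one seed. Regions smaller than
#' \code{min_region_area_um2} are merged into their largest neighbour.
#'
#' @param img calibrated \code{image2d} (maximum-intensity projection).
#' @param params \code{segmentation_params}.
#' @return \code{label_map}.
#' @export
segment_caps <- function(img, params = segmentation_params()) {
  stopifnot(inherits(img, "image2d"))
  if (min(dim(img$pixels)) < params$median_size_px)
    stop("image smaller than the median filter support")
  scaled <- scale_intensity(img, params$intensity_scale)
  ridge <- enhance_ridges(scaled, params)
  blurred <- blur(ridge, params$gauss_sigma_px)
  seeds <- find_seeds(blurred, params)
  if (seeds$n_seeds == 0) stop("zero usable seeds: input unusable for segmentation")
  surface <- image2d(cpp_median_filter(ridge$pixels, params$median_size_px),
                     img$pixel_size_um, img$channel_name)
  lm <- watershed_from_seeds(surface, seeds)
  if (params$min_region_area_um2 > 0)
    lm <- merge_small_regions(lm, params$min_region_area_um2)
  lm
}

# merge regions below a minimum area into their largest adjacent region;
# the separating line pixels are reassigned where unambiguous
merge_small_regions <- function(lm, min_area_um2) {
  lab <- lm$labels
  px2 <- lm$pixel_size_um^2
  repeat {
    tab <- table(lab[lab > 0])
    small <- as.integer(names(tab)[as.numeric(tab) * px2 < min_area_um2])
    if (length(small) == 0) break
    k <- small[1]
    nbr <- adjacent_labels(lab, k)
    if (length(nbr) == 0) { lab[lab == k] <- 0L } else {
      sizes <- tab[as.character(nbr)]
      target <- nbr[which.max(sizes)]
      lab[lab == k] <- target
    }
    lab <- absorb_lines(lab)
  }
  # relabel consecutively, preserving raster order of first appearance
  ids <- unique(lab[lab > 0])
  remap <- integer(max(c(lab, 1L)))
  remap[sort(ids)] <- seq_along(ids)
  lab[lab > 0] <- remap[lab[lab > 0]]
  label_map(lab, lm$pixel_size_um)
}

# labels 8-adjacent to region k, looking across at most one line pixel
adjacent_labels <- function(lab, k) {
  nr <- nrow(lab); nc <- ncol(lab)
  w <- which(lab == k, arr.ind = TRUE)
  found <- integer(0)
  for (dr in -2:2) for (dc in -2:2) {
    if (dr == 0 && dc == 0) next
    rr <- w[, 1] + dr; cc <- w[, 2] + dc
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    v <- lab[cbind(rr[ok], cc[ok])]
    found <- c(found, v[v > 0 & v != k])
  }
  sort(unique(found))
}

# assign line pixels whose positive neighbours all share one label
absorb_lines <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  zero <- which(lab == 0)
  if (length(zero) == 0) return(lab)
  r <- (zero - 1L) %% nr + 1L
  c <- (zero - 1L) %/% nr + 1L
  lo <- hi <- rep(0L, length(zero))
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0 && dc == 0) next
    rr <- r + dr; cc <- c + dc
    ok <- rr >= 1 & rr <= nr & cc >= 1 & cc <= nc
    v <- integer(length(zero)); v[ok] <- lab[cbind(rr[ok], cc[ok])]
    pos <- v > 0
    lo[pos & lo == 0L] <- v[pos & lo == 0L]
    hi[pos] <- ifelse(v[pos] != lo[pos], v[pos], hi[pos])
  }
  assign_ok <- lo > 0L & (hi == 0L | hi == lo)
  lab[zero[assign_ok]] <- lo[assign_ok]
  lab
}

#' Tabulate compartments of a label map
#'
#' @param lm \code{label_map}.
#' @return data frame with one row per positive label: \code{label},
#'   \code{area_um2}, \code{centroid_x_um}, \code{centroid_y_um}.
#' @export
cap_table <- function(lm) {
  stopifnot(inherits(lm, "label_map"))
  lab <- lm$labels
  ids <- sort(unique(lab[lab > 0]))
  px <- lm$pixel_size_um
  rows <- lapply(ids, function(k) {
    w <- which(lab == k, arr.ind = TRUE)
    data.frame(label = k,
               area_um2 = nrow(w) * px^2,
               centroid_x_um = mean(w[, 2] - 0.5) * px,
               centroid_y_um = mean(w[, 1] - 0.5) * px)
  })
  if (length(rows) == 0)
    return(data.frame(label = integer(), area_um2 = numeric(),
                      centroid_x_um = numeric(), centroid_y_um = numeric()))
  do.call(rbind, rows)
}
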