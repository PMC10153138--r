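#' Per-embryo cap statistics
#'
#' Mean cap area, an area histogram, and the fraction of small caps: the
#' proportion of compartments with area strictly below the threshold
#' (default 80 um^2, the conventional small-cap cutoff; the small-cap mode
#' of perturbed embryos peaks near 30 um^2).
#'
#' @param table cap table (columns \code{label}, \code{area_um2}, ...), as
#'   returned by \code{\link{cap_table}}; must be non-empty.
#' @param small_threshold_um2 strict upper bound defining a small cap
#'   (default 80).
#' @param bin_width_um2 histogram bin width (default 10).
#' @return list of class \code{embryo_summary}: \code{n_caps},
#'   \code{mean_cap_area_um2}, \code{small_cap_fraction},
#'   \code{histogram} (data frame: bin_left, bin_right, count).
#' @export
cap_statistics <- function(table, small_threshold_um2 = 80,
                           bin_width_um2 = 10) {
  if (is.null(table$area_um2) || nrow(table) == 0)
    stop("empty cap table")
  if (any(table$area_um2 <= 0)) stop("cap areas must be positive")
  a <- table$area_um2
  breaks <- seq(0, max(a) + bin_width_um2, by = bin_width_um2)
  counts <- tabulate(findInterval(a, breaks, left.open = TRUE),
                     nbins = length(breaks) - 1)
  structure(list(
    n_caps = length(a),
    mean_cap_area_um2 = mean(a),
    small_cap_fraction = mean(a < small_threshold_um2),
    histogram = data.frame(bin_left = breaks[-length(breaks)],
                           bin_right = breaks[-1], count = counts)
  ), class = "embryo_summary")
}

#' @export
print.embryo_summary <- function(x, ...) {
  cat(sprintf("<embryo_summary> %d caps, mean area %.2f um^2, small-cap fraction %.3f\n",
              x$n_caps, x$mean_cap_area_um2, x$small_cap_fraction))
  invisible(x)
}

#' Nuclear density
#'
#' Nuclei per unit area; the count usually comes from segmenting a
#' myosin/nuclear channel with \code{\link{segment_caps}} and counting
#' labels, the area from the image extent or a supplied embryo area.
#'
#' @param n_nuclei nonnegative count.
#' @param field_area_um2 field or embryo area (> 0), um^2.
#' @return nuclei per um^2.
#' @export
nuclear_density <- function(n_nuclei, field_area_um2) {
  if (n_nuclei < 0) stop("n_nuclei must be >= 0")
  if (!is.finite(field_area_um2) || field_area_um2 <= 0)
    stop("field_area_um2 must be > 0")
  n_nuclei / field_area_um2
}

#' Missing-furrow ratio
#'
#' Number of missing pseudo-cleavage furrows normalized over the total
#' number of actin caps; counts are manual annotations.
#'
#' @param n_missing nonnegative count of missing furrows.
#' @param n_caps total cap count (>= 1).
#' @return ratio in [0, 1] (can exceed 1 only if annotations do).
#' @export
missing_furrow_ratio <- function(n_missing, n_caps) {
  if (n_missing < 0) stop("n_missing must be >= 0")
  if (n_caps < 1) stop("n_caps must be >= 1")
  n_missing / n_caps
}

#' Centrosome-pair and spindle geometry
#'
#' Distance between the two centrosomes of a nucleus, the angle the pair
#' subtends at the nuclear centre (180 degrees = fully separated to opposite
#' sides), and optionally the spindle length (pole-to-pole distance).
#'
#' @param nucleus_um,centrosome_a_um,centrosome_b_um numeric (x, y) pairs.
#' @param spindle_pole_a_um,spindle_pole_b_um optional (x, y) pairs.
#' @return list: \code{distance_um}, \code{angle_deg} in [0, 180],
#'   \code{spindle_length_um} (NA when poles are not given).
#' @export
centrosome_metrics <- function(nucleus_um, centrosome_a_um, centrosome_b_um,
                               spindle_pole_a_um = NULL,
                               spindle_pole_b_um = NULL) {
  pts <- list(nucleus_um, centrosome_a_um, centrosome_b_um)
  if (any(!vapply(pts, function(p) length(p) == 2 && all(is.finite(p)),
                  logical(1))))
    stop("nucleus and centrosome points must be finite (x, y) pairs")
  va <- centrosome_a_um - nucleus_um
  vb <- centrosome_b_um - nucleus_um
  if (sqrt(sum(va^2)) == 0 || sqrt(sum(vb^2)) == 0)
    stop("centrosome coincides with the nuclear centre; angle undefined")
  cosang <- sum(va * vb) / (sqrt(sum(va^2)) * sqrt(sum(vb^2)))
  angle <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
  dist <- sqrt(sum((centrosome_a_um - centrosome_b_um)^2))
  sl <- NA_real_
  if (!is.null(spindle_pole_a_um) && !is.null(spindle_pole_b_um))
    sl <- sqrt(sum((spindle_pole_a_um - spindle_pole_b_um)^2))
  list(distance_um = dist, angle_deg = angle, spindle_length_um = sl)
}

#' Centrosome metrics for a table of annotated pairs
#'
#' @param geometry data frame in the layout of
#'   \code{\link{generate_point_geometry}}.
#' @return input data frame with \code{distance_um} and \code{angle_deg}
#'   columns appended.
#' @export
centrosome_metrics_table <- function(geometry) {
  need <- c("nucleus_x_um", "nucleus_y_um", "centrosome_ax_um",
            "centrosome_ay_um", "centrosome_bx_um", "centrosome_by_um")
  miss <- setdiff(need, names(geometry))
  if (length(miss) > 0) stop("geometry lacks columns: ", paste(miss, collapse = ", "))
  res <- lapply(seq_len(nrow(geometry)), function(i) {
    g <- geometry[i, ]
    centrosome_metrics(c(g$nucleus_x_um, g$nucleus_y_um),
                       c(g$centrosome_ax_um, g$centrosome_ay_um),
                       c(g$centrosome_bx_um, g$centrosome_by_um))
  })
  geometry$distance_um <- vapply(res, `[[`, numeric(1), "distance_um")
  geometry$angle_deg <- vapply(res, `[[`, numeric(1), "angle_deg")
  geometry
}

#' Min-max normalization to [0, 1]
#'
#' (I - I_min) / (I_max - I_min); the minimum maps to 0, the maximum to 1,
#' order is preserved. Idempotent on already-normalized input.
#'
#' @param values numeric vector with at least two distinct values.
#' @return normalized vector.
#' @export
normalize_minmax <- function(values) {
  if (any(!is.finite(values))) stop("values must be finite")
  rng <- range(values)
  if (diff(rng) == 0) stop("zero dynamic range: all values equal")
  (values - rng[1]) / (rng[2] - rng[1])
}

#' Apical/basal furrow intensity ratio
#'
#' The intensity trace along a furrow is min-max normalized, then the mean
#' over the most apical window (the start of the profile) is divided by the
#' mean over the most basal window (the end). Default windows are 2 um at
#' each end.
#'
#' @param positions_um positions along the furrow axis, increasing from
#'   apical to basal, um.
#' @param intensities intensities at those positions.
#' @param apical_window_um,basal_window_um window lengths, um (default 2).
#' @return apical/basal ratio of normalized mean intensities.
#' @export
furrow_intensity_ratio <- function(positions_um, intensities,
                                   apical_window_um = 2,
                                   basal_window_um = 2) {
  if (length(positions_um) != length(intensities))
    stop("positions and intensities must have equal length")
  if (is.unsorted(positions_um, strictly = TRUE))
    stop("positions must be strictly increasing")
  span <- diff(range(positions_um))
  if (span < apical_window_um + basal_window_um)
    stop("profile shorter than the apical + basal windows")
  v <- normalize_minmax(intensities)
  apical <- positions_um <= positions_um[1] + apical_window_um
  basal <- positions_um >= positions_um[length(positions_um)] - basal_window_um
  mb <- mean(v[basal])
  if (mb == 0) stop("basal window mean is zero after normalization")
  mean(v[apical]) / mb
}
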