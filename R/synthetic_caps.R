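#' Specification of a synthetic actin-cap field
#'
#' Describes a field of polygonal actin compartments: caps are cells of a
#' radius-weighted nearest-site tessellation around jittered lattice sites,
#' outlined by bright ridges (the furrow signal) on a dimmer interior, over
#' a dark noisy background. A fraction of lattice sites can be left empty to
#' emulate nuclear fallout, and a fraction of caps can be drawn from a
#' second small-area mode to emulate a bimodal size distribution with a
#' small-cap peak near 30 um^2.
#'
#' @param field_size_px integer pair (rows, cols).
#' @param pixel_size_um pixel size, um (default 0.35).
#' @param n_caps number of lattice sites (caps before fallout).
#' @param cap_area_mean_um2,cap_area_sd_um2 main-mode cap area (um^2);
#'   defaults 120 and 25.
#' @param small_cap_fraction fraction of caps drawn from the small mode.
#' @param small_cap_area_mean_um2,small_cap_area_sd_um2 small-mode area
#'   (um^2); defaults 30 and 8.
#' @param fallout_fraction fraction of lattice sites left empty.
#' @param cap_reach_slack_px caps may grow up to this many pixels beyond
#'   their nominal radius to meet their neighbours (default 12), so that at
#'   zero fallout the compartments tile the cortex as post-expansion caps
#'   do; fallout holes are wider than the slack and stay open.
#' @param ridge_width_px total painted width of the ridge separating two
#'   adjoining caps, px (even, default 2: each cap contributes a ring of
#'   half that width). Pseudo-cleavage furrows span roughly 0.5-1 um, so
#'   at fine sampling a wider ridge is the realistic choice.
#' @param furrow_halo_px unowned pixels within this distance of the edges of
#'   at least two different caps are painted at ridge intensity, emulating
#'   the contiguous actin-furrow network that fills the space between
#'   neighbouring caps (default 6); rims of isolated caps and the cores of
#'   larger empty regions (fallout holes) stay dark.
#' @param ridge_intensity,interior_intensity,background_intensity painted
#'   intensities; must satisfy ridge > interior > background.
#' @param noise_sd additive Gaussian noise SD (clipped at 0).
#' @param seed integer RNG seed; all randomness of the generator flows from
#'   it.
#' @return A list of class \code{cap_field_spec}.
#' @export
cap_field_spec <- function(field_size_px = c(320, 320),
                           pixel_size_um = 0.35,
                           n_caps = 100,
                           cap_area_mean_um2 = 120,
                           cap_area_sd_um2 = 25,
                           small_cap_fraction = 0,
                           small_cap_area_mean_um2 = 30,
                           small_cap_area_sd_um2 = 8,
                           fallout_fraction = 0,
                           cap_reach_slack_px = 12,
                           ridge_width_px = 4,
                           furrow_halo_px = 6,
                           ridge_intensity = 1,
                           interior_intensity = 0.5,
                           background_intensity = 0.15,
                           noise_sd = 0,
                           seed = 1L) {
  field_size_px <- as.integer(field_size_px)
  if (length(field_size_px) != 2 || any(field_size_px < 8))
    stop("field_size_px must be a pair of integers >= 8")
  if (n_caps < 1) stop("n_caps must be >= 1")
  if (cap_area_mean_um2 <= 0 || cap_area_sd_um2 <= 0 ||
      small_cap_area_mean_um2 <= 0 || small_cap_area_sd_um2 <= 0)
    stop("cap area parameters must be positive")
  if (small_cap_fraction < 0 || small_cap_fraction > 1)
    stop("small_cap_fraction must be in [0,1]")
  if (fallout_fraction < 0 || fallout_fraction > 1)
    stop("fallout_fraction must be in [0,1]")
  if (!(ridge_intensity > interior_intensity &&
        interior_intensity > background_intensity))
    stop("need ridge_intensity > interior_intensity > background_intensity")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (furrow_halo_px < 0) stop("furrow_halo_px must be >= 0")
  if (ridge_width_px < 2) stop("ridge_width_px must be >= 2")
  if (cap_reach_slack_px < 0) stop("cap_reach_slack_px must be >= 0")
  mix_mean <- (1 - small_cap_fraction) * cap_area_mean_um2 +
    small_cap_fraction * small_cap_area_mean_um2
  field_area <- prod(field_size_px) * pixel_size_um^2
  if (n_caps * mix_mean > field_area)
    stop("n_caps x mean cap area exceeds the field area")
  structure(as.list(environment())[c(
    "field_size_px", "pixel_size_um", "n_caps",
    "cap_area_mean_um2", "cap_area_sd_um2", "small_cap_fraction",
    "small_cap_area_mean_um2", "small_cap_area_sd_um2",
    "fallout_fraction", "cap_reach_slack_px", "ridge_width_px",
    "furrow_halo_px",
    "ridge_intensity", "interior_intensity",
    "background_intensity", "noise_sd", "seed")],
    class = "cap_field_spec")
}

#' Draw cap areas from a spec's (possibly bimodal) area distribution
#'
#' Each area comes from the main normal mode with probability
#' 1 - small_cap_fraction and from the small mode otherwise, floored at
#' four pixel areas. This is the sampler \code{\link{generate_cap_field}}
#' uses to size its tessellation cells.
#'
#' @param spec \code{cap_field_spec}.
#' @param n number of areas to draw.
#' @param .reseed seed the RNG from the spec (default TRUE); internal
#'   callers that already manage the RNG state pass FALSE.
#' @return numeric vector of areas, um^2.
#' @export
sample_cap_areas <- function(spec, n = spec$n_caps, .reseed = TRUE) {
  stopifnot(inherits(spec, "cap_field_spec"))
  draw <- function() {
    from_small <- runif(n) < spec$small_cap_fraction
    a <- ifelse(from_small,
                rnorm(n, spec$small_cap_area_mean_um2,
                      spec$small_cap_area_sd_um2),
                rnorm(n, spec$cap_area_mean_um2, spec$cap_area_sd_um2))
    pmax(a, 4 * spec$pixel_size_um^2)
  }
  if (.reseed) withr::with_seed(spec$seed, draw()) else draw()
}

#' Generate a synthetic actin-cap image with ground truth
#'
#' Sites are placed on a jittered square lattice sized to hold
#' \code{n_caps}; a \code{fallout_fraction} of sites is removed. Each
#' remaining cap k gets a target area from the (possibly bimodal) area
#' distribution and the corresponding radius r_k; a pixel belongs to the cap
#' minimising distance/r_k provided that distance <= r_k, giving round caps
#' where isolated and polygonal, furrow-delimited cells where crowded.
#' Boundary pixels (one ring per cap, so ~2 px where caps adjoin) are
#' painted at \code{ridge_intensity}, interiors at
#' \code{interior_intensity}; unowned pixels within \code{furrow_halo_px}
#' of a cap edge are painted at ridge intensity (the inter-cap furrow
#' network), and only the cores of large empty regions -- fallout holes --
#' stay at \code{background_intensity}. Gaussian noise is added and the
#' image clipped at 0.
#'
#' Ground truth records the painted geometry exactly: the label map holds
#' each cap's full tessellation cell (interior plus its own ridge ring),
#' labels are consecutive from 1, and areas/centroids are computed from
#' those cells.
#'
#' @param spec \code{cap_field_spec}.
#' @return list with \code{image} (\code{image2d}) and \code{truth}, itself
#'   a list: \code{label_map}, \code{table} (label, area_um2,
#'   centroid_x_um, centroid_y_um), \code{n_caps}.
#' @export
generate_cap_field <- function(spec) {
  stopifnot(inherits(spec, "cap_field_spec"))
  withr::with_seed(spec$seed, {
    nr <- spec$field_size_px[1]; nc <- spec$field_size_px[2]
    px <- spec$pixel_size_um

    # jittered square lattice with at least n_caps sites
    gc_ <- ceiling(sqrt(spec$n_caps * nc / nr))
    gr_ <- ceiling(spec$n_caps / gc_)
    sx <- nc / gc_; sy <- nr / gr_
    sites <- expand.grid(gy = seq_len(gr_), gx = seq_len(gc_))
    sites <- sites[seq_len(spec$n_caps), , drop = FALSE]
    site_y <- (sites$gy - 0.5) * sy + runif(spec$n_caps, -0.2, 0.2) * sy
    site_x <- (sites$gx - 0.5) * sx + runif(spec$n_caps, -0.2, 0.2) * sx

    # bimodal target areas -> radii in px
    areas <- sample_cap_areas(spec, spec$n_caps, .reseed = FALSE)
    radius <- sqrt(areas / pi) / px

    # nuclear fallout: dropped sites stay in the tessellation as phantom
    # cells so the lost nucleus leaves a dark, cap-sized patch of bare
    # cortex rather than being silently absorbed by its neighbours
    n_drop <- round(spec$fallout_fraction * spec$n_caps)
    keep <- rep(TRUE, spec$n_caps)
    if (n_drop > 0) keep[sample.int(spec$n_caps, n_drop)] <- FALSE
    n_kept <- sum(keep)

    assign <- matrix(0L, nr, nc)      # winning site (1..n_caps, 0 = none)
    phantom <- matrix(FALSE, nr, nc)  # pixel won by a dropped site
    min_excess <- matrix(Inf, nr, nc)  # smallest (d - r) over kept caps
    min2_excess <- matrix(Inf, nr, nc) # second smallest (d - r)
    if (spec$n_caps > 0) {
      ys <- matrix(rep(seq_len(nr) - 0.5, nc), nr, nc)
      xs <- matrix(rep(seq_len(nc) - 0.5, each = nr), nr, nc)
      best_ratio <- matrix(Inf, nr, nc)
      best_excess <- matrix(Inf, nr, nc)  # d - r of the owning site
      for (k in seq_len(spec$n_caps)) {
        d <- sqrt((ys - site_y[k])^2 + (xs - site_x[k])^2)
        ratio <- d / radius[k]
        upd <- ratio < best_ratio
        best_ratio[upd] <- ratio[upd]
        best_excess[upd] <- d[upd] - radius[k]
        assign[upd] <- k
        if (keep[k]) {
          ex <- d - radius[k]
          lower <- ex < min_excess
          min2_excess[lower] <- min_excess[lower]
          min_excess[lower] <- ex[lower]
          mid <- !lower & ex < min2_excess
          min2_excess[mid] <- ex[mid]
        }
      }
      phantom <- matrix(!keep[assign], nr, nc)
      # a cap reaches at most slack px beyond its nominal radius
      assign[phantom | best_excess > spec$cap_reach_slack_px] <- 0L
      # renumber kept caps 1..n_kept in site order
      site_rank <- cumsum(keep)
      assign[assign > 0L] <- site_rank[assign[assign > 0L]]
    }

    # boundary ring: cap pixel within ridge_width_px/2 (chebyshev) of a
    # pixel outside its own cap
    boundary <- matrix(FALSE, nr, nc)
    hw <- max(1L, as.integer(round(spec$ridge_width_px / 2)))
    if (n_kept > 0) {
      for (dr in -hw:hw) for (dc in -hw:hw) {
        if (dr == 0 && dc == 0) next
        shifted <- matrix(0L, nr, nc)
        rsrc <- seq_len(nr) - dr; csrc <- seq_len(nc) - dc
        rok <- rsrc >= 1 & rsrc <= nr; cok <- csrc >= 1 & csrc <= nc
        shifted[rok, cok] <- assign[rsrc[rok], csrc[cok]]
        boundary <- boundary | (assign > 0L & shifted != assign)
      }
    }

    img <- matrix(spec$background_intensity, nr, nc)
    # at free rims the furrow ridge straddles the compartment edge: paint a
    # collar one pixel wider than the inner half-ring just outside the owned
    # cell, so the ridge crest -- and the one-pixel boundary line the
    # watershed draws on it -- falls outside the compartment, mirroring the
    # one-pixel line convention used between adjoining caps
    collar <- assign == 0L & !phantom &
      min_excess <= spec$cap_reach_slack_px + hw + 1
    # furrow network: gaps BETWEEN caps (near the edges of two or more
    # caps) are actin-bright, and small unowned pockets at cell junctions
    # are furrow canals, bright throughout; rims of isolated caps and the
    # cores of large empty regions (fallout holes) stay dark
    halo <- assign == 0L & min2_excess <= spec$furrow_halo_px
    halo <- halo & !phantom
    if (n_kept > 0 && any(assign == 0L)) {
      comp <- cpp_regional_minima(matrix(as.numeric(assign > 0L), nr, nc))
      if (max(comp) > 0) {
        csize <- tabulate(comp[comp > 0], nbins = max(comp))
        pocket_max <- 0.25 * mean(pi * radius[keep]^2)
        small_comp <- which(csize > 0 & csize < pocket_max)
        halo <- halo | (comp > 0 & matrix(comp %in% small_comp, nr, nc) &
                          !phantom)
      }
    }
    img[halo | collar] <- spec$ridge_intensity
    img[assign > 0L] <- spec$interior_intensity
    img[boundary] <- spec$ridge_intensity
    if (spec$noise_sd > 0)
      img <- pmax(img + rnorm(nr * nc, 0, spec$noise_sd), 0)

    labels <- assign
    # ground-truth boundary convention: a one-pixel line separates adjacent
    # cells (label 0), mirroring how compartment boundaries are reported;
    # of two facing pixels the one farther from its site (larger d/r,
    # ties by linear index) yields the line pixel
    if (n_kept > 0) {
      line <- matrix(FALSE, nr, nc)
      for (dr in -1:1) for (dc in -1:1) {
        if (dr == 0 && dc == 0) next
        sh_lab <- matrix(0L, nr, nc)
        sh_ratio <- matrix(Inf, nr, nc)
        rsrc <- seq_len(nr) - dr; csrc <- seq_len(nc) - dc
        rok <- rsrc >= 1 & rsrc <= nr; cok <- csrc >= 1 & csrc <= nc
        sh_lab[rok, cok] <- assign[rsrc[rok], csrc[cok]]
        sh_ratio[rok, cok] <- best_ratio[rsrc[rok], csrc[cok]]
        idx <- matrix(seq_len(nr * nc), nr, nc)
        sh_idx <- matrix(NA_integer_, nr, nc)
        sh_idx[rok, cok] <- idx[rsrc[rok], csrc[cok]]
        cross <- assign > 0L & sh_lab > 0L & sh_lab != assign
        beats <- best_ratio > sh_ratio |
          (best_ratio == sh_ratio & idx > sh_idx)
        line <- line | (cross & beats)
      }
      labels[line] <- 0L
    }
    # consecutive labels from 1 in order of site index
    ids <- sort(unique(labels[labels > 0L]))
    remap <- integer(max(c(ids, 1L)))
    remap[ids] <- seq_along(ids)
    labels[labels > 0L] <- remap[labels[labels > 0L]]

    lm <- label_map(labels, px)
    truth_tab <- cap_table(lm)
    list(image = image2d(img, px, "actin"),
         truth = list(label_map = lm, table = truth_tab,
                      n_caps = nrow(truth_tab)))
  })
}

#' Write a synthetic cap field to disk
#'
#' Writes the image and the ground-truth label map as 32-bit float TIFFs and
#' the ground-truth table as CSV.
#'
#' @param field result of \code{\link{generate_cap_field}}.
#' @param dir output directory (created if needed).
#' @param basename file stem (default \code{"caps"}).
#' @return named character vector of the written paths, invisibly.
#' @export
write_cap_field <- function(field, dir, basename = "caps") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p_img <- file.path(dir, paste0(basename, "_image.tif"))
  p_lab <- file.path(dir, paste0(basename, "_truth_labels.tif"))
  p_csv <- file.path(dir, paste0(basename, "_truth.csv"))
  write_image_tiff(field$image, p_img)
  write_image_tiff(field$truth$label_map, p_lab)
  write.csv(field$truth$table, p_csv, row.names = FALSE)
  invisible(c(image = p_img, labels = p_lab, table = p_csv))
}

#' Generate nuclear/centrosome point geometry
#'
#' Emits nuclear centres on a square grid plus two centrosome points per
#' nucleus, placed so that the segment between the centrosomes has length
#' \code{separation_um} and subtends \code{angle_deg} at the nuclear centre,
#' with a random orientation per nucleus and isotropic Gaussian jitter of SD
#' \code{jitter_um} added to each centrosome coordinate.
#'
#' @param n_pairs number of nuclei (>= 1).
#' @param separation_um centrosome-centrosome distance, um.
#' @param angle_deg subtended angle at the nucleus, degrees, in (0, 180].
#' @param jitter_um isotropic jitter SD, um.
#' @param seed integer RNG seed.
#' @return data frame with columns \code{pair}, \code{nucleus_x_um},
#'   \code{nucleus_y_um}, \code{centrosome_ax_um}, \code{centrosome_ay_um},
#'   \code{centrosome_bx_um}, \code{centrosome_by_um}.
#' @export
generate_point_geometry <- function(n_pairs, separation_um, angle_deg,
                                    jitter_um = 0, seed = 1L) {
  if (n_pairs < 1) stop("n_pairs must be >= 1")
  if (separation_um <= 0) stop("separation_um must be > 0")
  if (angle_deg <= 0 || angle_deg > 180) stop("angle_deg must be in (0, 180]")
  withr::with_seed(seed, {
    gside <- ceiling(sqrt(n_pairs))
    spacing <- 3 * separation_um
    i <- seq_len(n_pairs) - 1L
    nx <- (i %% gside) * spacing + spacing
    ny <- (i %/% gside) * spacing + spacing
    theta <- angle_deg * pi / 180
    r <- separation_um / (2 * sin(theta / 2))
    phi <- runif(n_pairs, 0, 2 * pi)       # random orientation
    ax <- nx + r * cos(phi - theta / 2)
    ay <- ny + r * sin(phi - theta / 2)
    bx <- nx + r * cos(phi + theta / 2)
    by <- ny + r * sin(phi + theta / 2)
    if (jitter_um > 0) {
      ax <- ax + rnorm(n_pairs, 0, jitter_um)
      ay <- ay + rnorm(n_pairs, 0, jitter_um)
      bx <- bx + rnorm(n_pairs, 0, jitter_um)
      by <- by + rnorm(n_pairs, 0, jitter_um)
    }
    data.frame(pair = seq_len(n_pairs),
               nucleus_x_um = nx, nucleus_y_um = ny,
               centrosome_ax_um = ax, centrosome_ay_um = ay,
               centrosome_bx_um = bx, centrosome_by_um = by)
  })
}
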